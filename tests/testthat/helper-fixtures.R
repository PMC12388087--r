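# Shared builders for in-code fixtures; everything is generated, nothing
# read from disk.

# data frame of SNP records with sensible defaults, overridable per column
snp_df <- function(n = 3, snp = sprintf("rs%03d", seq_len(n)), chr = "1",
                   pos = seq_len(n) * 100000L, effect_allele = "A",
                   other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.02,
                   pvalue = NULL, n_sample = 10000) {
  beta <- rep_len(beta, n); se <- rep_len(se, n)
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  data.frame(snp = snp, chr = chr, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n_sample,
             stringsAsFactors = FALSE)
}

quick_stats <- function(df, name = "trait", type = "quantitative", ...) {
  summary_stats(df, trait_name = name, trait_type = type,
                check_p_consistency = FALSE, ...)
}

# summary stats from a vector of z-scores (constant se), for coloc fixtures
z_stats <- function(z, se = 0.02, name = "trait", type = "quantitative",
                    chr = "1", pos0 = 1000000L) {
  n <- length(z)
  quick_stats(snp_df(n, chr = chr, pos = pos0 + seq_len(n) * 1000L,
                     beta = z * se, se = se,
                     pvalue = pmax(2 * pnorm(-abs(z)), 1e-300)),
              name = name, type = type)
}

# harmonized-pair-shaped data frame for direct estimator input
pair_df <- function(bx, sx, by, sy, snp = sprintf("rs%03d", seq_along(bx))) {
  data.frame(snp = snp, beta_exp = bx, se_exp = sx, beta_out = by, se_out = sy,
             stringsAsFactors = FALSE)
}

# agreement with a printed value: to its printed precision, or 0.2% relative
# for values whose rounding error is dominated by the rounded inputs
expect_printed <- function(value, printed) {
  dec <- nchar(sub("^[^.]*\\.?", "", format(printed, scientific = FALSE)))
  tol <- max(0.5 * 10^(-dec), 0.002 * abs(printed))
  expect_lt(abs(value - printed), tol + 1e-12)
}
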