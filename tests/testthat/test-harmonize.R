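make_pair <- function(exp_alleles, out_alleles, beta_out = 0.3, eaf_exp = 0.3,
                      eaf_out = 0.3, palindromic_eaf_limit = 0.42) {
  ex <- quick_stats(snp_df(1, effect_allele = exp_alleles[1],
                           other_allele = exp_alleles[2], eaf = eaf_exp),
                    name = "exp")
  ou <- quick_stats(snp_df(1, effect_allele = out_alleles[1],
                           other_allele = out_alleles[2], beta = beta_out,
                           se = 0.05, eaf = eaf_out),
                    name = "out")
  harmonize(ex, ou, palindromic_eaf_limit = palindromic_eaf_limit)
}

test_that("swapped outcome orientation flips the outcome beta and EAF", {
  h <- make_pair(c("A", "G"), c("G", "A"), beta_out = 0.3, eaf_out = 0.7)
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_out, -0.3)
  expect_equal(h$eaf_out, 0.3)
  expect_equal(h$effect_allele, "A")  # exposure orientation reported
})

test_that("strand-complement labels are reconciled", {
  expect_equal(make_pair(c("A", "G"), c("T", "C"))$action, "kept")
  h <- make_pair(c("A", "G"), c("C", "T"), beta_out = 0.3)
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_out, -0.3)
})

test_that("palindromic SNPs resolve by allele frequency or drop", {
  # frequency at 0.5 is uninformative
  h <- make_pair(c("A", "T"), c("A", "T"), eaf_exp = 0.5, eaf_out = 0.5)
  expect_equal(h$action, "dropped_palindromic")
  # inside the ambiguity zone
  h <- make_pair(c("C", "G"), c("C", "G"), eaf_exp = 0.44, eaf_out = 0.3)
  expect_equal(h$action, "dropped_palindromic")
  # informative and concordant
  h <- make_pair(c("A", "T"), c("A", "T"), eaf_exp = 0.2, eaf_out = 0.25)
  expect_equal(h$action, "palindromic_kept")
  expect_equal(h$beta_out, 0.3)
  # label-swapped palindromic: flip, then frequencies agree
  h <- make_pair(c("A", "T"), c("T", "A"), eaf_exp = 0.2, eaf_out = 0.8)
  expect_equal(h$action, "palindromic_kept")
  expect_equal(h$beta_out, -0.3)
  # discordant frequency sides after alignment
  h <- make_pair(c("A", "T"), c("A", "T"), eaf_exp = 0.2, eaf_out = 0.8)
  expect_equal(h$action, "dropped_palindromic")
  # missing frequency drops conservatively
  h <- make_pair(c("A", "T"), c("A", "T"), eaf_exp = NA, eaf_out = 0.2)
  expect_equal(h$action, "dropped_palindromic")
})

test_that("irreconcilable allele pairs are dropped", {
  expect_equal(make_pair(c("A", "G"), c("A", "C"))$action, "dropped_allele_mismatch")
  expect_equal(make_pair(c("A", "T"), c("A", "G"))$action, "dropped_allele_mismatch")
})

test_that("empty intersection is an error naming both traits", {
  e1 <- quick_stats(snp_df(2), name = "taxonA")
  e2 <- quick_stats(snp_df(2, snp = c("rs900", "rs901")), name = "mpn")
  expect_error(harmonize(e1, e2), "taxonA.*mpn")
})

test_that("randomized orientations recover the generator's ground truth", {
  sim <- simulate_gwas(sim_config(seed = 11, n_snp = 50, n_instruments = 15,
                                  n_med_instruments = 0, gamma_sd = 0.1,
                                  beta_direct_true = 0.3))
  for (target in c("mediator", "outcome")) {
    h <- harmonize(sim$exposure, sim[[target]])
    kept <- kept_rows(h)
    expect_gt(nrow(kept), 20)  # most SNPs survive; palindromes may drop
    truth <- sim$truth$per_snp[match(kept$snp, sim$truth$per_snp$snp), ]
    obs_col <- paste0("obs_beta_", target)
    # harmonized outcome betas equal the true-orientation observed betas
    expect_equal(kept$beta_out, truth[[obs_col]], tolerance = 1e-12)
    expect_equal(kept$eaf_out, truth$maf, tolerance = 1e-12)
    # no kept row has mismatched allele pairs
    expect_true(all(kept$effect_allele != kept$other_allele))
  }
})

test_that("harmonization is idempotent and double-flip is the identity", {
  sim <- simulate_gwas(sim_config(seed = 12, n_snp = 60, n_instruments = 20,
                                  n_med_instruments = 0, gamma_sd = 0.1,
                                  beta_direct_true = 0.2))
  h <- harmonize(sim$exposure, sim$outcome)
  kept <- kept_rows(h)

  # rebuild the outcome in exposure orientation and harmonize again
  out2 <- quick_stats(
    data.frame(snp = kept$snp, chr = kept$chr, pos = kept$pos,
               effect_allele = kept$effect_allele, other_allele = kept$other_allele,
               eaf = kept$eaf_out, beta = kept$beta_out, se = kept$se_out,
               pvalue = kept$pval_out, n = 1000),
    name = "outcome2", type = "binary")
  h2 <- kept_rows(harmonize(sim$exposure, out2))
  expect_equal(h2$beta_out, kept$beta_out[match(h2$snp, kept$snp)], tolerance = 1e-12)
  expect_true(all(h2$action %in% c("kept", "palindromic_kept")))

  # negate outcome betas and swap its alleles: kept pairs are unchanged
  flipped_df <- as.data.frame(sim$outcome)
  flipped_df$beta <- -flipped_df$beta
  flipped_df$eaf <- 1 - flipped_df$eaf
  tmp <- flipped_df$effect_allele
  flipped_df$effect_allele <- flipped_df$other_allele
  flipped_df$other_allele <- tmp
  hf <- kept_rows(harmonize(sim$exposure, quick_stats(flipped_df, name = "outflip")))
  common <- intersect(hf$snp, kept$snp)
  expect_equal(hf$beta_out[match(common, hf$snp)],
               kept$beta_out[match(common, kept$snp)], tolerance = 1e-12)
  expect_equal(hf$beta_exp[match(common, hf$snp)],
               kept$beta_exp[match(common, kept$snp)], tolerance = 1e-12)
})
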