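#' Wakefield approximate Bayes factor (log scale)
#'
#' For a per-SNP estimate `beta` with variance `V = se^2` and a normal prior
#' with standard deviation `prior_sd` (`W = prior_sd^2`) on the true effect,
#' the log approximate Bayes factor against the null is
#' `0.5 * (log(V/(V+W)) + z^2 * W/(V+W))` with `z = beta/se`.
#'
#' @param beta,se Per-SNP effect estimates and standard errors (vectorized).
#' @param prior_sd Prior standard deviation of the true effect; conventional
#'   values are 0.15 for quantitative traits and 0.2 for binary traits on the
#'   log-odds scale.
#' @return Numeric vector of log Bayes factors.
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(is.na(se)) || any(se <= 0)) stop("`se` must be positive", call. = FALSE)
  assert_scalar_number(prior_sd, "prior_sd", positive = TRUE)
  v <- se^2
  w <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * (log(v / (v + w)) + z2 * w / (v + w))
}

#' Restrict summary statistics to a locus window
#'
#' @param stats A `summary_stats` object with coordinates.
#' @param chr Chromosome of the anchor.
#' @param anchor_pos Anchor position (1-based), e.g. a gene midpoint.
#' @param window_kb Half-width of the window in kilobases (default 500, i.e.
#'   anchor +/- 500 kb).
#' @return The `summary_stats` subset inside the window.
#' @export
window_locus <- function(stats, chr, anchor_pos, window_kb = 500) {
  stopifnot(inherits(stats, "summary_stats"))
  keep <- !is.na(stats$chr) & stats$chr == as.character(chr) &
    !is.na(stats$pos) & abs(stats$pos - anchor_pos) <= window_kb * 1000
  out <- stats[keep, , drop = FALSE]
  attributes(out)[c("trait_name", "trait_type", "case_count", "control_count")] <-
    attributes(stats)[c("trait_name", "trait_type", "case_count", "control_count")]
  class(out) <- class(stats)
  out
}

#' Bayesian colocalization of two traits at a locus
#'
#' Tests, from summary statistics alone, whether two traits share a causal
#' variant at a locus, under the standard five-hypothesis model with a single
#' causal variant per trait:
#'
#' * H0: no association with either trait;
#' * H1 / H2: association with trait 1 / trait 2 only;
#' * H3: both traits associated, distinct causal variants;
#' * H4: both traits associated, one shared causal variant.
#'
#' Per-SNP log approximate Bayes factors ([log_abf()]) for each trait are
#' combined with per-hypothesis priors (`p1`, `p2`: a SNP is causal for one
#' trait; `p12`: causal for both) through log-sum-exp accumulation, so the
#' computation stays finite for z-scores far beyond overflow of the plain
#' Bayes factors. Posterior probabilities PPH0-PPH4 sum to one; `PPH4 >
#' pph4_threshold` (default 0.75) is called colocalization.
#'
#' @param trait1,trait2 `summary_stats` objects, typically pre-windowed with
#'   [window_locus()] (or pass `chr`/`anchor_pos` to window here). At least
#'   two shared SNPs are required.
#' @param p1,p2,p12 Prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_sd1,prior_sd2 Prior effect standard deviations; default 0.15
#'   for quantitative and 0.2 for binary traits.
#' @param chr,anchor_pos,window_kb Optional locus window applied to both
#'   traits before intersection.
#' @param locus_id Label for the report row.
#' @param pph4_threshold Decision threshold on PPH4 (default 0.75).
#' @return A one-row tibble of class `coloc_result` with columns `locus_id,
#'   n_snp, pph0, pph1, pph2, pph3, pph4, p1, p2, p12, colocalized`.
#' @export
colocalize <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       prior_sd1 = NULL, prior_sd2 = NULL,
                       chr = NULL, anchor_pos = NULL, window_kb = 500,
                       locus_id = NULL, pph4_threshold = 0.75) {
  stopifnot(inherits(trait1, "summary_stats"), inherits(trait2, "summary_stats"))
  for (p in c(p1, p2, p12)) {
    if (p <= 0 || p >= 1) stop("priors must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(anchor_pos)) {
    trait1 <- window_locus(trait1, chr, anchor_pos, window_kb)
    trait2 <- window_locus(trait2, chr, anchor_pos, window_kb)
  }
  default_sd <- function(tr) if (identical(trait_type(tr), "binary")) 0.2 else 0.15
  prior_sd1 <- prior_sd1 %||% default_sd(trait1)
  prior_sd2 <- prior_sd2 %||% default_sd(trait2)

  shared <- sort(intersect(trait1$snp, trait2$snp))
  if (length(shared) < 2L) {
    stop(sprintf("colocalization needs at least 2 shared SNPs at the locus (found %d)",
                 length(shared)), call. = FALSE)
  }
  t1 <- trait1[match(shared, trait1$snp), , drop = FALSE]
  t2 <- trait2[match(shared, trait2$snp), , drop = FALSE]
  l1 <- log_abf(t1$beta, t1$se, prior_sd1)
  l2 <- log_abf(t2$beta, t2$se, prior_sd2)

  s1 <- log_sum_exp(l1)
  s2 <- log_sum_exp(l2)
  s12 <- log_sum_exp(l1 + l2)   # shared-SNP terms

  lh <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    h3 = log(p1) + log(p2) + log_diff_exp(s1 + s2, s12),
    h4 = log(p12) + s12
  )
  denom <- log_sum_exp(lh)
  pp <- exp(lh - denom)

  structure(
    tibble::tibble(
      locus_id = locus_id %||% sprintf("%s:%s", trait_name(trait1), trait_name(trait2)),
      n_snp = length(shared),
      pph0 = pp[["h0"]], pph1 = pp[["h1"]], pph2 = pp[["h2"]],
      pph3 = pp[["h3"]], pph4 = pp[["h4"]],
      p1 = p1, p2 = p2, p12 = p12,
      colocalized = pp[["h4"]] > pph4_threshold
    ),
    class = c("coloc_result", class(tibble::tibble()))
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  if (all(c("locus_id", "n_snp", "pph4", "colocalized") %in% names(x))) {
    cat(sprintf("<coloc_result> locus %s (%d SNPs): PPH4 = %.3f (%scolocalized)\n",
                x$locus_id[1], x$n_snp[1], x$pph4[1],
                if (x$colocalized[1]) "" else "not "))
  }
  NextMethod()
}
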