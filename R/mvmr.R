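#' Multivariable MR from summary associations
#'
#' Estimates the direct effect of each of several exposures on one outcome by
#' weighted multiple linear regression, without intercept, of the per-SNP
#' outcome betas on the matrix of exposure betas, with weights `1/se_out^2`.
#' Per-exposure standard errors come from the weighted-least-squares
#' covariance with the residual scale floored at 1 (never below the
#' fixed-effect covariance); p-values are two-sided normal.
#'
#' Exposure columns that are identically zero carry no information and are
#' reported as `NA` with a warning; genuine collinearity among the remaining
#' exposures is an error naming the offending exposures.
#'
#' @param bx Numeric matrix (`J` SNPs by `K` exposures) of SNP-exposure betas,
#'   all aligned to the same per-SNP effect allele as `by`.
#' @param by,se_out Per-SNP outcome betas and standard errors.
#' @param exposure_names Labels for the `K` exposures; defaults to
#'   `colnames(bx)`.
#' @param outcome_name Outcome label for the report.
#' @return A tibble of class `mvmr_estimate`, one row per exposure with
#'   `exposure, outcome, n_snp, beta, se, pvalue, or, ci_low, ci_high`.
#' @export
mvmr_fit <- function(bx, by, se_out, exposure_names = colnames(bx),
                     outcome_name = "outcome") {
  bx <- as.matrix(bx)
  k <- ncol(bx)
  j <- nrow(bx)
  if (k < 2L) stop("multivariable MR needs at least 2 exposures", call. = FALSE)
  if (is.null(exposure_names)) exposure_names <- paste0("exposure", seq_len(k))
  if (length(by) != j || length(se_out) != j) {
    stop("`by` and `se_out` must have one entry per SNP row of `bx`", call. = FALSE)
  }
  if (j < k + 1L) {
    stop(sprintf("multivariable MR needs at least %d SNPs for %d exposures (got %d)",
                 k + 1L, k, j), call. = FALSE)
  }

  zero_col <- apply(bx, 2L, function(col) all(col == 0))
  if (any(zero_col)) {
    warning("exposure(s) with all-zero instrument betas reported as NA: ",
            paste(exposure_names[zero_col], collapse = ", "), call. = FALSE)
  }
  use <- which(!zero_col)
  xm <- bx[, use, drop = FALSE]
  if (qr(xm)$rank < ncol(xm)) {
    stop("collinear exposure betas in multivariable MR: ",
         paste(exposure_names[use], collapse = ", "), call. = FALSE)
  }

  # explicit weighted least squares: bhat = (X'WX)^-1 X'Wy, residual scale
  # floored at 1 so the covariance never shrinks below the fixed-effect one
  w <- 1 / se_out^2
  xtwx <- crossprod(xm, xm * w)
  xtwx_inv <- solve(xtwx)
  bhat <- drop(xtwx_inv %*% crossprod(xm, w * by))
  resid <- by - drop(xm %*% bhat)
  sigma2 <- sum(w * resid^2) / (j - length(use))
  scale <- max(1, sqrt(sigma2))
  beta <- rep(NA_real_, k)
  se <- rep(NA_real_, k)
  beta[use] <- bhat
  se[use] <- sqrt(diag(xtwx_inv)) * scale
  pvalue <- z_pvalue(beta, se)
  odds <- to_odds_scale(beta, se)

  structure(
    tibble::tibble(
      exposure = exposure_names, outcome = outcome_name, n_snp = j,
      beta = beta, se = se, pvalue = pvalue,
      or = odds$or, ci_low = odds$ci_low, ci_high = odds$ci_high
    ),
    class = c("mvmr_estimate", class(tibble::tibble()))
  )
}

#' Multivariable MR from harmonized pairs
#'
#' Joins one harmonized exposure-outcome pair per exposure (all against the
#' same outcome) on the SNPs kept in every pair, re-orients every exposure's
#' betas to the first pair's per-SNP effect allele, and fits [mvmr_fit()].
#' SNPs whose allele pairs cannot be reconciled across exposures are dropped.
#'
#' @param pairs Named list of `harmonized_pair` objects sharing the outcome.
#' @param snps Optional SNP ids (e.g. the union of per-exposure instruments,
#'   jointly re-clumped) to restrict the regression to.
#' @return A `mvmr_estimate` tibble (see [mvmr_fit()]).
#' @export
mvmr <- function(pairs, snps = NULL) {
  if (!is.list(pairs) || length(pairs) < 2L) {
    stop("`pairs` must be a list of at least 2 harmonized pairs", call. = FALSE)
  }
  stopifnot(all(vapply(pairs, inherits, logical(1), "harmonized_pair")))
  nm <- names(pairs) %||% vapply(pairs, function(p) attr(p, "exposure_name"), character(1))
  if (is.null(names(pairs))) names(pairs) <- nm
  outcome_name <- attr(pairs[[1L]], "outcome_name") %||% "outcome"

  kept <- lapply(pairs, kept_rows, snps = snps)
  shared <- Reduce(intersect, lapply(kept, function(k) k$snp))
  if (length(shared) == 0L) stop("no SNPs shared across all exposures", call. = FALSE)
  shared <- sort(shared)

  ref <- kept[[1L]][match(shared, kept[[1L]]$snp), , drop = FALSE]
  bx <- matrix(NA_real_, nrow = length(shared), ncol = length(pairs),
               dimnames = list(shared, names(pairs)))
  ok <- rep(TRUE, length(shared))
  for (i in seq_along(kept)) {
    ki <- kept[[i]][match(shared, kept[[i]]$snp), , drop = FALSE]
    # align exposure i to the reference pair's effect allele, allowing for
    # strand-complement labels
    exact_same <- ki$effect_allele == ref$effect_allele & ki$other_allele == ref$other_allele
    exact_swap <- ki$effect_allele == ref$other_allele & ki$other_allele == ref$effect_allele
    comp_same <- complement_allele(ki$effect_allele) == ref$effect_allele &
      complement_allele(ki$other_allele) == ref$other_allele
    comp_swap <- complement_allele(ki$effect_allele) == ref$other_allele &
      complement_allele(ki$other_allele) == ref$effect_allele
    # exact label matches take priority so palindromic SNPs (where the
    # complement reproduces the same pair) are not double-counted as swapped
    same <- exact_same | (!exact_same & !exact_swap & comp_same)
    swapped <- exact_swap | (!exact_same & !exact_swap & comp_swap)
    ok <- ok & (same | swapped)
    bx[, i] <- ifelse(swapped, -ki$beta_exp, ki$beta_exp)
  }
  if (!all(ok)) {
    message(sprintf("mvmr: dropped %d SNP(s) with irreconcilable alleles across exposures",
                    sum(!ok)))
  }
  bx <- bx[ok, , drop = FALSE]
  ref <- ref[ok, , drop = FALSE]
  mvmr_fit(bx, by = ref$beta_out, se_out = ref$se_out,
           exposure_names = names(pairs), outcome_name = outcome_name)
}
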