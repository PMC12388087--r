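# Univariable two-sample MR estimators and sensitivity statistics.

new_mr_estimate <- function(exposure, outcome, method, n_snp, beta, se, pvalue,
                            egger_intercept = NA_real_, egger_intercept_se = NA_real_,
                            egger_intercept_p = NA_real_,
                            q_statistic = NA_real_, q_pvalue = NA_real_) {
  odds <- to_odds_scale(beta, se)
  tibble::tibble(
    exposure = exposure, outcome = outcome, method = method,
    n_snp = as.integer(n_snp),
    beta = beta, se = se, pvalue = pvalue,
    or = odds$or, ci_low = odds$ci_low, ci_high = odds$ci_high,
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_p = egger_intercept_p,
    q_statistic = q_statistic, q_pvalue = q_pvalue
  )
}

#' Convert a log-scale effect to an odds ratio with 95% CI
#'
#' For binary outcomes modeled on the log-odds scale, `OR = exp(beta)` with
#' normal-theory confidence limits `exp(beta -/+ z * se)`.
#'
#' @param beta,se Effect estimate(s) and standard error(s) (vectorized).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with columns `or`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' to_odds_scale(6.868, 3.138)  # OR ~ 961, CI lower ~ 2.05
to_odds_scale <- function(beta, se, conf_level = 0.95) {
  if (any(!is.na(se) & se <= 0)) stop("`se` must be positive", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Wald-ratio causal estimate from a single SNP
#'
#' `beta = beta_out / beta_exp` with, by default, the first-order delta-method
#' standard error `se_out / |beta_exp|`. The second-order expansion
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)` is
#' available and is never smaller than the first-order value.
#'
#' @param beta_exp,se_exp SNP-exposure estimate and standard error.
#' @param beta_out,se_out SNP-outcome estimate and standard error.
#' @param exposure,outcome Trait labels for the report row.
#' @param second_order Use the second-order delta-method SE (default `FALSE`).
#' @return A one-row `mr_estimate` tibble (method `"wald_ratio"`).
#' @export
mr_wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                          exposure = "exposure", outcome = "outcome",
                          second_order = FALSE) {
  assert_scalar_number(beta_exp, "beta_exp")
  assert_scalar_number(se_exp, "se_exp", positive = TRUE)
  assert_scalar_number(beta_out, "beta_out")
  assert_scalar_number(se_out, "se_out", positive = TRUE)
  if (beta_exp == 0) stop("Wald ratio undefined: SNP-exposure beta is zero", call. = FALSE)
  beta <- beta_out / beta_exp
  se <- if (second_order) {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  } else {
    se_out / abs(beta_exp)
  }
  new_mr_estimate(exposure, outcome, "wald_ratio", 1L, beta, se, z_pvalue(beta, se))
}

# Extract the (bx, sx, by, sy) arrays an estimator consumes
#' @noRd
pair_inputs <- function(pair, snps = NULL) {
  if (inherits(pair, "harmonized_pair")) {
    k <- kept_rows(pair, snps)
    list(bx = k$beta_exp, sx = k$se_exp, by = k$beta_out, sy = k$se_out,
         snp = k$snp,
         exposure = attr(pair, "exposure_name") %||% "exposure",
         outcome = attr(pair, "outcome_name") %||% "outcome")
  } else if (is.data.frame(pair)) {
    need <- c("beta_exp", "se_exp", "beta_out", "se_out")
    if (!all(need %in% names(pair))) {
      stop("data frame input needs columns ", paste(need, collapse = ", "), call. = FALSE)
    }
    list(bx = pair$beta_exp, sx = pair$se_exp, by = pair$beta_out, sy = pair$se_out,
         snp = pair$snp %||% as.character(seq_len(nrow(pair))),
         exposure = "exposure", outcome = "outcome")
  } else {
    stop("`pair` must be a harmonized_pair or a data frame", call. = FALSE)
  }
}

#' Cochran's Q heterogeneity statistic over per-SNP Wald ratios
#'
#' `Q = sum(w_j * (r_j - pooled_beta)^2)` with `w_j = 1/se(r_j)^2`, where
#' `r_j` are the per-SNP ratio estimates; under homogeneity Q is chi-square
#' with `J - 1` degrees of freedom.
#'
#' @param ratio Per-SNP Wald-ratio estimates.
#' @param ratio_se Their (first-order) standard errors.
#' @param pooled_beta The pooled causal estimate the ratios are compared to.
#' @return List with elements `q`, `df` and `p`.
#' @export
cochran_q <- function(ratio, ratio_se, pooled_beta) {
  stopifnot(length(ratio) == length(ratio_se), length(ratio) >= 2L)
  if (any(ratio_se <= 0)) stop("ratio standard errors must be positive", call. = FALSE)
  q <- sum((ratio - pooled_beta)^2 / ratio_se^2)
  df <- length(ratio) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-SNP Wald ratios with weights `1/se_out^2`, equivalent to a
#' weighted regression of outcome betas on exposure betas through the origin:
#' `beta = sum(w * bx * by) / sum(w * bx^2)`. The default multiplicative
#' random-effects model scales the fixed-effect standard error by
#' `sqrt(Q/(J-1))` whenever that exceeds 1, so the SE never shrinks below the
#' fixed-effect value; `method = "fixed"` disables the scaling. Inference is
#' normal-theory; Cochran's Q is attached.
#'
#' @param pair A `harmonized_pair` (kept rows are used) or a data frame with
#'   columns `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @param snps Optional SNP ids or an `instrument_set` to restrict to.
#' @param method `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @param allow_single Permit a one-SNP input, in which case the estimate
#'   reduces to the Wald ratio (default `FALSE`: one SNP is an error and the
#'   caller should route to [mr_wald_ratio()]).
#' @return A one-row `mr_estimate` tibble (method `"ivw"`).
#' @export
mr_ivw <- function(pair, snps = NULL, method = c("random", "fixed"),
                   allow_single = FALSE) {
  method <- match.arg(method)
  d <- pair_inputs(pair, snps)
  j <- length(d$bx)
  if (j == 0L) stop("no usable SNPs for IVW", call. = FALSE)
  if (j < 2L && !allow_single) {
    stop("IVW requires at least 2 SNPs; use mr_wald_ratio() for a single SNP",
         call. = FALSE)
  }
  w <- 1 / d$sy^2
  beta <- sum(w * d$bx * d$by) / sum(w * d$bx^2)
  se_fe <- sqrt(1 / sum(w * d$bx^2))
  q_statistic <- NA_real_; q_pvalue <- NA_real_
  se <- se_fe
  if (j >= 2L) {
    qq <- cochran_q(d$by / d$bx, d$sy / abs(d$bx), beta)
    q_statistic <- qq$q; q_pvalue <- qq$p
    if (method == "random") se <- se_fe * max(1, sqrt(qq$q / (j - 1L)))
  }
  new_mr_estimate(d$exposure, d$outcome, "ivw", j, beta, se, z_pvalue(beta, se),
                  q_statistic = q_statistic, q_pvalue = q_pvalue)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with a free
#' intercept and weights `1/se_out^2`, after orienting each SNP so its
#' exposure beta is non-negative. The slope is the pleiotropy-adjusted causal
#' estimate; a non-zero intercept indicates directional horizontal
#' pleiotropy. Slope and intercept inference uses the t-distribution with
#' `J - 2` degrees of freedom; standard errors are floored at their
#' fixed-effect values (the residual scale is never taken below 1). Rücker's
#' Q' (heterogeneity about the Egger fit, `J - 2` df) is attached.
#'
#' @inheritParams mr_ivw
#' @return A one-row `mr_estimate` tibble (method `"mr_egger"`) with
#'   `egger_intercept`, `egger_intercept_se` and `egger_intercept_p` filled.
#' @export
mr_egger <- function(pair, snps = NULL) {
  d <- pair_inputs(pair, snps)
  j <- length(d$bx)
  if (j < 3L) stop("MR-Egger requires at least 3 SNPs", call. = FALSE)
  flip <- sign(d$bx)
  flip[flip == 0] <- 1
  bx <- d$bx * flip
  by <- d$by * flip
  # explicit weighted least squares with intercept; residual scale floored
  # at 1 (the SE never shrinks below its fixed-effect value)
  w <- 1 / d$sy^2
  x <- cbind(icpt = 1, bx = bx)
  xtwx_inv <- solve(crossprod(x, x * w))
  coefs <- drop(xtwx_inv %*% crossprod(x, w * by))
  resid <- by - drop(x %*% coefs)
  sigma2 <- sum(w * resid^2) / (j - 2L)
  scale <- max(1, sqrt(sigma2))
  ses <- sqrt(diag(xtwx_inv)) * scale
  slope <- coefs[["bx"]]
  slope_se <- ses[["bx"]]
  icpt <- coefs[["icpt"]]
  icpt_se <- ses[["icpt"]]
  df <- j - 2L
  slope_p <- 2 * stats::pt(-abs(slope / slope_se), df)
  icpt_p <- 2 * stats::pt(-abs(icpt / icpt_se), df)
  qp <- sum(w * (by - icpt - slope * bx)^2)
  new_mr_estimate(d$exposure, d$outcome, "mr_egger", j,
                  slope, slope_se, slope_p,
                  egger_intercept = icpt, egger_intercept_se = icpt_se,
                  egger_intercept_p = icpt_p,
                  q_statistic = qp,
                  q_pvalue = stats::pchisq(qp, df, lower.tail = FALSE))
}
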