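#' Two-step mediation MR with proportion mediated
#'
#' Decomposes the total causal effect of an exposure on an outcome into the
#' component transmitted through a mediator, using the product of
#' coefficients: with `beta_EM` the exposure-to-mediator effect, `beta_MO`
#' the mediator-to-outcome effect and `beta_EO` the total exposure-to-outcome
#' effect,
#'
#' * indirect effect  = `beta_EM * beta_MO`
#' * direct effect    = `beta_EO - indirect`
#' * proportion mediated = `indirect / beta_EO`
#'
#' The accounting identities `indirect + direct = beta_EO` and
#' `proportion * beta_EO = indirect` hold exactly. A first-order delta-method
#' standard error for the proportion is computed treating the three estimates
#' as independent (customary in two-sample designs where each leg comes from
#' non-overlapping cohorts). A proportion outside `[0, 1]` — possible when the
#' indirect and total effects disagree in sign — is returned and flagged, not
#' treated as an error. The no-interaction assumption of two-step MR (the
#' mediator effect does not depend on exposure level) is not testable from
#' summary data and is simply assumed.
#'
#' @param est_EO,est_EM,est_MO The three component estimates: `mr_estimate`
#'   rows (from [mr_ivw()] etc.) or lists/one-row data frames with at least
#'   `beta` and `se` elements.
#' @param exposure,mediator,outcome Optional trait labels; defaults are taken
#'   from the component estimates where available.
#' @return A one-row tibble of class `mediation_result` with columns
#'   `exposure, mediator, outcome, beta_EO, beta_EM, beta_MO, indirect,
#'   direct, proportion_mediated, proportion_pct, se_proportion,
#'   proportion_outside_unit`; the three component estimates are attached as
#'   the `components` attribute.
#' @export
#' @examples
#' # published gut-microbiota -> succinylcarnitine -> MPN pathway constants
#' two_step_mediation(
#'   est_EO = list(beta = log(0.49), se = 0.36),
#'   est_EM = list(beta = 0.046, se = 0.019),
#'   est_MO = list(beta = -2.244, se = 1.076)
#' )$proportion_pct  # ~14.5
two_step_mediation <- function(est_EO, est_EM, est_MO,
                               exposure = NULL, mediator = NULL, outcome = NULL) {
  take <- function(est, field) {
    v <- if (is.data.frame(est)) est[[field]][1] else est[[field]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  b_eo <- take(est_EO, "beta"); s_eo <- take(est_EO, "se")
  b_em <- take(est_EM, "beta"); s_em <- take(est_EM, "se")
  b_mo <- take(est_MO, "beta"); s_mo <- take(est_MO, "se")
  for (v in list(b_eo, b_em, b_mo)) assert_scalar_number(v, "beta")
  if (b_eo == 0) stop("proportion mediated undefined: total effect beta_EO is zero",
                      call. = FALSE)

  exposure <- exposure %||% (if (is.data.frame(est_EO)) est_EO$exposure[1] else NULL) %||% "exposure"
  mediator <- mediator %||% (if (is.data.frame(est_MO)) est_MO$exposure[1] else NULL) %||% "mediator"
  outcome <- outcome %||% (if (is.data.frame(est_EO)) est_EO$outcome[1] else NULL) %||% "outcome"

  indirect <- b_em * b_mo
  direct <- b_eo - indirect
  prop <- indirect / b_eo

  # first-order delta method, independent components:
  # prop = b_em * b_mo / b_eo; gradient (b_mo/b_eo, b_em/b_eo, -prop/b_eo)
  se_prop <- if (anyNA(c(s_em, s_mo, s_eo))) {
    NA_real_
  } else {
    sqrt((b_mo / b_eo)^2 * s_em^2 + (b_em / b_eo)^2 * s_mo^2 + (prop / b_eo)^2 * s_eo^2)
  }

  outside <- prop < 0 || prop > 1
  if (outside) {
    message(sprintf("proportion mediated %.3f lies outside [0, 1] (sign-discordant indirect and total effects)",
                    prop))
  }
  res <- tibble::tibble(
    exposure = exposure, mediator = mediator, outcome = outcome,
    beta_EO = b_eo, beta_EM = b_em, beta_MO = b_mo,
    indirect = indirect, direct = direct,
    proportion_mediated = prop, proportion_pct = 100 * prop,
    se_proportion = se_prop,
    proportion_outside_unit = outside
  )
  structure(res,
            components = list(EO = est_EO, EM = est_EM, MO = est_MO),
            class = c("mediation_result", class(tibble::tibble())))
}

#' @export
print.mediation_result <- function(x, ...) {
  if (all(c("exposure", "mediator", "outcome", "proportion_pct") %in% names(x))) {
    cat(sprintf("<mediation_result> %s -> %s -> %s: %.1f%% of the total effect mediated\n",
                x$exposure[1], x$mediator[1], x$outcome[1], x$proportion_pct[1]))
  }
  NextMethod()
}
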