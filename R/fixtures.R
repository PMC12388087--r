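#' Published effect estimates for the microbiota-metabolite-MPN pathways
#'
#' Packages the reported summary estimates for the two mediation pathways
#' linking the *Eubacterium xylanophilum* group to myeloproliferative
#' neoplasm (MPN) risk through plasma metabolites, exactly as printed in the
#' source study:
#'
#' * the total effect of the taxon on MPN, reported as OR 0.49
#'   (`beta_EO = log(0.49)`, 95% CI 0.24-1.00);
#' * the taxon-to-metabolite legs (IVW): succinylcarnitine `beta = 0.046`
#'   (se 0.019), lysine `beta = -0.029` (se 0.014);
#' * the metabolite-to-MPN legs, univariable: succinylcarnitine
#'   `beta = -2.244` (se 1.076), lysine `beta = 6.868` (se 3.138);
#' * the corresponding multivariable estimates: succinylcarnitine
#'   `beta = -2.342` (se 0.823), lysine `beta = 5.714` (se 2.780).
#'
#' Routed through [two_step_mediation()], the univariable legs reproduce the
#' reported mediated proportions of about 14.5% (succinylcarnitine) and
#' 27.9% (lysine). Used by examples and validation tests; the constants are
#' printed values, not re-estimated.
#'
#' @return Nested list with elements `beta_EO`, `se_EO`, `or_EO`, and one
#'   sublist per metabolite (`succinylcarnitine`, `lysine`) holding
#'   `beta_EM`, `se_EM`, `beta_MO`, `se_MO`, `beta_MO_mv`, `se_MO_mv`.
#' @export
#' @examples
#' k <- mpn_mediation_constants()
#' with(k$succinylcarnitine, beta_EM * beta_MO) / k$beta_EO  # ~0.145
mpn_mediation_constants <- function() {
  list(
    exposure = "Eubacterium xylanophilum group",
    outcome = "MPN",
    or_EO = 0.49,
    beta_EO = log(0.49),
    # CI 0.24-1.00 implies se = (log(1.00) - log(0.24)) / (2 * 1.96)
    se_EO = (log(1.00) - log(0.24)) / (2 * stats::qnorm(0.975)),
    succinylcarnitine = list(
      beta_EM = 0.046, se_EM = 0.019,
      beta_MO = -2.244, se_MO = 1.076,
      beta_MO_mv = -2.342, se_MO_mv = 0.823
    ),
    lysine = list(
      beta_EM = -0.029, se_EM = 0.014,
      beta_MO = 6.868, se_MO = 3.138,
      beta_MO_mv = 5.714, se_MO_mv = 2.780
    )
  )
}
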