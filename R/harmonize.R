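#' Harmonize effect alleles between two summary-statistics sets
#'
#' Two-sample MR requires the exposure and outcome effect estimates at each
#' shared SNP to refer to the same effect allele. For every SNP in the
#' intersection this function aligns the outcome record to the exposure's
#' allele orientation:
#'
#' * same allele pair, same orientation: kept unchanged (`kept`);
#' * same pair, swapped orientation: outcome beta negated and EAF
#'   complemented (`flipped`);
#' * strand-complement pair (e.g. exposure A/G vs outcome T/C): outcome
#'   alleles complemented first, then the two rules above;
#' * palindromic pair (A/T or C/G, where strand cannot be resolved from the
#'   alleles): kept only when both effect-allele frequencies are informative —
#'   on the same side of 0.5 and outside
#'   `[palindromic_eaf_limit, 1 - palindromic_eaf_limit]` — after label
#'   alignment (`palindromic_kept`), otherwise `dropped_palindromic`.
#'   A missing EAF on either side drops the SNP (conservative);
#' * irreconcilable allele pairs: `dropped_allele_mismatch`.
#'
#' Rows are returned for every shared SNP, in deterministic `snp` order, with
#' the action recorded; estimators consume only the kept rows (see
#' [kept_rows()]).
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param palindromic_eaf_limit Frequencies in
#'   `[limit, 1 - limit]` are considered too close to 0.5 to orient a
#'   palindromic SNP (default 0.42).
#' @return A tibble of class `harmonized_pair` with columns
#'   `snp, chr, pos, effect_allele, other_allele, eaf_exp, beta_exp, se_exp,
#'   pval_exp, eaf_out, beta_out, se_out, pval_out, action`, and
#'   `exposure_name`/`outcome_name` attributes. Alleles are reported in the
#'   exposure orientation.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_limit = 0.42) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  if (palindromic_eaf_limit <= 0 || palindromic_eaf_limit >= 0.5) {
    stop("`palindromic_eaf_limit` must be in (0, 0.5)", call. = FALSE)
  }
  shared <- sort(intersect(exposure$snp, outcome$snp))
  if (length(shared) == 0L) {
    stop(sprintf("no shared SNPs between exposures '%s' and '%s'",
                 trait_name(exposure), trait_name(outcome)), call. = FALSE)
  }
  ex <- as.data.frame(exposure)[match(shared, exposure$snp), , drop = FALSE]
  ou <- as.data.frame(outcome)[match(shared, outcome$snp), , drop = FALSE]

  n <- length(shared)
  action <- character(n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf

  e_ea <- ex$effect_allele; e_oa <- ex$other_allele
  o_ea <- ou$effect_allele; o_oa <- ou$other_allele
  lim_lo <- palindromic_eaf_limit
  lim_hi <- 1 - palindromic_eaf_limit

  for (i in seq_len(n)) {
    if (is_palindromic(e_ea[i], e_oa[i])) {
      # outcome alleles must form the same (self-complementary) pair
      if (!setequal(c(o_ea[i], o_oa[i]), c(e_ea[i], e_oa[i]))) {
        action[i] <- "dropped_allele_mismatch"
        next
      }
      flipped <- o_ea[i] != e_ea[i]
      ef <- ex$eaf[i]
      of <- if (flipped) 1 - ou$eaf[i] else ou$eaf[i]
      if (is.na(ef) || is.na(of) ||
          (ef >= lim_lo && ef <= lim_hi) || (of >= lim_lo && of <= lim_hi) ||
          (ef < 0.5) != (of < 0.5)) {
        action[i] <- "dropped_palindromic"
        next
      }
      if (flipped) {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- of
      }
      action[i] <- "palindromic_kept"
    } else {
      oc_ea <- complement_allele(o_ea[i]); oc_oa <- complement_allele(o_oa[i])
      if (o_ea[i] == e_ea[i] && o_oa[i] == e_oa[i]) {
        action[i] <- "kept"
      } else if (o_ea[i] == e_oa[i] && o_oa[i] == e_ea[i]) {
        action[i] <- "flipped"
      } else if (oc_ea == e_ea[i] && oc_oa == e_oa[i]) {
        action[i] <- "kept"                       # strand flip only
      } else if (oc_ea == e_oa[i] && oc_oa == e_ea[i]) {
        action[i] <- "flipped"                    # strand flip + swap
      } else {
        action[i] <- "dropped_allele_mismatch"
        next
      }
      if (action[i] == "flipped") {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
    }
  }

  out <- tibble::tibble(
    snp = shared,
    chr = ex$chr,
    pos = ex$pos,
    effect_allele = e_ea,
    other_allele = e_oa,
    eaf_exp = ex$eaf,
    beta_exp = ex$beta,
    se_exp = ex$se,
    pval_exp = ex$pvalue,
    eaf_out = eaf_out,
    beta_out = beta_out,
    se_out = ou$se,
    pval_out = ou$pvalue,
    action = action
  )
  structure(out,
            exposure_name = trait_name(exposure),
            outcome_name = trait_name(outcome),
            palindromic_eaf_limit = palindromic_eaf_limit,
            class = c("harmonized_pair", class(tibble::tibble())))
}

#' Rows of a harmonized pair usable for estimation
#'
#' @param pair A `harmonized_pair`.
#' @param snps Optional SNP identifiers (e.g. an instrument set) to restrict to.
#' @return The subset of rows whose harmonization action is `kept`, `flipped`
#'   or `palindromic_kept`.
#' @export
kept_rows <- function(pair, snps = NULL) {
  stopifnot(inherits(pair, "harmonized_pair"))
  keep <- pair$action %in% c("kept", "flipped", "palindromic_kept")
  if (!is.null(snps)) {
    if (inherits(snps, "instrument_set")) snps <- snps$snp
    keep <- keep & pair$snp %in% snps
  }
  pair[keep, , drop = FALSE]
}

#' @export
print.harmonized_pair <- function(x, ...) {
  if ("action" %in% names(x)) {
    cat(sprintf("<harmonized_pair> '%s' -> '%s': %d shared SNPs (%d kept)\n",
                attr(x, "exposure_name") %||% "?", attr(x, "outcome_name") %||% "?",
                nrow(x), sum(x$action %in% c("kept", "flipped", "palindromic_kept"))))
  }
  NextMethod()
}
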