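#' Pipeline configuration
#'
#' Collects the thresholds and policies shared by the screening, mediation
#' and multivariable stages. Defaults follow common practice for
#' microbiome/metabolite MR: the suggestive threshold 1e-5 for 16S microbial
#' exposures (which rarely reach genome-wide significance), the conventional
#' 5e-8 for metabolites and for the disease outcome (used when instrumenting
#' it in reverse-direction analyses), minor-allele frequency > 0.01,
#' F >= 10, LD clumping at r² < 0.001 within 10 Mb, and method routing by
#' instrument count: one SNP uses the Wald ratio, two or more IVW, and three
#' or more add MR-Egger sensitivity statistics. Screening significance is the
#' raw IVW/Wald p-value below `screen_alpha`; Benjamini-Hochberg q-values
#' are reported alongside (see [annotate_multiplicity()]) without replacing
#' the raw-p decision.
#'
#' @param p_threshold_microbe,p_threshold_metabolite,p_threshold_outcome
#'   Instrument p-value thresholds per trait category.
#' @param eaf_min,f_min,clump_r2,clump_window_kb,palindromic_eaf_limit
#'   Filter settings passed through to [select_instruments()] and
#'   [harmonize()].
#' @param ivw_method `"random"` or `"fixed"`, see [mr_ivw()].
#' @param screen_alpha Nominal significance level for screening (default 0.05).
#' @param seed Seed recorded with the run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(p_threshold_microbe = 1e-5,
                            p_threshold_metabolite = 5e-8,
                            p_threshold_outcome = 5e-8,
                            eaf_min = 0.01, f_min = 10,
                            clump_r2 = 0.001, clump_window_kb = 10000,
                            palindromic_eaf_limit = 0.42,
                            ivw_method = c("random", "fixed"),
                            screen_alpha = 0.05, seed = 1L) {
  ivw_method <- match.arg(ivw_method)
  cfg <- list(
    p_threshold_microbe = p_threshold_microbe,
    p_threshold_metabolite = p_threshold_metabolite,
    p_threshold_outcome = p_threshold_outcome,
    eaf_min = eaf_min, f_min = f_min,
    clump_r2 = clump_r2, clump_window_kb = clump_window_kb,
    palindromic_eaf_limit = palindromic_eaf_limit,
    ivw_method = ivw_method, screen_alpha = screen_alpha,
    seed = as.integer(seed)
  )
  for (p in c(cfg$p_threshold_microbe, cfg$p_threshold_metabolite,
              cfg$p_threshold_outcome, cfg$screen_alpha)) {
    if (p <= 0 || p >= 1) stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files", call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    warning("ignoring unknown configuration key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals[intersect(names(vals), known)])
}

# one screened exposure-outcome pair: instruments -> harmonize -> routed method
#' @noRd
estimate_pair <- function(exposure, outcome, p_threshold, config, ld = NULL) {
  iv <- suppressMessages(suppressWarnings(
    select_instruments(exposure, p_threshold = p_threshold,
                       eaf_min = config$eaf_min, f_min = config$f_min,
                       ld = ld, clump_r2 = config$clump_r2,
                       clump_window_kb = config$clump_window_kb)
  ))
  log <- attr(iv, "selection_log")
  if (nrow(iv) == 0L) {
    return(list(est = NULL, egger = NULL, status = "no_instruments",
                n_instruments = 0L, log = log, median_f = NA_real_))
  }
  pair <- harmonize(exposure, outcome,
                    palindromic_eaf_limit = config$palindromic_eaf_limit)
  k <- kept_rows(pair, iv)
  j <- nrow(k)
  if (j == 0L) {
    return(list(est = NULL, egger = NULL, status = "no_harmonized_snps",
                n_instruments = nrow(iv), log = log, median_f = NA_real_))
  }
  median_f <- stats::median(iv$f_stat[iv$snp %in% k$snp])
  est <- if (j == 1L) {
    mr_wald_ratio(k$beta_exp, k$se_exp, k$beta_out, k$se_out,
                  exposure = trait_name(exposure), outcome = trait_name(outcome))
  } else {
    mr_ivw(pair, snps = iv, method = config$ivw_method)
  }
  # a failing sensitivity fit (e.g. a numerically singular Egger design)
  # must not void the primary estimate
  egger <- if (j >= 3L) {
    tryCatch(mr_egger(pair, snps = iv), error = function(e) NULL)
  } else NULL
  list(est = est, egger = egger, status = "ok", n_instruments = nrow(iv),
       log = log, median_f = median_f)
}

#' @noRd
na_screen_row <- function(exposure, outcome, status) {
  tibble::tibble(
    exposure = exposure, outcome = outcome, method = NA_character_,
    n_snp = NA_integer_, beta = NA_real_, se = NA_real_, pvalue = NA_real_,
    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    q_statistic = NA_real_, q_pvalue = NA_real_,
    egger_beta = NA_real_, egger_se = NA_real_, egger_pvalue = NA_real_,
    egger_intercept = NA_real_, egger_intercept_p = NA_real_,
    median_f = NA_real_, significant = NA, status = status
  )
}

#' Screen many exposures against one outcome
#'
#' Runs the univariable MR screen: for each exposure, instruments are
#' selected, harmonized against the outcome, and the method is routed by
#' instrument count (1 SNP: Wald ratio; >= 2: IVW; >= 3 adds MR-Egger
#' sensitivity columns). `direction = "reverse"` swaps the roles — the
#' outcome trait is instrumented (at `p_threshold_outcome`) and tested
#' against each listed trait — to probe reverse causation. Per-pair failures
#' (no instruments, no harmonizable SNPs) yield `NA` rows with a `status`
#' label and never abort the screen; the output always has one row per pair,
#' in deterministic order.
#'
#' @param exposures Named list of `summary_stats` (names default to trait
#'   names).
#' @param outcome A `summary_stats` object.
#' @param config A [pipeline_config()].
#' @param p_threshold Instrument threshold for the exposures; defaults to
#'   `config$p_threshold_microbe` forward and `config$p_threshold_outcome`
#'   in reverse.
#' @param ld Optional [ld_matrix()] shared by all exposures.
#' @param direction `"forward"` or `"reverse"`.
#' @return Tibble with one row per pair: estimate, OR/CI, Cochran's Q,
#'   MR-Egger sensitivity columns, median instrument F-statistic, the
#'   raw-p significance flag and a status column.
#' @export
run_screen <- function(exposures, outcome, config = pipeline_config(),
                       p_threshold = NULL, ld = NULL,
                       direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (inherits(exposures, "summary_stats")) exposures <- list(exposures)
  if (length(exposures) == 0L) {
    return(na_screen_row(character(0), character(0), character(0)))
  }
  if (is.null(names(exposures)) || any(!nzchar(names(exposures)))) {
    names(exposures) <- vapply(exposures, trait_name, character(1))
  }
  p_threshold <- p_threshold %||%
    if (direction == "forward") config$p_threshold_microbe else config$p_threshold_outcome

  rows <- lapply(names(exposures), function(nm) {
    ex <- exposures[[nm]]
    if (direction == "forward") {
      from <- ex; to <- outcome
      from_name <- nm; to_name <- trait_name(outcome)
    } else {
      from <- outcome; to <- ex
      from_name <- trait_name(outcome); to_name <- nm
    }
    res <- tryCatch(
      estimate_pair(from, to, p_threshold = p_threshold, config = config, ld = ld),
      error = function(e) list(est = NULL, egger = NULL, status = conditionMessage(e),
                               n_instruments = NA_integer_, log = NULL,
                               median_f = NA_real_)
    )
    if (is.null(res$est)) return(na_screen_row(from_name, to_name, res$status))
    e <- res$est
    g <- res$egger
    tibble::tibble(
      exposure = from_name, outcome = to_name, method = e$method,
      n_snp = e$n_snp, beta = e$beta, se = e$se, pvalue = e$pvalue,
      or = e$or, ci_low = e$ci_low, ci_high = e$ci_high,
      q_statistic = e$q_statistic, q_pvalue = e$q_pvalue,
      egger_beta = if (is.null(g)) NA_real_ else g$beta,
      egger_se = if (is.null(g)) NA_real_ else g$se,
      egger_pvalue = if (is.null(g)) NA_real_ else g$pvalue,
      egger_intercept = if (is.null(g)) NA_real_ else g$egger_intercept,
      egger_intercept_p = if (is.null(g)) NA_real_ else g$egger_intercept_p,
      median_f = res$median_f,
      significant = e$pvalue < config$screen_alpha,
      status = "ok"
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$exposure, out$outcome), , drop = FALSE]
}

#' Append Benjamini-Hochberg q-values to a screen report
#'
#' Adds a `q_value` column per screening family (e.g. all taxa screened
#' against the outcome form one family). The raw-p `significant` flag is left
#' untouched: q-values are reported for transparency, not used for the
#' primary decision.
#'
#' @param estimates A screen report from [run_screen()] (any data frame with
#'   a `pvalue` column).
#' @param family Optional grouping vector (one value per row); by default all
#'   rows form a single family.
#' @return `estimates` with a `q_value` column appended.
#' @export
annotate_multiplicity <- function(estimates, family = NULL) {
  stopifnot(is.data.frame(estimates), "pvalue" %in% names(estimates))
  if (nrow(estimates) == 0L) {
    estimates$q_value <- numeric(0)
    return(estimates)
  }
  family <- family %||% rep("all", nrow(estimates))
  q <- rep(NA_real_, nrow(estimates))
  for (f in unique(family)) {
    idx <- which(family == f)
    q[idx] <- stats::p.adjust(estimates$pvalue[idx], method = "BH")
  }
  estimates$q_value <- q
  estimates
}

#' Run one exposure -> mediator -> outcome mediation chain
#'
#' Composes the three univariable legs — total effect (exposure on outcome),
#' exposure on mediator, and mediator on outcome — each via instrument
#' selection, harmonization and count-routed estimation, then decomposes the
#' total effect with [two_step_mediation()]. The exposure legs use the
#' microbial instrument threshold and the mediator leg the metabolite
#' threshold from `config`. Reversing the roles of exposure and mediator
#' (metabolite-to-taxon chains) is the same call with arguments swapped and
#' appropriate thresholds.
#'
#' @param exposure,mediator,outcome `summary_stats` objects.
#' @param config A [pipeline_config()].
#' @param ld Optional [ld_matrix()].
#' @param exposure_threshold,mediator_threshold Override the per-category
#'   instrument thresholds.
#' @return A `mediation_result` (see [two_step_mediation()]); the three leg
#'   estimates, each with its heterogeneity and pleiotropy statistics where
#'   defined, are in the `components` attribute (`EO`, `EM`, `MO`, plus
#'   `EO_egger`, `EM_egger`, `MO_egger` when available).
#' @export
run_mediation_chain <- function(exposure, mediator, outcome,
                                config = pipeline_config(), ld = NULL,
                                exposure_threshold = NULL,
                                mediator_threshold = NULL) {
  exposure_threshold <- exposure_threshold %||% config$p_threshold_microbe
  mediator_threshold <- mediator_threshold %||% config$p_threshold_metabolite

  leg <- function(from, to, thr, label) {
    res <- estimate_pair(from, to, p_threshold = thr, config = config, ld = ld)
    if (is.null(res$est)) {
      stop(sprintf("mediation chain incomplete: %s leg ('%s' -> '%s'): %s",
                   label, trait_name(from), trait_name(to), res$status),
           call. = FALSE)
    }
    res
  }
  eo <- leg(exposure, outcome, exposure_threshold, "total-effect")
  em <- leg(exposure, mediator, exposure_threshold, "exposure-mediator")
  mo <- leg(mediator, outcome, mediator_threshold, "mediator-outcome")

  res <- two_step_mediation(eo$est, em$est, mo$est,
                            exposure = trait_name(exposure),
                            mediator = trait_name(mediator),
                            outcome = trait_name(outcome))
  attr(res, "components") <- list(
    EO = eo$est, EM = em$est, MO = mo$est,
    EO_egger = eo$egger, EM_egger = em$egger, MO_egger = mo$egger
  )
  res
}

#' Write a tidy report table to TSV
#'
#' Fixed column order (as produced), tab separation, 12-significant-digit
#' numerics; the standard output format of every pipeline stage.
#'
#' @param report A data frame (screen report, mediation result, coloc
#'   result, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mr_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  write_tsv_plain(as.data.frame(report), path)
}
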