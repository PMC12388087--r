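#' Configuration for the summary-statistics simulator
#'
#' Defines a known exposure -> mediator -> outcome causal model on GWAS
#' summary scale. The first `n_instruments` SNPs receive true exposure
#' effects `gamma_j ~ N(0, gamma_sd^2)`; the next `n_med_instruments` SNPs
#' receive mediator-specific effects `delta_j ~ N(0, delta_sd^2)` (these give
#' the mediator instruments of its own, independent of the exposure, that a
#' mediator-to-outcome analysis requires); remaining SNPs are null. True
#' per-SNP effects are then
#'
#' * exposure: `gamma_j`
#' * mediator: `beta_EM * gamma_j + delta_j + alpha_med_j`
#' * outcome (log-odds): `beta_direct * gamma_j + beta_MO * (mediator effect
#'   net of its pleiotropy) + beta_MO * delta_j + alpha_out_j`,
#'   i.e. `(beta_direct + beta_EM * beta_MO) * gamma_j + beta_MO * delta_j +
#'   alpha_out_j`
#'
#' Pleiotropy terms `alpha_j` model exclusion-restriction violations on the
#' exposure instruments: `none` (zero), `balanced` (`N(0, pleiotropy_sd^2)`)
#' or `directional` (`N(pleiotropy_mean, pleiotropy_sd^2)`).
#'
#' Default cohort sizes mirror large published consortium scales: 18,340 for
#' the 16S microbial exposure, 7,824 for the plasma-metabolite mediator, and
#' a 408,241-participant case-control outcome with 1,086 cases.
#'
#' @param seed Integer RNG seed; the simulator is deterministic given it.
#' @param n_snp Total SNPs simulated.
#' @param n_instruments SNPs with true exposure effects.
#' @param n_med_instruments SNPs with mediator-specific effects.
#' @param maf_range Uniform range for minor-allele frequencies, within (0, 0.5].
#' @param n_exp,n_med,n_out GWAS sample sizes per trait.
#' @param outcome_case_fraction Case fraction of the binary outcome.
#' @param gamma_sd,delta_sd SDs of the true instrument effects.
#' @param beta_EM_true,beta_MO_true,beta_direct_true Structural effects.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_sd,pleiotropy_mean Pleiotropy distribution parameters.
#' @param ld_block_size SNPs per LD block (1 = independent SNPs).
#' @param ld_within_block_r Correlation of sampling z-scores (and LD r)
#'   within a block, in `[0, 1)`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_snp = 200L, n_instruments = 20L,
                       n_med_instruments = 20L, maf_range = c(0.05, 0.5),
                       n_exp = 18340, n_med = 7824, n_out = 408241,
                       outcome_case_fraction = 1086 / 408241,
                       gamma_sd = 0.08, delta_sd = 0.2,
                       beta_EM_true = 0, beta_MO_true = 0, beta_direct_true = 0,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0, pleiotropy_mean = 0,
                       ld_block_size = 1L, ld_within_block_r = 0) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  cfg <- list(
    seed = as.integer(seed), n_snp = as.integer(n_snp),
    n_instruments = as.integer(n_instruments),
    n_med_instruments = as.integer(n_med_instruments),
    maf_range = as.numeric(maf_range),
    n_exp = n_exp, n_med = n_med, n_out = n_out,
    outcome_case_fraction = outcome_case_fraction,
    gamma_sd = gamma_sd, delta_sd = delta_sd,
    beta_EM_true = beta_EM_true, beta_MO_true = beta_MO_true,
    beta_direct_true = beta_direct_true,
    pleiotropy_mode = pleiotropy_mode,
    pleiotropy_sd = pleiotropy_sd, pleiotropy_mean = pleiotropy_mean,
    ld_block_size = as.integer(ld_block_size),
    ld_within_block_r = ld_within_block_r
  )
  if (cfg$n_snp < 1L) stop("`n_snp` must be positive", call. = FALSE)
  if (cfg$n_instruments + cfg$n_med_instruments > cfg$n_snp) {
    stop("instrument counts exceed `n_snp`", call. = FALSE)
  }
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("`maf_range` must lie within (0, 0.5]", call. = FALSE)
  }
  if (any(c(cfg$n_exp, cfg$n_med, cfg$n_out) <= 0)) {
    stop("sample sizes must be positive", call. = FALSE)
  }
  if (cfg$outcome_case_fraction <= 0 || cfg$outcome_case_fraction >= 1) {
    stop("`outcome_case_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (cfg$gamma_sd < 0 || cfg$delta_sd < 0 || cfg$pleiotropy_sd < 0) {
    stop("effect SDs must be non-negative", call. = FALSE)
  }
  if (cfg$ld_within_block_r < 0 || cfg$ld_within_block_r >= 1) {
    stop("`ld_within_block_r` must be in [0, 1)", call. = FALSE)
  }
  if (cfg$ld_block_size < 1L) stop("`ld_block_size` must be >= 1", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# correlated standard-normal sampling noise: equicorrelated within LD blocks
#' @noRd
block_noise <- function(block, r) {
  e <- stats::rnorm(length(block))
  if (r == 0) return(e)
  u <- stats::rnorm(length(unique(block)))
  sqrt(r) * u[match(block, unique(block))] + sqrt(1 - r) * e
}

#' Simulate GWAS summary statistics with known causal structure
#'
#' Generates exposure, mediator and outcome summary statistics under the
#' model of [sim_config()]. Per SNP, the sampling standard error is
#' `1/sqrt(2 p (1-p) n)` for the quantitative traits and
#' `1/sqrt(2 p (1-p) n phi (1-phi))` for the binary outcome on the log-odds
#' scale (`phi` the case fraction); observed betas are the true effects plus
#' `se * z` noise, with z-scores equicorrelated within LD blocks. Allele
#' labels are drawn at random (palindromic pairs included) and the mediator
#' and outcome records are emitted with randomly swapped allele orientation
#' and/or strand-complemented labels, with the truth of every flip recorded,
#' so harmonization can be validated against ground truth.
#'
#' @param config A [sim_config()].
#' @return List with elements `exposure`, `mediator`, `outcome`
#'   (`summary_stats`), `ld` ([ld_matrix()]) and `truth` (class `gwas_truth`:
#'   a `per_snp` tibble of true effects and orientations plus the structural
#'   effects, including the true total/indirect/direct effect and proportion
#'   mediated).
#' @export
simulate_gwas <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_snp
  snp <- sprintf("rs%06d", seq_len(n))

  block <- ceiling(seq_len(n) / config$ld_block_size)
  offset <- seq_len(n) - (block - 1L) * config$ld_block_size
  chr <- as.character(((block - 1L) %% 22L) + 1L)
  # blocks sharing a chromosome sit 20 Mb apart (beyond any clumping window);
  # the coordinate recycles after 100 rounds to stay within integer range,
  # which is safe because inter-block LD is zero by construction
  round_i <- ((ceiling(block / 22L) - 1L) %% 100L) + 1L
  pos <- as.integer(2e7 * round_i + 5000L * offset)

  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, n, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1L), character(1))

  is_instr <- seq_len(n) <= config$n_instruments
  is_med_instr <- seq_len(n) > config$n_instruments &
    seq_len(n) <= config$n_instruments + config$n_med_instruments
  # instrument effects oriented positive on the effect allele: a pure
  # labeling convention (the effect-allele choice is arbitrary), which makes
  # directional pleiotropy a well-defined quantity for MR-Egger to recover
  gamma <- ifelse(is_instr, abs(stats::rnorm(n, 0, config$gamma_sd)), 0)
  delta <- ifelse(is_med_instr, abs(stats::rnorm(n, 0, config$delta_sd)), 0)

  draw_pleio <- function() {
    switch(config$pleiotropy_mode,
           none = rep(0, n),
           balanced = ifelse(is_instr, stats::rnorm(n, 0, config$pleiotropy_sd), 0),
           directional = ifelse(is_instr,
                                stats::rnorm(n, config$pleiotropy_mean, config$pleiotropy_sd), 0))
  }
  alpha_med <- draw_pleio()
  alpha_out <- draw_pleio()

  true_exp <- gamma
  true_med <- config$beta_EM_true * gamma + delta + alpha_med
  true_out <- (config$beta_direct_true + config$beta_EM_true * config$beta_MO_true) * gamma +
    config$beta_MO_true * delta + alpha_out

  phi <- config$outcome_case_fraction
  se_exp <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exp)
  se_med <- 1 / sqrt(2 * maf * (1 - maf) * config$n_med)
  se_out <- 1 / sqrt(2 * maf * (1 - maf) * config$n_out * phi * (1 - phi))

  r <- config$ld_within_block_r
  obs_exp <- true_exp + se_exp * block_noise(block, r)
  obs_med <- true_med + se_med * block_noise(block, r)
  obs_out <- true_out + se_out * block_noise(block, r)

  make_df <- function(beta, se, n_sample) {
    data.frame(snp = snp, chr = chr, pos = pos,
               effect_allele = ea, other_allele = oa, eaf = maf,
               beta = beta, se = se, pvalue = z_pvalue(beta, se), n = n_sample,
               stringsAsFactors = FALSE)
  }

  # randomize allele orientation (swap) and strand labels for mediator/outcome
  scramble <- function(df) {
    flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
    strand <- sample(c(TRUE, FALSE), n, replace = TRUE)
    out <- df
    out$beta[flip] <- -out$beta[flip]
    out$eaf[flip] <- 1 - out$eaf[flip]
    tmp <- out$effect_allele[flip]
    out$effect_allele[flip] <- out$other_allele[flip]
    out$other_allele[flip] <- tmp
    out$effect_allele[strand] <- complement_allele(out$effect_allele[strand])
    out$other_allele[strand] <- complement_allele(out$other_allele[strand])
    list(df = out, flip = flip, strand = strand)
  }
  med_s <- scramble(make_df(obs_med, se_med, round(config$n_med)))
  out_s <- scramble(make_df(obs_out, se_out, round(config$n_out)))

  exposure <- summary_stats(make_df(obs_exp, se_exp, round(config$n_exp)),
                            trait_name = "exposure", trait_type = "quantitative",
                            check_p_consistency = FALSE)
  mediator <- summary_stats(med_s$df, trait_name = "mediator",
                            trait_type = "quantitative", check_p_consistency = FALSE)
  n_cases <- round(config$n_out * phi)
  outcome <- summary_stats(out_s$df, trait_name = "outcome", trait_type = "binary",
                           case_count = n_cases,
                           control_count = round(config$n_out) - n_cases,
                           check_p_consistency = FALSE)

  ld_r <- diag(n)
  if (config$ld_block_size > 1L && r > 0) {
    for (b in unique(block)) {
      idx <- which(block == b)
      ld_r[idx, idx] <- r
      diag(ld_r)[idx] <- 1
    }
  }
  # diag() assignment above only touches the full diagonal; restore exactly
  diag(ld_r) <- 1
  ld <- ld_matrix(ld_r, snp_ids = snp)

  total <- config$beta_direct_true + config$beta_EM_true * config$beta_MO_true
  indirect <- config$beta_EM_true * config$beta_MO_true
  truth <- structure(list(
    per_snp = tibble::tibble(
      snp = snp, maf = maf, block = block,
      is_instrument = is_instr, is_mediator_instrument = is_med_instr,
      gamma = gamma, delta = delta,
      alpha_mediator = alpha_med, alpha_outcome = alpha_out,
      true_beta_exposure = true_exp, true_beta_mediator = true_med,
      true_beta_outcome = true_out,
      se_exposure = se_exp, se_mediator = se_med, se_outcome = se_out,
      obs_beta_exposure = obs_exp, obs_beta_mediator = obs_med,
      obs_beta_outcome = obs_out,
      flipped_mediator = med_s$flip, strand_mediator = med_s$strand,
      flipped_outcome = out_s$flip, strand_outcome = out_s$strand
    ),
    beta_EM = config$beta_EM_true,
    beta_MO = config$beta_MO_true,
    beta_direct = config$beta_direct_true,
    total_effect = total,
    indirect_effect = indirect,
    proportion_mediated = if (total != 0) indirect / total else NA_real_
  ), class = "gwas_truth")

  list(exposure = exposure, mediator = mediator, outcome = outcome,
       ld = ld, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits the three summary-statistics TSVs, the LD matrix and a JSON ground
#' truth file into a directory.
#'
#' @param sim Result of [simulate_gwas()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_gwas <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_summary_stats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_summary_stats(sim$mediator, file.path(dir, "mediator.tsv"))
  write_summary_stats(sim$outcome, file.path(dir, "outcome.tsv"))
  write_ld_matrix(sim$ld, file.path(dir, "ld_matrix.txt"))
  truth <- sim$truth
  truth$per_snp <- as.data.frame(truth$per_snp)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
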