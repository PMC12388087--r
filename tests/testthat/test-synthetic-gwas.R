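test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(seed = 42, n_snp = 80, n_instruments = 20,
                    n_med_instruments = 10, beta_EM_true = 0.4,
                    beta_MO_true = 0.5, ld_block_size = 4,
                    ld_within_block_r = 0.5)
  s1 <- simulate_gwas(cfg)
  s2 <- simulate_gwas(cfg)
  expect_identical(as.data.frame(s1$exposure), as.data.frame(s2$exposure))
  expect_identical(as.data.frame(s1$outcome), as.data.frame(s2$outcome))
  expect_identical(unclass(s1$ld), unclass(s2$ld))
  expect_identical(s1$truth$per_snp, s2$truth$per_snp)

  s3 <- simulate_gwas(sim_config(seed = 43, n_snp = 80, n_instruments = 20,
                                 n_med_instruments = 10, beta_EM_true = 0.4,
                                 beta_MO_true = 0.5, ld_block_size = 4,
                                 ld_within_block_r = 0.5))
  expect_false(identical(s1$exposure$beta, s3$exposure$beta))
})

test_that("null configuration yields standard-normal z-scores", {
  sim <- simulate_gwas(sim_config(seed = 44, n_snp = 5000, n_instruments = 0,
                                  n_med_instruments = 0, gamma_sd = 0,
                                  delta_sd = 0))
  for (tr in list(sim$exposure, sim$mediator, sim$outcome)) {
    z <- tr$beta / tr$se
    # mean |z| for a standard normal is sqrt(2/pi); sd of the mean over
    # 5000 draws is sqrt(1 - 2/pi)/sqrt(5000) ~ 0.0085
    expect_equal(mean(abs(z)), sqrt(2 / pi), tolerance = 3 * 0.0085 / sqrt(2 / pi))
    expect_lt(abs(mean(z)), 4 / sqrt(5000))
  }
})

test_that("sampling standard errors follow the stated formulas exactly", {
  cfg <- sim_config(seed = 45, n_snp = 200, n_instruments = 20,
                    n_med_instruments = 20)
  sim <- simulate_gwas(cfg)
  truth <- sim$truth$per_snp
  maf <- truth$maf
  expect_equal(truth$se_exposure, 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exp),
               tolerance = 1e-12)
  expect_equal(truth$se_mediator, 1 / sqrt(2 * maf * (1 - maf) * cfg$n_med),
               tolerance = 1e-12)
  phi <- cfg$outcome_case_fraction
  expect_equal(truth$se_outcome,
               1 / sqrt(2 * maf * (1 - maf) * cfg$n_out * phi * (1 - phi)),
               tolerance = 1e-12)
  # and the emitted records carry them (in scrambled orientation, se unchanged)
  expect_equal(sort(sim$exposure$se), sort(truth$se_exposure), tolerance = 1e-12)
})

test_that("observed betas scatter around truth with the stated variance", {
  sim <- simulate_gwas(sim_config(seed = 46, n_snp = 5000, n_instruments = 1000,
                                  n_med_instruments = 1000, gamma_sd = 0.1,
                                  delta_sd = 0.1, beta_EM_true = 0.3,
                                  beta_MO_true = 0.4, beta_direct_true = 0.2))
  truth <- sim$truth$per_snp
  for (tr in c("exposure", "mediator", "outcome")) {
    z <- (truth[[paste0("obs_beta_", tr)]] - truth[[paste0("true_beta_", tr)]]) /
      truth[[paste0("se_", tr)]]
    # sum of squared standardized deviations ~ chi-square(5000)
    expect_gt(sum(z^2), qchisq(0.005, 5000))
    expect_lt(sum(z^2), qchisq(0.995, 5000))
  }
})

test_that("LD blocks induce the configured z-score correlation", {
  sim <- simulate_gwas(sim_config(seed = 47, n_snp = 4000, n_instruments = 0,
                                  n_med_instruments = 0, gamma_sd = 0,
                                  ld_block_size = 2, ld_within_block_r = 0.8))
  z <- sim$truth$per_snp$obs_beta_exposure / sim$truth$per_snp$se_exposure
  first <- z[seq(1, 4000, by = 2)]
  second <- z[seq(2, 4000, by = 2)]
  expect_equal(cor(first, second), 0.8, tolerance = 0.05)
  # and the LD matrix records it
  expect_equal(sim$ld[1, 2], 0.8)
  expect_equal(sim$ld[2, 3], 0)
})

test_that("a pure mediation chain yields proportion mediated near one", {
  sim <- simulate_gwas(sim_config(
    seed = 48, n_snp = 80, n_instruments = 30, n_med_instruments = 30,
    gamma_sd = 0.1, delta_sd = 0.1,
    n_exp = 1e6, n_med = 1e6, n_out = 2e6, outcome_case_fraction = 0.5,
    beta_direct_true = 0, beta_EM_true = 0.4, beta_MO_true = 0.5
  ))
  expect_equal(sim$truth$proportion_mediated, 1)
  res <- suppressMessages(run_mediation_chain(
    sim$exposure, sim$mediator, sim$outcome,
    config = pipeline_config(p_threshold_microbe = 1e-5,
                             p_threshold_metabolite = 5e-8)
  ))
  expect_equal(res$proportion_mediated, 1, tolerance = 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_snp = 10, n_instruments = 20), "exceed")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(outcome_case_fraction = 0), "case_fraction")
  expect_error(sim_config(ld_within_block_r = 1), "ld_within_block_r")
  expect_error(sim_config(gamma_sd = -1), "non-negative")
})

test_that("simulated datasets write to disk and read back", {
  sim <- simulate_gwas(sim_config(seed = 49, n_snp = 20, n_instruments = 5,
                                  n_med_instruments = 5))
  dir <- withr::local_tempdir()
  write_simulated_gwas(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("exposure.tsv", "mediator.tsv",
                                               "outcome.tsv", "ld_matrix.txt",
                                               "truth.json")))))
  ld <- read_ld_matrix(file.path(dir, "ld_matrix.txt"))
  expect_equal(dim(ld), c(20L, 20L))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$beta_EM, sim$truth$beta_EM)
})
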