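test_that("F-statistic arithmetic and input checks", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0, 0.5), 0)
  expect_equal(f_statistic(c(0.1, -0.1), c(0.02, 0.02)), c(25, 25))
  expect_error(f_statistic(0.1, 0), "positive")
})

test_that("observed F matches the analytic expectation n*2p(1-p)*gamma^2 + 1", {
  sim <- simulate_gwas(sim_config(seed = 21, n_snp = 3000, n_instruments = 3000,
                                  n_med_instruments = 0, gamma_sd = 0.08))
  truth <- sim$truth$per_snp
  f_obs <- f_statistic(sim$exposure$beta[match(truth$snp, sim$exposure$snp)],
                       sim$exposure$se[match(truth$snp, sim$exposure$snp)])
  f_expected <- 2 * truth$maf * (1 - truth$maf) * 18340 * truth$gamma^2 + 1
  expect_equal(mean(f_obs), mean(f_expected), tolerance = 0.05)
  expect_equal(median(f_obs), median(f_expected), tolerance = 0.1)
})

test_that("a fully correlated clump retains exactly the top SNP", {
  df <- snp_df(5, pos = 1000L + seq_len(5) * 100L,
               beta = c(0.10, 0.11, 0.12, 0.13, 0.14), se = 0.02)
  ss <- quick_stats(df)
  r <- matrix(0.95, 5, 5); diag(r) <- 1
  ld <- ld_matrix(r, snp_ids = df$snp)
  iv <- select_instruments(ss, p_threshold = 0.999, f_min = 0, ld = ld,
                           clump_r2 = 0.1)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$snp, "rs005")  # largest |z| = smallest p
  expect_equal(attr(iv, "selection_log")[["clumped"]], 4L)
})

test_that("an identity LD matrix clumps nothing", {
  df <- snp_df(6, beta = 0.2, se = 0.02)
  ss <- quick_stats(df)
  ld <- ld_matrix(diag(6), snp_ids = df$snp)
  iv <- select_instruments(ss, p_threshold = 0.999, f_min = 0, ld = ld)
  expect_equal(nrow(iv), 6L)
  expect_equal(attr(iv, "selection_log")[["clumped"]], 0L)
})

test_that("greedy clumping agrees with an independent pairwise oracle", {
  sim <- simulate_gwas(sim_config(seed = 23, n_snp = 200, n_instruments = 200,
                                  n_med_instruments = 0, gamma_sd = 0.06,
                                  ld_block_size = 10, ld_within_block_r = 0.9))
  ss <- sim$exposure
  ld <- sim$ld
  clump_r2 <- 0.5
  window_kb <- 10000
  iv <- select_instruments(ss, p_threshold = 0.999, eaf_min = 0, f_min = 0,
                           ld = ld, clump_r2 = clump_r2,
                           clump_window_kb = window_kb)

  # oracle: walk SNPs in (p, snp) order, keep unless an already-kept SNP on
  # the same chromosome within the window has r^2 >= threshold
  df <- as.data.frame(ss)[order(ss$pvalue, ss$snp), ]
  kept <- character(0)
  for (i in seq_len(nrow(df))) {
    s <- df$snp[i]
    conflict <- FALSE
    for (k in kept) {
      same_chr <- df$chr[match(k, df$snp)] == df$chr[i]
      close <- abs(df$pos[match(k, df$snp)] - df$pos[i]) <= window_kb * 1000
      if (same_chr && close && ld[s, k]^2 >= clump_r2) { conflict <- TRUE; break }
    }
    if (!conflict) kept <- c(kept, s)
  }
  expect_setequal(iv$snp, kept)

  # every retained pair within the window is below the r^2 threshold
  for (a in seq_len(nrow(iv))) {
    for (b in seq_len(nrow(iv))) {
      if (a >= b) next
      if (iv$chr[a] == iv$chr[b] && abs(iv$pos[a] - iv$pos[b]) <= window_kb * 1000) {
        expect_lt(ld[iv$snp[a], iv$snp[b]]^2, clump_r2)
      }
    }
  }
})

test_that("selection is invariant to input row order and monotone in p", {
  sim <- simulate_gwas(sim_config(seed = 24, n_snp = 100, n_instruments = 40,
                                  n_med_instruments = 0, gamma_sd = 0.05,
                                  ld_block_size = 5, ld_within_block_r = 0.8))
  df <- as.data.frame(sim$exposure)
  shuffled <- quick_stats(df[sample(nrow(df)), ], name = "exposure")
  iv1 <- select_instruments(sim$exposure, p_threshold = 1e-3, f_min = 0,
                            ld = sim$ld)
  iv2 <- select_instruments(shuffled, p_threshold = 1e-3, f_min = 0,
                            ld = sim$ld)
  expect_identical(iv1$snp, iv2$snp)

  iv_strict <- select_instruments(sim$exposure, p_threshold = 1e-6, f_min = 0,
                                  ld = sim$ld)
  expect_lte(nrow(iv_strict), nrow(iv1))
})

test_that("filters are staged and logged; empty survivors warn", {
  df <- snp_df(4, beta = c(0.5, 0.5, 0.06, 0.5), se = c(0.02, 0.02, 0.02, 0.02),
               eaf = c(0.3, 0.005, 0.3, 0.3))
  df$pvalue[4] <- 0.5
  ss <- quick_stats(df)
  iv <- select_instruments(ss, p_threshold = 0.01, eaf_min = 0.01, f_min = 10)
  log <- attr(iv, "selection_log")
  expect_equal(log[["below_p"]], 1L)   # the p = 0.5 SNP
  expect_equal(log[["low_eaf"]], 1L)   # eaf 0.005
  expect_equal(log[["low_f"]], 1L)     # z = 3: p = 0.0027 passes, F = 9 fails
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$snp, "rs001")

  expect_warning(
    empty <- select_instruments(quick_stats(snp_df(2, beta = 0.001, se = 0.02))),
    "no instruments"
  )
  expect_equal(nrow(empty), 0L)
})

test_that("SNPs missing from the LD matrix are treated as independent", {
  df <- snp_df(3, pos = c(1000L, 1100L, 1200L), beta = c(0.12, 0.11, 0.10),
               se = 0.02)
  ss <- quick_stats(df)
  r <- matrix(0.99, 2, 2); diag(r) <- 1
  ld <- ld_matrix(r, snp_ids = c("rs001", "rs002"))
  expect_warning(
    iv <- select_instruments(ss, p_threshold = 0.999, f_min = 0, ld = ld,
                             clump_r2 = 0.1),
    "absent"
  )
  expect_setequal(iv$snp, c("rs001", "rs003"))  # rs002 clumped with rs001
})

test_that("LD matrix text files round trip", {
  r <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  ld <- ld_matrix(r, snp_ids = c("rs1", "rs2"))
  f <- withr::local_tempfile(fileext = ".txt")
  write_ld_matrix(ld, f)
  back <- read_ld_matrix(f)
  expect_equal(unclass(back), unclass(ld), tolerance = 1e-9)
  expect_error(ld_matrix(matrix(c(1, 0.2, 0.5, 1), 2, 2), c("a", "b")), "symmetric")
})
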