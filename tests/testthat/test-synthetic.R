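test_that("group covariances are tiered correlation matrices", {
  cfg <- cohort_config(coupling_boost = 0, within_block_rho = 0.5,
                       homotopic_rho = 0.5, between_block_rho = 0.1,
                       n_roi = 26L)
  R_c <- make_group_covariance(cfg, "carrier")
  R_n <- make_group_covariance(cfg, "noncarrier")
  expect_identical(R_c, R_n)                       # boost 0: null case
  expect_equal(unname(diag(R_n)), rep(1, 26))
  # with homotopic tied to within, off-diagonals take exactly two values
  offd <- R_n[upper.tri(R_n)]
  expect_equal(sort(unique(round(offd, 12))), c(0.1, 0.5))
  # PSD by construction
  ev <- eigen(R_n, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)

  # boosted carrier raises exactly the homotopic pairs
  cfg2 <- cohort_config(coupling_boost = 0.2)
  R2c <- make_group_covariance(cfg2, "carrier")
  R2n <- make_group_covariance(cfg2, "noncarrier")
  delta <- R2c - R2n
  hom <- cbind(seq(1, 25, by = 2), seq(2, 26, by = 2))
  expect_equal(unname(delta[hom]), rep(0.2, 13))
  delta[hom] <- 0
  delta[hom[, 2:1]] <- 0
  expect_equal(max(abs(delta)), 0)
})

test_that("extreme parameters still give positive semi-definite matrices", {
  cfg <- cohort_config(within_block_rho = 0.9, homotopic_rho = 0.95,
                       between_block_rho = 0, coupling_boost = 0.3)
  for (g in c("carrier", "noncarrier")) {
    for (sc in c(0.5, 1, 2)) {
      R <- make_group_covariance(cfg, g, within_shift = 0.05,
                                 between_shift = -0.3, scale = sc)
      ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-10)
      expect_true(all(abs(R) <= 1 + 1e-12))
    }
  }
})

test_that("simulated series reproduce the target correlations at large K", {
  cfg <- cohort_config(n_roi = 8L, coupling_boost = 0)
  R <- make_group_covariance(cfg, "noncarrier")
  ts <- simulate_subject(R, n_timepoints = 50000, seed = 21)
  r_hat <- stats::cor(t(ts))
  expect_lt(max(abs(r_hat - R)), 0.02)

  # independent signals: sample correlations stay inside the null envelope
  K <- 2000
  ts0 <- simulate_subject(diag(8), n_timepoints = K, seed = 22)
  r0 <- stats::cor(t(ts0))
  expect_lt(mean(abs(r0[upper.tri(r0)])), 2 * 1.96 / sqrt(K))

  # noise_sd scales amplitude, not correlation
  ts2 <- simulate_subject(R, n_timepoints = 500, noise_sd = 5, seed = 23)
  expect_equal(stats::sd(as.vector(ts2)) / 5, 1, tolerance = 0.1)

  # determinism
  expect_identical(simulate_subject(R, 100, seed = 9),
                   simulate_subject(R, 100, seed = 9))
})

test_that("AR(1) signals keep the cross-ROI correlation target", {
  cfg <- cohort_config(n_roi = 6L, coupling_boost = 0, ar1 = 0.4)
  R <- make_group_covariance(cfg, "noncarrier")
  ts <- simulate_subject(R, n_timepoints = 30000, seed = 33, ar1 = 0.4)
  expect_lt(max(abs(stats::cor(t(ts)) - R)), 0.03)
  # and the lag-1 autocorrelation is near the requested coefficient
  ac <- mean(apply(ts, 1, function(x) stats::acf(x, plot = FALSE)$acf[2]))
  expect_equal(ac, 0.4, tolerance = 0.05)
})

test_that("default cohorts have the study dimensions and planted direction", {
  cfg <- cohort_config(n_timepoints = 2000L, seed = 5L)
  coh <- simulate_cohort(cfg)
  groups <- vapply(coh$subjects, `[[`, character(1), "group")
  expect_equal(sum(groups == "carrier"), 27L)
  expect_equal(sum(groups == "noncarrier"), 31L)
  expect_equal(dim(coh$subjects[[1]]$values), c(26L, 2000L))
  expect_equal(rownames(coh$subjects[[1]]$values),
               dmn_atlas()$abbreviation)
  ids <- vapply(coh$subjects, `[[`, character(1), "subject_id")
  expect_false(anyDuplicated(ids) > 0L)

  # carrier group-mean weights are smaller on the boosted (homotopic) pairs
  mean_net <- function(g) {
    group_mean_network(lapply(coh$subjects[groups == g],
                              function(s) build_network(s$values, "both")))
  }
  Wc <- mean_net("carrier")
  Wn <- mean_net("noncarrier")
  hom <- cbind(seq(1, 25, by = 2), seq(2, 26, by = 2))
  expect_true(all(Wc[hom] < Wn[hom]))
})

test_that("cohort simulation is deterministic and round-trips through files", {
  cfg <- tiny_config()
  coh1 <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh1, coh2)

  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh1, dir)
  expect_true(file.exists(manifest))
  back <- read_cohort(manifest)
  expect_equal(length(back$subjects), 6L)
  for (i in seq_along(back$subjects)) {
    expect_identical(back$subjects[[i]]$subject_id,
                     coh1$subjects[[i]]$subject_id)
    expect_identical(back$subjects[[i]]$group, coh1$subjects[[i]]$group)
    expect_equal(back$subjects[[i]]$values, coh1$subjects[[i]]$values,
                 tolerance = 1e-12)
  }

  # rewriting produces byte-identical files
  dir2 <- withr::local_tempdir()
  write_cohort(coh2, dir2)
  f1 <- list.files(dir, full.names = TRUE)
  f2 <- list.files(dir2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (k in seq_along(f1)) {
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  }
})

test_that("a null configuration yields exchangeable groups", {
  set.seed(881)
  pvals <- numeric(40)
  for (i in seq_len(40)) {
    cfg <- cohort_config(n_carrier = 5L, n_noncarrier = 5L, n_roi = 10L,
                         n_timepoints = 60L, coupling_boost = 0,
                         seed = 7000L + i)
    coh <- simulate_cohort(cfg)
    ft <- feature_table(coh, scopes = "both", n_restarts = 2L)
    pvals[i] <- permutation_test(ft$cpl[ft$group == "carrier"],
                                 ft$cpl[ft$group == "noncarrier"],
                                 n_perm = 99)$p_value
  }
  # no pile-up of small p-values under the null
  expect_lt(mean(pvals <= 0.05), 0.25)
  expect_gt(mean(pvals), 0.3)
})
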