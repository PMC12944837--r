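point_ep <- function(AA = 1.54, ABS = 0.01, BW = 55) {
  list(AA = AA, ABS = ABS, BW = BW)
}
point_tox <- list(rfd_abs = 3e-4, csf = 32)

test_that("lognormal MLE uses log-scale mean and population sd", {
  f <- fit_lognormal(c(1, 1, 1))
  expect_equal(f$mu, 0)
  expect_equal(f$sigma, 0)
  expect_equal(f$n_fitted, 3)

  f2 <- fit_lognormal(c(exp(1), exp(3)))
  expect_equal(f2$mu, 2)
  expect_equal(f2$sigma, 1)  # population (divide-by-n) sd of {1, 3}

  expect_error(fit_lognormal(5), "at least 2")
  expect_error(fit_lognormal(c(1, -2)), "positive")

  withr::with_seed(61, x <- stats::rlnorm(5000, 1, 2))
  f3 <- fit_lognormal(x)
  expect_lt(abs(f3$mu - 1), 3 * 2 / sqrt(5000))
  expect_lt(abs(f3$sigma - 2), 3 * 2 / sqrt(2 * 5000))
})

test_that("degenerate variability and uncertainty collapse to a point dose", {
  vm <- fit_lognormal(c(2, 2))
  res <- run_mc2d(vm, body_weight_model(55, 0), point_ep(), point_tox,
                  mc2d_config(n_var = 50, n_unc = 10, seed = 1))
  expected <- compute_sed(2, 1.54, 0.01, 55)
  expect_true(all(abs(res$sed_grid - expected) < 1e-15))
  expect_equal(unname(res$sed_summary["p50"]), expected)
  expect_equal(unname(res$sed_summary["p95"]), expected)
  expect_equal(unname(res$sed_summary["max"]), expected)
})

test_that("the simulation grid is reproducible and correctly shaped", {
  vm <- fit_lognormal(c(1, 5, 20))
  cfg <- mc2d_config(n_var = 300, n_unc = 40, seed = 7)
  r1 <- run_mc2d(vm, body_weight_model(), point_ep(), point_tox, cfg)
  r2 <- run_mc2d(vm, body_weight_model(), point_ep(), point_tox, cfg)
  expect_identical(r1$sed_grid, r2$sed_grid)
  expect_equal(dim(r1$sed_grid), c(300, 40))
  # summary ordering invariant
  expect_lte(r1$sed_summary[["p50"]], r1$sed_summary[["p95"]])
  expect_lte(r1$sed_summary[["p95"]], r1$sed_summary[["max"]])
  # exact monotone-map equivariance of the summaries
  expect_identical(r1$hq_summary, r1$sed_summary / point_tox$rfd_abs)
  expect_identical(r1$lcr_summary, r1$sed_summary * point_tox$csf)
})

test_that("with no uncertainty the 2-D engine matches a 1-D brute-force stream", {
  vm <- structure(list(metal = "Hg", mu = log(5), sigma = 1, n_fitted = 10),
                  class = "lognormal_model")
  cfg <- mc2d_config(n_var = 5000, n_unc = 20, seed = 11)
  ep <- point_ep()
  res <- run_mc2d(vm, body_weight_model(55, 0), ep, point_tox, cfg)

  # independent 1-D oracle drawing the same concentration stream
  sed_1d <- withr::with_seed(11, {
    compute_sed(stats::rlnorm(5000, log(5), 1), ep$AA, ep$ABS, 55)
  })
  for (u in c(1, 7, 20)) {
    expect_equal(res$sed_grid[, u], sed_1d, tolerance = 1e-14)
  }

  # closed-form lognormal quantiles within 3 asymptotic SE
  scale_f <- ep$AA * ep$ABS * 1e-3 / 55
  for (p in c(0.5, 0.95)) {
    q_true <- exp(log(5) + stats::qnorm(p) * 1) * scale_f
    dens <- stats::dlnorm(q_true / scale_f, log(5), 1) / scale_f
    se <- sqrt(p * (1 - p) / 5000) / dens
    q_hat <- unname(res$sed_summary[[paste0("p", p * 100)]])
    expect_lt(abs(q_hat - q_true), 3 * se)
  }
})

test_that("HQ exceedance probability covers the degenerate and median cases", {
  vm0 <- fit_lognormal(c(2, 2))
  ep <- point_ep()
  low <- run_mc2d(vm0, body_weight_model(55, 0), ep,
                  list(rfd_abs = 1, csf = NA), mc2d_config(10, 5, 1))
  expect_equal(exceedance_probability(low), 0)

  # point mass at HQ = 2
  sed_point <- compute_sed(2, ep$AA, ep$ABS, 55)
  high <- run_mc2d(vm0, body_weight_model(55, 0), ep,
                   list(rfd_abs = sed_point / 2, csf = NA),
                   mc2d_config(10, 5, 1))
  expect_equal(exceedance_probability(high), 1)

  # RfD at the SED median: exceedance probability near 1/2
  vm <- structure(list(metal = "Hg", mu = 0, sigma = 1.5, n_fitted = 10),
                  class = "lognormal_model")
  med_sed <- exp(0) * ep$AA * ep$ABS * 1e-3 / 55
  res <- run_mc2d(vm, body_weight_model(55, 0), ep,
                  list(rfd_abs = med_sed, csf = NA),
                  mc2d_config(5000, 1, 13))
  expect_lt(abs(exceedance_probability(res) - 0.5), 3 * sqrt(0.25 / 5000))
})

test_that("uncertainty bands widen with body-weight spread and cover the pooled median", {
  vm <- structure(list(metal = "Ni", mu = log(2), sigma = 0.8, n_fitted = 20),
                  class = "lognormal_model")
  cfg <- mc2d_config(n_var = 1000, n_unc = 50, seed = 17)
  r0 <- run_mc2d(vm, body_weight_model(55, 0), point_ep(), point_tox, cfg)
  b0 <- summarize_by_uncertainty(r0)
  expect_true(all(b0$band_width == 0))

  r5 <- run_mc2d(vm, body_weight_model(55, 5), point_ep(), point_tox, cfg)
  r10 <- run_mc2d(vm, body_weight_model(55, 10), point_ep(), point_tox, cfg)
  b5 <- summarize_by_uncertainty(r5)
  b10 <- summarize_by_uncertainty(r10)
  expect_true(all(b10$band_width > b5$band_width))
  expect_true(all(b5$band_width > 0))

  # pooled p50 lies within the column-wise p50 band
  pooled_p50 <- unname(r5$sed_summary[["p50"]])
  expect_gte(pooled_p50, b5$lower[b5$percentile == 50])
  expect_lte(pooled_p50, b5$upper[b5$percentile == 50])
})

test_that("risk_report gates metals, skips sparse ones and stays equivariant", {
  ds <- generate_survey(asia7_config(seed = 3))
  cfg <- mc2d_config(n_var = 500, n_unc = 20, seed = 3)
  rep_fc <- risk_report(ds, "facial_cream", cfg = cfg)

  expect_true("Hg" %in% rep_fc$metal)
  skipped <- attr(rep_fc, "skipped")
  expect_true(all(c("metal", "reason") %in% names(skipped)))

  # LCR columns equal SED columns times CSF exactly
  reg <- tox_registry()
  for (m in rep_fc$metal) {
    csf <- reg$csf[reg$metal == m]
    row <- rep_fc[rep_fc$metal == m, ]
    if (is.na(csf)) {
      expect_true(is.na(row$lcr_p50))
    } else {
      expect_identical(row$lcr_p50, row$sed_p50 * csf)
      expect_identical(row$lcr_p95, row$sed_p95 * csf)
      expect_identical(row$lcr_max, row$sed_max * csf)
    }
  }

  # heavy-tailed planted Hg mixture: upper tail far above the median
  hg <- rep_fc[rep_fc$metal == "Hg", ]
  expect_gt(hg$p_hq_gt_1, 0)
  expect_gt(hg$hq_p95 / hg$hq_p50, 10)

  # all-clean low-concentration scenario: no flags anywhere
  clean_cfg <- uncensored_config(n = 60, seed = 19)
  clean_cfg$geogenic$face$log_mean <- c(As = log(0.001), Cr = log(0.001),
                                        Ni = log(0.001))
  clean_cfg$geogenic$eye <- clean_cfg$geogenic$face
  clean_cfg$adulteration$clean_log_mean <- log(0.001)
  clean <- generate_survey(clean_cfg)
  rep_clean <- risk_report(clean, "facial_cream", cfg = cfg)
  expect_true(all(rep_clean$hq_p95 < 1))
  expect_true(all(rep_clean$lcr_max < 1e-6, na.rm = TRUE))
})
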