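# helper: minimal model object for retention-rule fixtures
eigen_fixture <- function(vals) {
  structure(list(eigenvalues = vals), class = "pca_model")
}

test_that("prepare_matrix logs, imputes and standardizes", {
  ds <- as_survey(dplyr::bind_rows(
    survey_rows(c(1, 2, 4, NA), metal = "Cr", lod = 1.0),
    survey_rows(c(2, 3, 5, 8), metal = "Ni", lod = 1.0)
  ))
  x <- prepare_matrix(ds, c("Cr", "Ni"), check_gate = FALSE)
  expect_equal(dim(x$matrix), c(4, 2))
  # the censored cell enters as log(LOD/sqrt(2)) before standardization
  expect_equal(unname(x$log_matrix[4, "Cr"]), log(1 / sqrt(2)))
  expect_equal(unname(colMeans(x$matrix)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(x$matrix, 2, stats::sd)), c(1, 1),
               tolerance = 1e-12)
})

test_that("prepare_matrix enforces the gate and rejects degenerate columns", {
  ds <- as_survey(dplyr::bind_rows(
    survey_rows(c(3, 3, 3), metal = "Cr", lod = 1.0),
    survey_rows(c(2, 3, 5), metal = "Ni", lod = 1.0)
  ))
  expect_error(prepare_matrix(ds, c("Cr", "Ni"), check_gate = FALSE),
               "zero-variance column for metal Cr")

  gated <- as_survey(dplyr::bind_rows(
    survey_rows(c(NA, NA, NA, 2), metal = "As", lod = 1.0),
    survey_rows(c(2, 3, 5, 7), metal = "Ni", lod = 1.0)
  ))
  expect_error(prepare_matrix(gated, c("As", "Ni")),
               "below the detection-rate gate: As")
})

test_that("correlation PCA has unit trace and reconstructs the correlation matrix", {
  cfg <- uncensored_config(n = 300, rho = 0.5, seed = 31)
  ds <- generate_survey(cfg)
  x <- prepare_matrix(ds, c("Hg", "As", "Cr", "Ni"))
  fit <- fit_pca(x)
  expect_equal(sum(fit$eigenvalues), 4, tolerance = 1e-10)
  expect_equal(sum(fit$variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_true(all(diff(fit$cumulative_variance) >= -1e-12))
  # full reconstruction of the correlation matrix
  r <- stats::cor(x$log_matrix)
  expect_lt(max(abs(fit$factor_loadings %*% t(fit$factor_loadings) - r)),
            1e-8)
  # eigenvector columns orthonormal
  expect_lt(max(abs(crossprod(fit$loadings) - diag(4))), 1e-10)
  # deterministic sign convention: dominant loading positive
  for (j in 1:4) {
    expect_gte(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
  }
})

test_that("degenerate correlation structures give the textbook eigenvalues", {
  # two perfectly correlated metals: eigenvalues {2, 0}
  ds <- as_survey(dplyr::bind_rows(
    survey_rows(c(1, 2, 4, 8), metal = "Cr", lod = 0.1),
    survey_rows(c(2, 4, 8, 16), metal = "Ni", lod = 0.1)
  ))
  fit <- fit_pca(prepare_matrix(ds, c("Cr", "Ni"), check_gate = FALSE))
  expect_equal(fit$eigenvalues, c(2, 0), tolerance = 1e-10)

  # independent standardized columns: eigenvalues near 1
  cfg <- uncensored_config(n = 2000, rho = 0, seed = 37)
  ds2 <- generate_survey(cfg)
  fit2 <- fit_pca(prepare_matrix(ds2, c("Hg", "As", "Cr", "Ni")))
  expect_true(all(abs(fit2$eigenvalues - 1) < 0.15))
})

test_that("retention rule applies the eigenvalue and cumulative-variance criteria", {
  expect_equal(retain_components(eigen_fixture(c(2.5, 1.2, 0.3))), 2)
  expect_equal(retain_components(eigen_fixture(c(3.0, 0.97, 0.03))), 1)
  # the near-one slack admits a 0.96 component to reach 71.5% cumulative
  expect_equal(retain_components(eigen_fixture(c(1.9, 0.96, 0.9, 0.24))), 2)
  # k is at least 1 even when nothing passes the eigenvalue cut
  expect_equal(retain_components(eigen_fixture(c(0.6, 0.25, 0.15))), 1)
})

test_that("varimax rotation preserves communalities and maximizes the criterion", {
  cfg <- uncensored_config(n = 200, rho = 0.6, seed = 41)
  fit <- fit_pca(prepare_matrix(generate_survey(cfg),
                                c("Hg", "As", "Cr", "Ni")))
  L <- fit$factor_loadings
  rot <- varimax_rotate(L, 2)

  # k = 1 is a no-op
  r1 <- varimax_rotate(L, 1)
  expect_equal(r1$loadings, L[, 1, drop = FALSE])

  # per-metal communalities identical before and after rotation
  expect_lt(max(abs(rowSums(rot$loadings^2) - rowSums(L[, 1:2]^2))), 1e-8)
  # the rotation matrix is orthogonal
  expect_lt(max(abs(crossprod(rot$rotmat) - diag(2))), 1e-10)
  # criterion does not decrease
  expect_gte(rot$criterion, cosmetrisk:::varimax_criterion(L[, 1:2]) - 1e-12)

  # brute-force oracle: grid over the single rotation angle for k = 2
  h <- sqrt(rowSums(L[, 1:2]^2))
  W <- L[, 1:2] / h
  grid_best <- max(vapply(seq(0, pi / 2, length.out = 20001), function(th) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    cosmetrisk:::varimax_criterion(W %*% R)
  }, numeric(1)))
  expect_gte(rot$criterion + 1e-8, grid_best)
})

test_that("varimax agrees with the reference implementation up to sign and order", {
  cfg <- uncensored_config(n = 150, rho = 0.6, seed = 43)
  fit <- fit_pca(prepare_matrix(generate_survey(cfg),
                                c("Hg", "As", "Cr", "Ni")))
  L <- fit$factor_loadings[, 1:2]
  mine <- varimax_rotate(L, 2)
  ref <- unclass(stats::varimax(L, normalize = TRUE)$loadings)
  # align reference columns/signs to ours before comparing
  perms <- list(c(1, 2), c(2, 1))
  best <- Inf
  for (p in perms) for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
    cand <- ref[, p] %*% diag(c(s1, s2))
    best <- min(best, max(abs(cand - mine$loadings)))
  }
  expect_lt(best, 0.05)
  # and our optimum is at least as good as the reference's
  h <- sqrt(rowSums(L^2))
  ref_crit <- cosmetrisk:::varimax_criterion(ref / h)
  expect_gte(mine$criterion, ref_crit - 1e-6)
})

test_that("rotation recovers the planted Hg-separable structure", {
  cfg <- uncensored_config(n = 150, rho = 0.6, seed = 47)
  x <- prepare_matrix(generate_survey(cfg), c("Hg", "As", "Cr", "Ni"))
  fit <- fit_pca(x)
  k <- retain_components(fit)
  expect_equal(k, 2)
  rot <- varimax_rotate(fit$factor_loadings, k)
  hg_comp <- which.max(abs(rot$loadings["Hg", ]))
  expect_gt(abs(rot$loadings["Hg", hg_comp]), 0.8)
  expect_lt(max(abs(rot$loadings[c("As", "Cr", "Ni"), hg_comp])), 0.3)

  # biplot geometry: Hg vector nearly orthogonal to the geogenic centroid
  bp <- biplot_data(fit, x)
  hg_vec <- unlist(bp$vectors[bp$vectors$metal == "Hg", c("PC1", "PC2")])
  cent <- colMeans(bp$vectors[bp$vectors$metal != "Hg", c("PC1", "PC2")])
  ang <- acos(sum(hg_vec * cent) /
                sqrt(sum(hg_vec^2) * sum(cent^2))) * 180 / pi
  expect_gt(ang, 60)
  expect_equal(unname(colMeans(as.matrix(bp$scores[, c("PC1", "PC2")]))),
               c(0, 0), tolerance = 1e-10)
})

test_that("biplot data requires two components and is deterministic", {
  degenerate <- structure(list(eigenvalues = 1), class = "pca_model")
  expect_error(biplot_data(degenerate), "at least 2 components")

  cfg <- uncensored_config(n = 50, seed = 53)
  x <- prepare_matrix(generate_survey(cfg), c("Hg", "As", "Cr", "Ni"))
  expect_identical(biplot_data(fit_pca(x), x), biplot_data(fit_pca(x), x))
})
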