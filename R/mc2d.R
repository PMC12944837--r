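# Two-dimensional Monte Carlo engine.
#
# Concentration variability (lognormal, fitted by MLE to detected values
# only) is crossed with body-weight uncertainty (truncated normal): one
# concentration draw per variability iteration, one body-weight draw per
# uncertainty iteration, and sed_grid[v, u] = SED(C_v, AA, ABS, BW_u).
# All remaining parameters (AA, ABS, RfD_ABS, CSF) are point estimates.
# HQ and LCR summaries are obtained from the SED summaries by the exact
# monotone maps HQ = SED / RfD_ABS and LCR = SED * CSF.

#' Fit a lognormal variability model to detected concentrations
#'
#' Maximum likelihood on the log scale: `mu` is the mean of logs and
#' `sigma` the population (divide-by-n) standard deviation of logs.
#'
#' @param detected Numeric vector of detected concentrations (mg/kg); at
#'   least 2 positive values.
#' @param metal Optional metal symbol tag.
#' @return Object of class `lognormal_model` with `mu`, `sigma`,
#'   `n_fitted`, `metal`.
#' @export
fit_lognormal <- function(detected, metal = NA_character_) {
  if (length(detected) < 2) {
    stop("need at least 2 detected values", call. = FALSE)
  }
  if (any(!is.finite(detected)) || any(detected <= 0)) {
    stop("detected concentrations must be positive and finite",
         call. = FALSE)
  }
  lx <- log(detected)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  structure(list(metal = metal, mu = mu, sigma = sigma,
                 n_fitted = length(detected)),
            class = "lognormal_model")
}

#' Simulation configuration for the two-dimensional engine
#'
#' @param n_var Variability iterations (concentration draws); default 5000.
#' @param n_unc Uncertainty iterations (body-weight draws); default 200.
#' @param seed Integer seed.
#' @param percentiles Percentiles to report (default 50 and 95).
#' @return Object of class `mc2d_config`.
#' @export
mc2d_config <- function(n_var = 5000L, n_unc = 200L, seed = 1L,
                        percentiles = c(50, 95)) {
  stopifnot(n_var >= 1, n_unc >= 1,
            all(percentiles > 0), all(percentiles < 100))
  structure(list(n_var = as.integer(n_var), n_unc = as.integer(n_unc),
                 seed = as.integer(seed), percentiles = percentiles),
            class = "mc2d_config")
}

#' @keywords internal
grid_summary <- function(x, percentiles) {
  q <- stats::quantile(x, percentiles / 100, names = FALSE, type = 7)
  stats::setNames(c(q, max(x)), c(paste0("p", percentiles), "max"))
}

#' Run the two-dimensional Monte Carlo simulation
#'
#' Draw order is fixed for reproducibility and oracle equivalence: the
#' `n_var` concentration draws are taken first, then the `n_unc`
#' body-weight draws. Percentile summaries use linear interpolation
#' (quantile type 7).
#'
#' @param vm A [fit_lognormal()] variability model.
#' @param bw A [body_weight_model()] (the uncertainty component).
#' @param ep Exposure parameters as from [exposure_params()] (point
#'   estimates of AA and ABS; the BW element is ignored in favor of `bw`).
#' @param tox List or one-row data frame with `rfd_abs` and `csf`
#'   (`csf` may be NA when no dermal slope factor applies).
#' @param cfg An [mc2d_config()].
#' @return Object of class `mc2d_result`: `sed_grid` (n_var x n_unc),
#'   `sed_summary`, `hq_summary`, `lcr_summary` (each p50/p95/max by
#'   default), `p_hq_gt_1`, plus the inputs.
#' @export
run_mc2d <- function(vm, bw, ep, tox, cfg = mc2d_config()) {
  stopifnot(inherits(vm, "lognormal_model"),
            inherits(bw, "body_weight_model"),
            inherits(cfg, "mc2d_config"))
  rfd <- tox$rfd_abs
  csf <- if (is.null(tox$csf)) NA_real_ else tox$csf
  stopifnot(rfd > 0)

  draws <- withr::with_seed(cfg$seed, {
    conc <- stats::rlnorm(cfg$n_var, vm$mu, vm$sigma)
    bws <- generate_body_weights(bw, cfg$n_unc)
    list(conc = conc, bws = bws)
  })
  # sed_grid[v, u] = C_v * AA * ABS * 1e-3 / BW_u
  sed_grid <- outer(draws$conc * ep$AA * ep$ABS * 1e-3, 1 / draws$bws)

  sed_summary <- grid_summary(sed_grid, cfg$percentiles)
  hq_summary <- sed_summary / rfd
  lcr_summary <- if (is.na(csf)) sed_summary * NA_real_ else sed_summary * csf
  structure(list(
    sed_grid = sed_grid,
    sed_summary = sed_summary,
    hq_summary = hq_summary,
    lcr_summary = lcr_summary,
    p_hq_gt_1 = mean(sed_grid / rfd > 1),
    rfd_abs = rfd, csf = csf,
    vm = vm, bw = bw, ep = ep, cfg = cfg
  ), class = "mc2d_result")
}

#' Probability of exceeding a threshold across all simulation cells
#'
#' Fraction of the n_var x n_unc cells strictly above the threshold, on
#' the HQ scale by default.
#'
#' @param result An `mc2d_result`.
#' @param threshold Exceedance threshold (default 1).
#' @param on Scale: `"hq"`, `"sed"` or `"lcr"`.
#' @return Fraction between 0 and 1.
#' @export
exceedance_probability <- function(result, threshold = 1,
                                   on = c("hq", "sed", "lcr")) {
  on <- match.arg(on)
  stopifnot(inherits(result, "mc2d_result"))
  g <- switch(on,
              hq = result$sed_grid / result$rfd_abs,
              sed = result$sed_grid,
              lcr = result$sed_grid * result$csf)
  mean(g > threshold)
}

#' Variability percentiles with uncertainty bands
#'
#' The standard two-dimensional Monte Carlo output: for each requested
#' variability percentile, the within-column (fixed body weight)
#' percentile is computed for each of the n_unc uncertainty iterations,
#' and its distribution over columns is summarized by the median and a
#' central band.
#'
#' @param result An `mc2d_result`.
#' @param percentiles Variability percentiles (default from the run
#'   config).
#' @param band Central band mass over uncertainty iterations
#'   (default 0.95).
#' @param on Scale: `"sed"` (default) or `"hq"`.
#' @return Tibble with `percentile`, `median`, `lower`, `upper`,
#'   `band_width`.
#' @export
summarize_by_uncertainty <- function(result, percentiles = NULL,
                                     band = 0.95, on = c("sed", "hq")) {
  on <- match.arg(on)
  stopifnot(inherits(result, "mc2d_result"))
  if (is.null(percentiles)) percentiles <- result$cfg$percentiles
  g <- if (on == "hq") result$sed_grid / result$rfd_abs else result$sed_grid
  alpha <- (1 - band) / 2
  rows <- lapply(percentiles, function(p) {
    colq <- apply(g, 2, stats::quantile, probs = p / 100, names = FALSE,
                  type = 7)
    qs <- stats::quantile(colq, c(alpha, 0.5, 1 - alpha), names = FALSE)
    tibble::tibble(percentile = p, median = qs[2], lower = qs[1],
                   upper = qs[3], band_width = qs[3] - qs[1])
  })
  dplyr::bind_rows(rows)
}

#' @keywords internal
derive_seed <- function(seed, metal, product_type) {
  mi <- match(metal, metal_symbols())
  pi_ <- match(product_type, names(product_type_categories()))
  as.integer((as.numeric(seed) * 7919 + mi * 104729 + pi_ * 131) %%
               2147483647)
}

#' Per-metal probabilistic risk report for a product type
#'
#' For each metal passing the detection-rate gate (rate >= 50% by default,
#' or listed in `force_metals`), fits a lognormal to the detected
#' concentrations of the product type and runs the two-dimensional engine.
#' Each metal uses an independently reproducible random stream keyed by
#' (seed, metal, product type). Metals with fewer than 2 detects are
#' skipped with a logged reason (see the `skipped` attribute).
#'
#' @param ds A `survey` tibble.
#' @param product_type Product type to evaluate.
#' @param cfg An [mc2d_config()].
#' @param registry Toxicity registry as from [tox_registry()].
#' @param bw A [body_weight_model()].
#' @param defaults Exposure defaults as from [exposure_defaults()].
#' @param detection_threshold Inclusion gate (default 0.50, non-strict).
#' @param force_metals Metals to evaluate regardless of the gate.
#' @return Tibble with one row per evaluated metal: SED/HQ/LCR p50, p95
#'   and max, `p_hq_gt_1`, `hq_flag` and `lcr_band_p95`; skipped metals
#'   recorded in `attr(, "skipped")`.
#' @export
risk_report <- function(ds, product_type, cfg = mc2d_config(),
                        registry = tox_registry(),
                        bw = body_weight_model(),
                        defaults = exposure_defaults(),
                        detection_threshold = 0.50, force_metals = NULL) {
  stopifnot(all(c(50, 95) %in% cfg$percentiles))
  sub <- filter_stratum(ds, product_type = product_type)
  if (nrow(sub) == 0) stop("no samples of product type ", product_type,
                           call. = FALSE)
  passing <- select_metals_by_detection(sub, detection_threshold,
                                        strict = FALSE)
  metals <- union(intersect(metal_symbols(), passing),
                  intersect(metal_symbols(), force_metals))
  metals <- intersect(metal_symbols(), metals)
  skipped <- list()
  rows <- list()
  for (m in setdiff(intersect(metal_symbols(), unique(sub$metal)), metals)) {
    skipped[[length(skipped) + 1]] <- tibble::tibble(
      metal = m, reason = "detection rate below gate")
  }
  for (m in metals) {
    det <- sub$value[sub$metal == m & sub$detected]
    if (length(det) < 2) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        metal = m, reason = "fewer than 2 detected values")
      next
    }
    vm <- fit_lognormal(det, metal = m)
    ep <- exposure_params(product_type, m, defaults, bw = bw$mean)
    tox <- registry[registry$metal == m, ]
    cfg_m <- mc2d_config(cfg$n_var, cfg$n_unc,
                         derive_seed(cfg$seed, m, product_type),
                         cfg$percentiles)
    res <- run_mc2d(vm, bw, ep, tox, cfg_m)
    s <- res$sed_summary; h <- res$hq_summary; l <- res$lcr_summary
    rows[[length(rows) + 1]] <- tibble::tibble(
      product_type = product_type, metal = m, n_fitted = vm$n_fitted,
      sed_p50 = s[["p50"]], sed_p95 = s[["p95"]], sed_max = s[["max"]],
      hq_p50 = h[["p50"]], hq_p95 = h[["p95"]], hq_max = h[["max"]],
      lcr_p50 = l[["p50"]], lcr_p95 = l[["p95"]], lcr_max = l[["max"]],
      p_hq_gt_1 = res$p_hq_gt_1,
      hq_flag = h[["p95"]] > 1,
      lcr_band_p95 = if (is.na(l[["p95"]])) NA_character_ else
        lcr_band(l[["p95"]])
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}
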