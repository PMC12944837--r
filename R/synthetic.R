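# Synthetic survey generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# a jointly lognormal "geogenic" block (As/Cr/Ni, correlated on the log
# scale, tracking mineral pigments and raw materials), an independent
# two-population Hg mixture in which a minority of face creams carry an
# adulteration spike orders of magnitude above the clean background, rare
# low-level Cd/Pb/Sb detections, and left-censoring at metal-specific LODs.

#' Geogenic (correlated lognormal) block model
#'
#' As/Cr/Ni concentrations are drawn jointly as exp of a multivariate
#' normal, so that their log-scale correlation is planted exactly.
#'
#' @param metals Ordered metal symbols in the block (default As, Cr, Ni).
#' @param log_mean Numeric vector of natural-log means (log mg/kg).
#' @param log_cov Symmetric positive-definite log-scale covariance matrix.
#' @return Object of class `geogenic_model`.
#' @export
geogenic_model <- function(metals = c("As", "Cr", "Ni"), log_mean, log_cov) {
  stopifnot(all(metals %in% metal_symbols()),
            length(log_mean) == length(metals),
            is.matrix(log_cov),
            nrow(log_cov) == length(metals),
            ncol(log_cov) == length(metals))
  if (max(abs(log_cov - t(log_cov))) > 1e-10) {
    stop("log_cov must be symmetric", call. = FALSE)
  }
  ok <- tryCatch({ chol(log_cov); TRUE }, error = function(e) FALSE)
  if (!ok) stop("log_cov must be positive definite", call. = FALSE)
  structure(list(metals = metals, log_mean = log_mean, log_cov = log_cov),
            class = "geogenic_model")
}

#' Helper: block covariance with common correlation
#'
#' @param sds Numeric vector of log-scale standard deviations.
#' @param rho Common pairwise correlation.
#' @return Covariance matrix.
#' @export
block_cov <- function(sds, rho) {
  p <- length(sds)
  r <- matrix(rho, p, p)
  diag(r) <- 1
  diag(sds) %*% r %*% diag(sds)
}

#' Two-population Hg adulteration mixture model
#'
#' With per-country prevalence, a sample from an affected product type draws
#' its Hg concentration from a high "spike" lognormal component (deliberate
#' addition to skin-lightening creams); otherwise from a low "clean"
#' background component. The Hg draw is independent of the geogenic block.
#'
#' @param prevalence Named numeric vector of spike prevalences by country
#'   (countries not listed get 0).
#' @param clean_log_mean,clean_log_sd Natural-log parameters of the clean
#'   background component.
#' @param spike_log_mean,spike_log_sd Natural-log parameters of the spike
#'   component; `spike_log_mean` must exceed `clean_log_mean`.
#' @param product_types Product types subject to adulteration
#'   (default `"facial_cream"`).
#' @return Object of class `adulteration_model`.
#' @export
adulteration_model <- function(prevalence, clean_log_mean, clean_log_sd,
                               spike_log_mean, spike_log_sd,
                               product_types = "facial_cream") {
  stopifnot(all(prevalence >= 0), all(prevalence <= 1),
            spike_log_mean > clean_log_mean,
            clean_log_sd >= 0, spike_log_sd >= 0)
  structure(list(prevalence = prevalence,
                 clean_log_mean = clean_log_mean, clean_log_sd = clean_log_sd,
                 spike_log_mean = spike_log_mean, spike_log_sd = spike_log_sd,
                 product_types = product_types),
            class = "adulteration_model")
}

#' Truncated-normal body-weight model
#'
#' Adult female body weight for the exposure equations, modeled as a normal
#' distribution truncated below at a physical floor.
#'
#' @param mean Mean body weight (kg); default 55 kg.
#' @param sd Standard deviation (kg); default 5 kg.
#' @param truncation_low Lower truncation bound (kg); default 30 kg.
#' @return Object of class `body_weight_model`.
#' @export
body_weight_model <- function(mean = 55, sd = 5, truncation_low = 30) {
  stopifnot(mean > 0, sd >= 0, truncation_low > 0)
  structure(list(mean = mean, sd = sd, truncation_low = truncation_low),
            class = "body_weight_model")
}

#' Generator configuration
#'
#' @param strata Data frame with columns `country`, `product_type`, `n`
#'   giving per-stratum sample counts.
#' @param geogenic A [geogenic_model()], or a named list with elements
#'   `face` and `eye` for category-specific blocks.
#' @param adulteration An [adulteration_model()] for Hg.
#' @param rare_metals Named list (by metal symbol) of
#'   `list(p_detect=, log_mean=, log_sd=)` models for sparsely detected
#'   metals: with probability `p_detect` a lognormal value is drawn,
#'   otherwise the metal is absent (recorded as a non-detect).
#' @param lod_registry Named numeric vector of per-metal LODs (mg/kg).
#' @param seed Integer seed; identical seeds yield identical datasets.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(strata, geogenic, adulteration, rare_metals,
                             lod_registry, seed = 1L) {
  strata <- tibble::as_tibble(strata)
  stopifnot(all(c("country", "product_type", "n") %in% names(strata)),
            all(strata$n >= 1),
            all(strata$product_type %in% names(product_type_categories())),
            all(names(lod_registry) %in% metal_symbols()),
            all(lod_registry > 0))
  if (inherits(geogenic, "geogenic_model")) {
    geogenic <- list(face = geogenic, eye = geogenic)
  }
  stopifnot(inherits(geogenic$face, "geogenic_model"),
            inherits(geogenic$eye, "geogenic_model"),
            inherits(adulteration, "adulteration_model"))
  for (m in names(rare_metals)) {
    rm <- rare_metals[[m]]
    stopifnot(m %in% metal_symbols(),
              rm$p_detect >= 0, rm$p_detect <= 1, rm$log_sd >= 0)
  }
  structure(list(strata = strata, geogenic = geogenic,
                 adulteration = adulteration, rare_metals = rare_metals,
                 lod_registry = lod_registry, seed = as.integer(seed)),
            class = "generator_config")
}

#' Default LODs shipped with the package (mg/kg)
#'
#' Chosen so that, as in real surveys of this kind, the As, Cd and Sb LODs
#' sit above the most conservative guidance values (the "minimum-estimate"
#' regime for exceedance screening), while Cr and Ni are detectable in
#' nearly every sample. Configurable, not asserted as instrument values.
#'
#' @return Named numeric vector of per-metal LODs.
#' @export
default_lod_registry <- function() {
  c(Hg = 0.005, As = 1.0, Cd = 0.2, Cr = 0.2, Ni = 0.2, Pb = 0.8, Sb = 1.5)
}

#' Default multi-country survey scenario ("asia7")
#'
#' A seven-country face/eye cosmetics survey emulating the qualitative
#' structure of a pooled Asian market sample: 189 products with the
#' stratum sizes of a real multi-country collection, a correlated geogenic
#' As/Cr/Ni block (higher As in eye products), a dichotomous Hg distribution
#' in facial creams with country-dependent spike prevalence (highest in the
#' Philippines and Bangladesh, spike centered near 15,400 mg/kg), and
#' sparse Cd/Pb/Sb. It is a synthetic fixture emulating published summary
#' patterns, not a reconstruction of any real per-sample data.
#'
#' @param seed Integer seed.
#' @return A [generator_config()].
#' @export
asia7_config <- function(seed = 1L) {
  strata <- tibble::tribble(
    ~country, ~product_type, ~n,
    "Bangladesh",  "facial_cream", 11L,
    "India",       "facial_cream",  4L,
    "Indonesia",   "facial_cream", 11L,
    "Korea",       "facial_cream", 10L,
    "Malaysia",    "facial_cream", 12L,
    "Philippines", "facial_cream", 45L,
    "Vietnam",     "facial_cream", 18L,
    "Bangladesh",  "foundation",    3L,
    "India",       "foundation",    5L,
    "Korea",       "foundation",    1L,
    "Philippines", "foundation",    1L,
    "Bangladesh",  "mascara",       5L,
    "India",       "mascara",       6L,
    "Indonesia",   "mascara",       8L,
    "Malaysia",    "mascara",       6L,
    "Philippines", "mascara",      20L,
    "Vietnam",     "mascara",      10L,
    "India",       "eye_shadow",    4L
  )
  geo_face <- geogenic_model(
    log_mean = c(As = log(0.55), Cr = log(1.6), Ni = log(0.8)),
    log_cov = block_cov(c(1.1, 0.8, 0.9), 0.6)
  )
  geo_eye <- geogenic_model(
    log_mean = c(As = log(2.6), Cr = log(1.4), Ni = log(2.6)),
    log_cov = block_cov(c(1.25, 0.8, 0.9), 0.6)
  )
  adult <- adulteration_model(
    prevalence = c(Philippines = 0.69, Bangladesh = 0.50, India = 0.25,
                   Malaysia = 0.15, Indonesia = 0.02, Korea = 0.02,
                   Vietnam = 0.02),
    clean_log_mean = log(0.002), clean_log_sd = 1.6,
    spike_log_mean = log(15400), spike_log_sd = 0.9
  )
  rare <- list(
    Cd = list(p_detect = 0.18, log_mean = log(0.30), log_sd = 0.8),
    Pb = list(p_detect = 0.24, log_mean = log(1.30), log_sd = 0.8),
    Sb = list(p_detect = 0.17, log_mean = log(6.0),  log_sd = 1.2)
  )
  generator_config(strata, list(face = geo_face, eye = geo_eye), adult, rare,
                   default_lod_registry(), seed = seed)
}

#' Generate a synthetic survey dataset
#'
#' Draws per-stratum samples according to the configured models, then
#' censors every value below the metal's LOD as a non-detect. Identical
#' seeds produce identical datasets.
#'
#' @param cfg A [generator_config()].
#' @return A `survey` tibble with a `planted_truth` attribute holding the
#'   exact generative parameters.
#' @export
generate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  ptc <- product_type_categories()
  lods <- cfg$lod_registry

  rows <- withr::with_seed(cfg$seed, {
    out <- vector("list", nrow(cfg$strata))
    for (s in seq_len(nrow(cfg$strata))) {
      st <- cfg$strata[s, ]
      n <- st$n
      category <- unname(ptc[st$product_type])
      geo <- cfg$geogenic[[category]]

      logs <- MASS::mvrnorm(n, mu = geo$log_mean, Sigma = geo$log_cov)
      if (n == 1) logs <- matrix(logs, nrow = 1)
      geo_vals <- exp(logs)
      colnames(geo_vals) <- geo$metals

      am <- cfg$adulteration
      prev <- if (st$product_type %in% am$product_types) {
        p <- am$prevalence[st$country]
        if (is.na(p)) 0 else unname(p)
      } else 0
      spike <- stats::rbinom(n, 1, prev) == 1
      hg <- ifelse(spike,
                   stats::rlnorm(n, am$spike_log_mean, am$spike_log_sd),
                   stats::rlnorm(n, am$clean_log_mean, am$clean_log_sd))

      vals <- cbind(Hg = hg, geo_vals)
      for (m in names(cfg$rare_metals)) {
        rm <- cfg$rare_metals[[m]]
        present <- stats::rbinom(n, 1, rm$p_detect) == 1
        v <- ifelse(present, stats::rlnorm(n, rm$log_mean, rm$log_sd), 0)
        vals <- cbind(vals, v)
        colnames(vals)[ncol(vals)] <- m
      }
      metals <- colnames(vals)
      ids <- sprintf("%s_%s_%03d", gsub("\\s+", "", st$country),
                     st$product_type, seq_len(n))
      out[[s]] <- tibble::tibble(
        sample_id = rep(ids, each = length(metals)),
        country = st$country, category = category,
        product_type = st$product_type,
        metal = rep(metals, times = n),
        value = as.vector(t(vals)),
        lod = unname(lods[rep(metals, times = n)]),
        method = "synthetic"
      )
    }
    dplyr::bind_rows(out)
  })

  rows$detected <- rows$value >= rows$lod
  rows$value[!rows$detected] <- NA_real_
  ds <- as_survey(rows, lod_registry = lods)
  attr(ds, "planted_truth") <- planted_truth(cfg)
  ds
}

#' Planted generative truth of a configuration or generated dataset
#'
#' Returns the exact generative parameters (log means, covariances,
#' correlations, prevalences, rare-metal models, LODs) for use in
#' parameter-recovery tests.
#'
#' @param x A [generator_config()] or a survey generated by
#'   [generate_survey()].
#' @return A list of generative parameters.
#' @export
planted_truth <- function(x) {
  if (inherits(x, "survey")) {
    return(attr(x, "planted_truth"))
  }
  stopifnot(inherits(x, "generator_config"))
  corr_of <- function(g) stats::cov2cor(g$log_cov)
  list(
    geogenic = x$geogenic,
    geogenic_correlation = lapply(x$geogenic, corr_of),
    adulteration = x$adulteration,
    rare_metals = x$rare_metals,
    lod_registry = x$lod_registry,
    seed = x$seed
  )
}

#' Draw body weights from a truncated normal model
#'
#' Uses inverse-CDF sampling so that no draw falls below the truncation
#' floor; with `sd = 0` all draws equal the mean.
#'
#' @param model A [body_weight_model()].
#' @param n Number of draws.
#' @param seed Optional integer seed; when `NULL`, draws come from the
#'   current RNG stream.
#' @return Numeric vector of n body weights (kg).
#' @export
generate_body_weights <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "body_weight_model"), n >= 1)
  draw <- function() {
    if (model$sd == 0) return(rep(model$mean, n))
    p_low <- stats::pnorm(model$truncation_low, model$mean, model$sd)
    u <- stats::runif(n, p_low, 1)
    stats::qnorm(u, model$mean, model$sd)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
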