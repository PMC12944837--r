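# Fixture builders used across the suite. All fixtures are constructed in
# code; no data files are shipped.

# Long-format survey rows for a single metal in a single stratum.
survey_rows <- function(values, metal = "Hg", lod = 0.5, country = "Korea",
                        category = "face", product_type = "facial_cream",
                        id_prefix = "S") {
  n <- length(values)
  tibble::tibble(
    sample_id = sprintf("%s_%03d", id_prefix, seq_len(n)),
    country = country, category = category, product_type = product_type,
    metal = metal,
    value = ifelse(is.na(values), NA_real_, values),
    detected = !is.na(values),
    lod = lod, method = "synthetic"
  )
}

# Survey with an exact (n_detected of n_total) detection count for one
# metal; detected values are spread above the LOD.
count_survey <- function(metal, n_total, n_detected, lod = 0.5,
                         category = "face",
                         product_type = if (category == "face")
                           "facial_cream" else "mascara",
                         country = "Korea") {
  values <- c(seq_len(n_detected) + lod, rep(NA_real_, n_total - n_detected))
  as_survey(survey_rows(values, metal = metal, lod = lod, country = country,
                        category = category, product_type = product_type))
}

# Multi-metal single-stratum survey with given per-metal detection counts.
rates_survey <- function(counts, n_total, lod = 0.5, category = "face") {
  product_type <- if (category == "face") "facial_cream" else "mascara"
  rows <- lapply(names(counts), function(m) {
    values <- c(seq_len(counts[[m]]) + lod,
                rep(NA_real_, n_total - counts[[m]]))
    r <- survey_rows(values, metal = m, lod = lod, category = category,
                     product_type = product_type)
    r$sample_id <- sprintf("P_%03d", seq_len(n_total))
    r
  })
  as_survey(dplyr::bind_rows(rows))
}

# Uncensored four-metal generator config with a planted correlated
# As/Cr/Ni block (common correlation rho) and independent lognormal Hg.
uncensored_config <- function(n, rho = 0.6, seed = 1,
                              sds = c(1, 1, 1), hg_sd = 1) {
  generator_config(
    strata = tibble::tibble(country = "Testland",
                            product_type = "facial_cream", n = as.integer(n)),
    geogenic = geogenic_model(
      log_mean = c(As = log(2), Cr = log(1.5), Ni = log(1)),
      log_cov = block_cov(sds, rho)),
    adulteration = adulteration_model(
      prevalence = c(Testland = 0), clean_log_mean = log(0.5),
      clean_log_sd = hg_sd, spike_log_mean = log(1000), spike_log_sd = 0.5),
    rare_metals = list(),
    lod_registry = c(Hg = 1e-9, As = 1e-9, Cd = 1e-9, Cr = 1e-9,
                     Ni = 1e-9, Pb = 1e-9, Sb = 1e-9),
    seed = seed
  )
}

# Write a small interchange-format CSV and return its path.
write_fixture_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

fixture_header <- "sample_id,country,category,product_type,metal,value,lod,method"
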