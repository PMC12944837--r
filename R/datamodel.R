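# Survey data model: left-censored metal determinations on cosmetic samples.
#
# A survey is a long-format tibble with one row per (sample, metal)
# determination, carrying the measured value (NA when below the limit of
# detection), the detection flag, the LOD and a method provenance tag.

#' Metal symbols covered by the survey data model
#'
#' The closed set of metals handled throughout the package: Hg, As, Cd, Cr,
#' Ni, Pb and Sb. Unknown symbols are rejected at parse time.
#'
#' @return Character vector of metal symbols.
#' @export
metal_symbols <- function() {
  c("Hg", "As", "Cd", "Cr", "Ni", "Pb", "Sb")
}

#' @keywords internal
survey_categories <- function() c("face", "eye")

#' Product types and their category mapping
#'
#' Facial creams and foundations are face products; mascaras and eye shadows
#' are eye products. The mapping is enforced as a validation invariant.
#'
#' @return Named character vector mapping product type to category.
#' @export
product_type_categories <- function() {
  c(facial_cream = "face", foundation = "face",
    mascara = "eye", eye_shadow = "eye")
}

#' @keywords internal
measurement_methods <- function() c("XRF", "DMA", "ICP-OES", "synthetic")

survey_columns <- c("sample_id", "country", "category", "product_type",
                    "metal", "value", "detected", "lod", "method")

#' Round half away from zero
#'
#' Presentation rounding used for detection-rate percentages, where 52.25
#' rounds to 52.3 rather than to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Construct a survey dataset from a data frame
#'
#' Validates the long-format measurement table and attaches the per-metal
#' LOD registry. Validation enforces: known metal symbols; product type
#' consistent with category; detected rows carry a non-negative value and
#' non-detect rows carry none; positive LODs; no duplicated
#' (sample, metal) determinations.
#'
#' @param df Data frame with columns `sample_id`, `country`, `category`,
#'   `product_type`, `metal`, `value`, `detected`, `lod`, `method`.
#' @param lod_registry Optional named numeric vector of per-metal LODs
#'   (mg/kg). Defaults to the most frequent LOD per metal observed in `df`;
#'   per-row LODs may override the registry value.
#' @return A tibble of class `survey` with a `lod_registry` attribute.
#' @export
as_survey <- function(df, lod_registry = NULL) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(survey_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("survey data missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[survey_columns]
  df$value <- as.numeric(df$value)
  df$lod <- as.numeric(df$lod)
  df$detected <- as.logical(df$detected)

  bad_metal <- setdiff(unique(df$metal), metal_symbols())
  if (length(bad_metal) > 0) {
    stop("unknown metal symbol(s): ", paste(bad_metal, collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(df$category), survey_categories())
  if (length(bad_cat) > 0) {
    stop("unknown category: ", paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  ptc <- product_type_categories()
  bad_pt <- setdiff(unique(df$product_type), names(ptc))
  if (length(bad_pt) > 0) {
    stop("unknown product_type: ", paste(bad_pt, collapse = ", "),
         call. = FALSE)
  }
  mismatch <- df$category != ptc[df$product_type]
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    stop("product_type '", df$product_type[i], "' inconsistent with category '",
         df$category[i], "' (sample ", df$sample_id[i], ")", call. = FALSE)
  }
  if (any(!df$method %in% measurement_methods())) {
    stop("unknown method tag; expected one of ",
         paste(measurement_methods(), collapse = ", "), call. = FALSE)
  }
  if (any(df$detected & (is.na(df$value) | df$value < 0))) {
    stop("detected measurements must carry a non-negative value",
         call. = FALSE)
  }
  if (any(!df$detected & !is.na(df$value))) {
    stop("non-detect measurements must not carry a value", call. = FALSE)
  }
  if (any(is.na(df$lod) | df$lod <= 0)) {
    stop("every measurement needs a positive LOD", call. = FALSE)
  }
  dup <- duplicated(df[c("sample_id", "metal")])
  if (any(dup)) {
    stop("duplicated determination for sample ", df$sample_id[which(dup)[1]],
         ", metal ", df$metal[which(dup)[1]], call. = FALSE)
  }

  if (is.null(lod_registry)) {
    lod_registry <- vapply(split(df$lod, df$metal), function(l) {
      tab <- sort(table(l), decreasing = TRUE)
      as.numeric(names(tab)[1])
    }, numeric(1))
  }
  attr(df, "lod_registry") <- lod_registry
  class(df) <- c("survey", class(df))
  df
}

#' Read a survey dataset from the delimited interchange format
#'
#' The format is UTF-8 CSV with header
#' `sample_id,country,category,product_type,metal,value,lod,method` and one
#' row per (sample, metal) determination. `value` is a decimal concentration
#' in mg/kg, or the sentinel token `ND` (case-insensitive) for a
#' determination below the limit of detection.
#'
#' @param path Path to the CSV file.
#' @return A validated `survey` tibble (see [as_survey()]).
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  expected <- c("sample_id", "country", "category", "product_type",
                "metal", "value", "lod", "method")
  if (!identical(names(raw), expected)) {
    stop("header mismatch: expected '", paste(expected, collapse = ","),
         "', got '", paste(names(raw), collapse = ","), "'", call. = FALSE)
  }
  is_nd <- toupper(trimws(raw$value)) == "ND"
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- !is_nd & is.na(value)
  if (any(bad)) {
    stop("malformed value '", raw$value[which(bad)[1]], "' at data row ",
         which(bad)[1], call. = FALSE)
  }
  lod <- suppressWarnings(as.numeric(raw$lod))
  if (any(is.na(lod))) {
    stop("malformed lod at data row ", which(is.na(lod))[1], call. = FALSE)
  }
  df <- tibble::tibble(
    sample_id = raw$sample_id, country = raw$country,
    category = raw$category, product_type = raw$product_type,
    metal = raw$metal,
    value = ifelse(is_nd, NA_real_, value),
    detected = !is_nd, lod = lod, method = raw$method
  )
  as_survey(df)
}

#' Write a survey dataset to the delimited interchange format
#'
#' Inverse of [read_survey()]: non-detects are written as the sentinel token
#' `ND`. `read_survey(write_survey(ds, p))` reproduces `ds`.
#'
#' @param ds A `survey` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(ds, path) {
  out <- tibble::tibble(
    sample_id = ds$sample_id, country = ds$country, category = ds$category,
    product_type = ds$product_type, metal = ds$metal,
    value = ifelse(ds$detected, format(ds$value, trim = TRUE, digits = 15,
                                       scientific = FALSE), "ND"),
    lod = ds$lod, method = ds$method
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @keywords internal
filter_stratum <- function(ds, country = NULL, category = NULL,
                           product_type = NULL) {
  keep <- rep(TRUE, nrow(ds))
  if (!is.null(country)) keep <- keep & ds$country %in% country
  if (!is.null(category)) keep <- keep & ds$category %in% category
  if (!is.null(product_type)) keep <- keep & ds$product_type %in% product_type
  ds[keep, , drop = FALSE]
}

#' Detection rate of a metal within a stratum
#'
#' The detection rate is the proportion of determinations above the LOD.
#' Percentages are reported to one decimal, rounding half away from zero.
#'
#' @param ds A `survey` tibble.
#' @param metal Metal symbol.
#' @param country,category,product_type Optional stratum filters; each may
#'   be a vector of accepted levels.
#' @return One-row tibble with `n_total`, `n_detected`, `detection_rate`
#'   (fraction) and `df_pct` (percent, one decimal).
#' @export
detection_rate <- function(ds, metal, country = NULL, category = NULL,
                           product_type = NULL) {
  stopifnot(metal %in% metal_symbols())
  sub <- filter_stratum(ds, country, category, product_type)
  sub <- sub[sub$metal == metal, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("empty stratum for metal ", metal, call. = FALSE)
  }
  n_total <- nrow(sub)
  n_detected <- sum(sub$detected)
  tibble::tibble(
    metal = metal, n_total = n_total, n_detected = n_detected,
    detection_rate = n_detected / n_total,
    df_pct = round_half_up(100 * n_detected / n_total, 1)
  )
}

#' Impute non-detects at LOD/sqrt(2)
#'
#' Detected values pass through unchanged; determinations below the LOD are
#' replaced by LOD/sqrt(2). Idempotent on its own output (imputed values are
#' treated as given).
#'
#' @param value Numeric concentrations (NA for non-detects).
#' @param detected Logical detection flags.
#' @param lod Numeric LODs (mg/kg), recycled as needed.
#' @return Numeric vector of concentrations with no missing entries.
#' @export
impute_nondetects <- function(value, detected, lod) {
  stopifnot(length(value) == length(detected))
  lod <- rep_len(lod, length(value))
  if (any(lod <= 0)) stop("LOD must be positive", call. = FALSE)
  ifelse(detected, value, lod / sqrt(2))
}

#' Censored descriptive summary for one metal within a stratum
#'
#' Reproduces the reporting convention of detection-frequency tables with
#' ranges: non-detects rank below every detected value, the median is
#' reported as ND (NA) when the median-rank determination is censored (or,
#' for even n, when the two central ranks straddle the detect/non-detect
#' boundary), the minimum is ND whenever any non-detect exists, and the
#' maximum is taken over detected values.
#'
#' @inheritParams detection_rate
#' @return One-row tibble: `metal`, `n_total`, `n_detected`, `df_pct`,
#'   `median`, `min`, `max` (NA encodes ND).
#' @export
summarize_stratum <- function(ds, metal, country = NULL, category = NULL,
                              product_type = NULL) {
  sub <- filter_stratum(ds, country, category, product_type)
  sub <- sub[sub$metal == metal, , drop = FALSE]
  if (nrow(sub) == 0) stop("empty stratum for metal ", metal, call. = FALSE)
  n <- nrow(sub)
  n_det <- sum(sub$detected)
  detects <- sort(sub$value[sub$detected])
  n_nd <- n - n_det

  med_at_rank <- function(r) {
    if (r <= n_nd) NA_real_ else detects[r - n_nd]
  }
  if (n %% 2 == 1) {
    med <- med_at_rank((n + 1) / 2)
  } else {
    lo <- med_at_rank(n / 2)
    hi <- med_at_rank(n / 2 + 1)
    med <- if (is.na(lo) || is.na(hi)) NA_real_ else (lo + hi) / 2
  }
  tibble::tibble(
    metal = metal, n_total = n, n_detected = n_det,
    df_pct = round_half_up(100 * n_det / n, 1),
    median = med,
    min = if (n_nd > 0) NA_real_ else min(detects),
    max = if (n_det > 0) max(detects) else NA_real_
  )
}

#' Long-format descriptive summary table
#'
#' One row per (stratum, metal), mirroring the layout of a detection
#' frequency/median(range) survey table.
#'
#' @param ds A `survey` tibble.
#' @param by Character vector of stratum columns to group by (subset of
#'   `country`, `category`, `product_type`).
#' @return Tibble with stratum columns, `metal`, `n`, `n_detected`,
#'   `df_pct`, `median`, `min`, `max`.
#' @export
survey_summary <- function(ds, by = c("country", "category")) {
  stopifnot(all(by %in% c("country", "category", "product_type")))
  groups <- unique(ds[by])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, , drop = FALSE]
    args <- list(ds = ds)
    for (b in by) args[[b]] <- g[[b]]
    present <- do.call(filter_stratum, c(list(ds), as.list(g)))
    rows <- lapply(intersect(metal_symbols(), unique(present$metal)),
                   function(m) do.call(summarize_stratum, c(args, metal = m)))
    dplyr::bind_cols(g[rep(1, length(rows)), , drop = FALSE],
                     dplyr::bind_rows(rows))
  })
  out <- dplyr::bind_rows(out)
  dplyr::rename(out, n = "n_total")
}

#' Select metals passing a detection-rate threshold
#'
#' Applies the analysis gates used for descriptive/risk work (rate >= 50%)
#' and for PCA inclusion (rate > 40%).
#'
#' @inheritParams detection_rate
#' @param threshold Detection-rate threshold as a fraction in (0, 1].
#' @param strict If `FALSE` (default) metals with rate >= threshold pass;
#'   if `TRUE` the inequality is strict.
#' @return Character vector of metal symbols passing the gate, in the
#'   canonical order of [metal_symbols()].
#' @export
select_metals_by_detection <- function(ds, threshold, strict = FALSE,
                                       country = NULL, category = NULL,
                                       product_type = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  sub <- filter_stratum(ds, country, category, product_type)
  metals <- intersect(metal_symbols(), unique(sub$metal))
  rates <- vapply(metals, function(m) {
    rows <- sub[sub$metal == m, , drop = FALSE]
    sum(rows$detected) / nrow(rows)
  }, numeric(1))
  pass <- if (strict) rates > threshold else rates >= threshold
  metals[pass]
}

#' Per-metal LOD registry of a survey
#'
#' @param ds A `survey` tibble.
#' @return Named numeric vector of LODs (mg/kg).
#' @export
lod_registry <- function(ds) {
  attr(ds, "lod_registry")
}
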