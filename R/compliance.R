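# Guidance-value exceedance screening.
#
# A sample exceeds a guidance value only when a quantified concentration is
# strictly greater than the limit; non-detects are conservatively counted
# as non-exceedances, so where the LOD sits above the limit the resulting
# proportions are minimum estimates.

#' Construct a guidance-value table
#'
#' @param entries Data frame with columns `metal`, `category` (`face`,
#'   `eye` or `any`), `limit` (mg/kg) and `source_label`.
#' @return A validated tibble of class `guidance_table`.
#' @export
guidance_table <- function(entries) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("metal", "category", "limit", "source_label") %in%
                  names(entries)),
            all(entries$metal %in% metal_symbols()),
            all(entries$category %in% c("face", "eye", "any")),
            all(entries$limit > 0))
  key <- paste(entries$metal, entries$category, entries$source_label)
  if (anyDuplicated(key)) {
    stop("duplicate guidance entry for ", key[duplicated(key)][1],
         call. = FALSE)
  }
  class(entries) <- c("guidance_table", class(entries))
  entries
}

#' Default guidance-value table (BVL limits, MFDS nickel limits)
#'
#' German BVL guidance values (Hg 0.1, As 0.5, Cd 0.1, Sb 0.5 mg/kg for all
#' products; Pb 2 mg/kg face / 5 mg/kg eye) supplemented with the Korean
#' MFDS nickel limits (10 mg/kg face / 35 mg/kg eye), since no BVL value
#' exists for Ni. Total Cr has no numerical guidance value and is handled
#' with an explicit marker by [exceedance_table()]. Fully user-overridable.
#'
#' @return A `guidance_table`.
#' @export
default_guidance <- function() {
  guidance_table(tibble::tribble(
    ~metal, ~category, ~limit, ~source_label,
    "Hg", "any",  0.1, "BVL",
    "As", "any",  0.5, "BVL",
    "Cd", "any",  0.1, "BVL",
    "Sb", "any",  0.5, "BVL",
    "Pb", "face", 2.0, "BVL",
    "Pb", "eye",  5.0, "BVL",
    "Ni", "face", 10.0, "MFDS",
    "Ni", "eye",  35.0, "MFDS"
  ))
}

#' ASEAN regional guidance-value table
#'
#' ASEAN cosmetic contaminant limits: Pb 10, As 5, Hg 0.5, Cd 0.3 mg/kg.
#'
#' @return A `guidance_table`.
#' @export
asean_guidance <- function() {
  guidance_table(tibble::tribble(
    ~metal, ~category, ~limit, ~source_label,
    "Pb", "any", 10.0, "ASEAN",
    "As", "any",  5.0, "ASEAN",
    "Hg", "any",  0.5, "ASEAN",
    "Cd", "any",  0.3, "ASEAN"
  ))
}

#' @keywords internal
lookup_limit <- function(table, metal, category) {
  hit <- table[table$metal == metal & table$category == category, ]
  if (nrow(hit) == 0) hit <- table[table$metal == metal &
                                     table$category == "any", ]
  if (nrow(hit) == 0) return(NULL)
  hit[1, ]
}

#' Classify a single determination against a guidance value
#'
#' TRUE only when the determination is a detect and its quantified value is
#' strictly greater than the limit; non-detects are non-exceedances.
#'
#' @param value Numeric concentration (NA for non-detects), vectorized.
#' @param detected Logical detection flag, vectorized.
#' @param limit Guidance value (mg/kg), positive.
#' @return Logical vector.
#' @export
classify_exceedance <- function(value, detected, limit) {
  stopifnot(limit > 0)
  detected & !is.na(value) & value > limit
}

#' Exceedance proportions by stratum and metal
#'
#' For each (stratum, metal) the count and proportion of samples exceeding
#' the applicable guidance value. Metals with no guidance value in the
#' table but present in `metals` — total Cr under the default table — are
#' reported with `no_guidance = TRUE` and NA proportion rather than a
#' number. `minimum_estimate_flag` marks strata where the LOD exceeds the
#' limit, so censoring may hide true exceedances.
#'
#' @param ds A `survey` tibble.
#' @param table A `guidance_table` (default [default_guidance()]).
#' @param by Stratum columns to group by (default country and category).
#' @param metals Metals to evaluate (default all present in `ds`).
#' @return Tibble with stratum columns, `metal`, `n_total`, `n_exceed`,
#'   `proportion`, `limit_used`, `source_label`, `minimum_estimate_flag`,
#'   `no_guidance`.
#' @export
exceedance_table <- function(ds, table = default_guidance(),
                             by = c("country", "category"), metals = NULL) {
  stopifnot(inherits(table, "guidance_table"),
            all(by %in% c("country", "category", "product_type")))
  if (is.null(metals)) metals <- intersect(metal_symbols(), unique(ds$metal))
  no_guidance_ok <- "Cr"
  for (m in setdiff(metals, no_guidance_ok)) {
    for (cat in unique(ds$category)) {
      if (is.null(lookup_limit(table, m, cat))) {
        stop("no guidance value for metal ", m, " in category ", cat,
             call. = FALSE)
      }
    }
  }
  groups <- unique(ds[by])
  out <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, , drop = FALSE]
    sub <- do.call(filter_stratum, c(list(ds), as.list(g)))
    for (m in metals) {
      rows <- sub[sub$metal == m, , drop = FALSE]
      if (nrow(rows) == 0) next
      cat <- unique(rows$category)
      lim <- if (length(cat) == 1) lookup_limit(table, m, cat) else NULL
      if (is.null(lim) && length(cat) > 1) {
        # mixed-category stratum: per-row limits, report NA limit_used
        lims <- vapply(rows$category, function(cc) {
          e <- lookup_limit(table, m, cc)
          if (is.null(e)) NA_real_ else e$limit
        }, numeric(1))
        if (all(is.na(lims))) lim <- NULL else {
          exceed <- rows$detected & !is.na(rows$value) &
            !is.na(lims) & rows$value > lims
          out[[length(out) + 1]] <- dplyr::bind_cols(g, tibble::tibble(
            metal = m, n_total = nrow(rows), n_exceed = sum(exceed),
            proportion = sum(exceed) / nrow(rows), limit_used = NA_real_,
            source_label = NA_character_,
            minimum_estimate_flag = any(rows$lod > lims, na.rm = TRUE),
            no_guidance = FALSE))
          next
        }
      }
      if (is.null(lim)) {
        out[[length(out) + 1]] <- dplyr::bind_cols(g, tibble::tibble(
          metal = m, n_total = nrow(rows), n_exceed = NA_integer_,
          proportion = NA_real_, limit_used = NA_real_,
          source_label = "no guidance value",
          minimum_estimate_flag = NA, no_guidance = TRUE))
        next
      }
      exceed <- classify_exceedance(rows$value, rows$detected, lim$limit)
      out[[length(out) + 1]] <- dplyr::bind_cols(g, tibble::tibble(
        metal = m, n_total = nrow(rows), n_exceed = sum(exceed),
        proportion = sum(exceed) / nrow(rows), limit_used = lim$limit,
        source_label = lim$source_label,
        minimum_estimate_flag = any(rows$lod > lim$limit),
        no_guidance = FALSE))
    }
  }
  dplyr::bind_rows(out)
}
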