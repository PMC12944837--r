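# Dermal exposure and risk equations.
#
# SED (systemic exposure dose, mg/kg-bw/day) = C * AA * ABS / BW * 1e-3,
# where C is the product concentration (mg/kg), AA the daily applied
# amount (g/day), ABS the dermal absorption fraction and BW body weight
# (kg); the 1e-3 converts the ug/kg-bw/day product of mg/kg with g/day to
# mg/kg-bw/day. HQ = SED / RfD_ABS (absorbed reference dose,
# RfD_ABS = RfD_o * ABS_GI); HQ > 1 flags possible non-cancer effects.
# LCR = SED * CSF, screened against the EPA 1e-6 to 1e-4 band.

#' Systemic exposure dose from dermal application
#'
#' @param C Concentration in the product (mg/kg); non-negative, vectorized.
#' @param AA Daily amount of product applied (g/day); positive.
#' @param ABS Dermal absorption fraction in (0, 1].
#' @param BW Body weight (kg); positive, vectorized.
#' @return SED in mg/kg-bw/day.
#' @export
compute_sed <- function(C, AA, ABS, BW) {
  if (any(C < 0)) stop("concentration must be non-negative", call. = FALSE)
  if (any(AA <= 0)) stop("AA must be positive", call. = FALSE)
  if (any(ABS <= 0) || any(ABS > 1)) {
    stop("ABS must be in (0, 1]", call. = FALSE)
  }
  if (any(BW <= 0)) stop("BW must be positive", call. = FALSE)
  C * AA * ABS / BW * 1e-3
}

#' Absorbed (dermal-adjusted) reference dose
#'
#' RfD_ABS = RfD_o * ABS_GI, where ABS_GI is the fraction absorbed in the
#' gastrointestinal tract in the critical oral toxicity study.
#'
#' @param rfd_o Oral reference dose (mg/kg/day); positive.
#' @param abs_gi Gastrointestinal absorption fraction in (0, 1].
#' @return RfD_ABS in mg/kg/day.
#' @export
rfd_abs <- function(rfd_o, abs_gi) {
  if (any(rfd_o <= 0)) stop("RfD_o must be positive", call. = FALSE)
  if (any(abs_gi <= 0)) stop("ABS_GI must be positive", call. = FALSE)
  if (any(abs_gi > 1)) stop("ABS_GI cannot exceed 1", call. = FALSE)
  rfd_o * abs_gi
}

#' Hazard quotient
#'
#' @param sed SED (mg/kg/day); vectorized.
#' @param rfd_abs Absorbed reference dose (mg/kg/day); positive.
#' @return HQ (dimensionless); values above 1 indicate possible systemic
#'   non-cancer effects.
#' @export
compute_hq <- function(sed, rfd_abs) {
  if (any(rfd_abs <= 0)) stop("RfD_ABS must be positive", call. = FALSE)
  sed / rfd_abs
}

#' Lifetime cancer risk
#'
#' @param sed SED (mg/kg/day); vectorized.
#' @param csf Cancer slope factor ((mg/kg/day)^-1); positive.
#' @return LCR (dimensionless lifetime probability increment).
#' @export
compute_lcr <- function(sed, csf) {
  if (any(csf <= 0)) stop("CSF must be positive", call. = FALSE)
  sed * csf
}

#' Classify an LCR value against the EPA screening band
#'
#' The acceptable band is 1e-6 to 1e-4.
#'
#' @param lcr Numeric LCR values.
#' @return Character vector: `"below"`, `"within"` or `"above"`.
#' @export
lcr_band <- function(lcr) {
  ifelse(lcr < 1e-6, "below", ifelse(lcr <= 1e-4, "within", "above"))
}

#' Toxicity parameter registry
#'
#' Per-metal absorbed reference doses (mg/kg/day) and cancer slope factors
#' ((mg/kg/day)^-1), each with a source label. Shipped defaults:
#' CSF Ni 0.91, As 32 (the `"as_csf_31.7"` profile substitutes the updated
#' EPA IRIS value 31.7), Pb 0.0085, Cd 6.7. The Pb non-cancer reference is
#' the BMDL10 of 0.5 ug/kg/day (5e-4 mg/kg/day) used in place of an RfD,
#' since the EPA has established none for Pb. The Hg and As RfD_ABS
#' defaults (3e-4 and 6e-5 mg/kg/day) are the absorbed reference doses this
#' assessment framework uses for dermal HQ; the remaining RfD_ABS values
#' are RfD_o x ABS_GI products from EPA sources. All values are
#' user-overridable via `overrides`.
#'
#' @param profile `"default"` or `"as_csf_31.7"`.
#' @param overrides Optional tibble with columns from the registry to
#'   replace rows by metal.
#' @return Tibble with `metal`, `rfd_abs`, `csf` (NA where no dermal CSF is
#'   applied), `source_label`.
#' @export
tox_registry <- function(profile = c("default", "as_csf_31.7"),
                         overrides = NULL) {
  profile <- match.arg(profile)
  reg <- tibble::tribble(
    ~metal, ~rfd_abs, ~csf, ~source_label,
    "Hg", 3e-4,    NA_real_, "inorganic Hg, absorbed RfD",
    "As", 6e-5,    32,       "inorganic As; CSF 32",
    "Cd", 2.5e-5,  6.7,      "EPA IRIS RfD_o 1e-3 x ABS_GI 0.025",
    "Cr", 1.95e-2, NA_real_, "Cr(III) RfD_o 1.5 x ABS_GI 0.013",
    "Ni", 8e-4,    0.91,     "Ni soluble salts RfD_o 2e-2 x ABS_GI 0.04",
    "Pb", 5e-4,    0.0085,   "BMDL10 0.5 ug/kg/day",
    "Sb", 6e-5,    NA_real_, "Sb RfD_o 4e-4 x ABS_GI 0.15"
  )
  if (profile == "as_csf_31.7") {
    reg$csf[reg$metal == "As"] <- 31.7
    reg$source_label[reg$metal == "As"] <- "inorganic As; EPA IRIS 2025 CSF 31.7"
  }
  if (!is.null(overrides)) {
    overrides <- tibble::as_tibble(overrides)
    stopifnot("metal" %in% names(overrides),
              all(overrides$metal %in% reg$metal))
    for (i in seq_len(nrow(overrides))) {
      j <- match(overrides$metal[i], reg$metal)
      for (col in setdiff(names(overrides), "metal")) {
        reg[[col]][j] <- overrides[[col]][i]
      }
    }
  }
  stopifnot(all(reg$rfd_abs > 0), all(is.na(reg$csf) | reg$csf > 0))
  reg
}

#' Default exposure parameters
#'
#' Daily applied amounts per product type (g/day, from standard cosmetic
#' exposure guidance: facial cream 1.54, foundation 0.51, mascara 0.025,
#' eye shadow 0.02) and a generic dermal absorption fraction of 0.01 per
#' metal; both configurable.
#'
#' @return List with `aa` (named by product type, g/day) and `abs` (named
#'   by metal, dimensionless fraction).
#' @export
exposure_defaults <- function() {
  list(
    aa = c(facial_cream = 1.54, foundation = 0.51,
           mascara = 0.025, eye_shadow = 0.02),
    abs = c(Hg = 0.01, As = 0.01, Cd = 0.01, Cr = 0.01,
            Ni = 0.01, Pb = 0.01, Sb = 0.01)
  )
}

#' Assemble exposure parameters for a product type and metal
#'
#' @param product_type One of the supported product types.
#' @param metal Metal symbol.
#' @param defaults Parameter set as from [exposure_defaults()].
#' @param bw Point body weight (kg) for deterministic use.
#' @return List with `AA` (g/day), `ABS` (fraction) and `BW` (kg).
#' @export
exposure_params <- function(product_type, metal,
                            defaults = exposure_defaults(), bw = 55) {
  stopifnot(product_type %in% names(defaults$aa),
            metal %in% names(defaults$abs))
  list(AA = unname(defaults$aa[product_type]),
       ABS = unname(defaults$abs[metal]), BW = bw)
}
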