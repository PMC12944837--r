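---
title: "Methods: probabilistic risk assessment of metal impurities in cosmetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic risk assessment of metal impurities in cosmetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosmetrisk)
```

## The problem

Market surveys of cosmetics quantify metal impurities (here Hg, As, Cd,
Cr, Ni, Pb, Sb) across products and countries. Three features make the
statistics non-standard:

* **Left-censoring.** Many determinations fall below the analytical limit
  of detection (LOD), and for some metals the LOD is higher than the most
  conservative regulatory guidance value.
* **Extreme heterogeneity.** Mercury in face creams is dichotomous: a
  clean background population orders of magnitude below 1 mg/kg, and an
  adulterated subpopulation (skin-lightening products) reaching
  10^4^–10^5^ mg/kg. Deterministic mean-based risk assessment badly
  understates the upper tail in such markets.
* **Mixed sources.** Pigment-associated metals (As, Cr, Ni) co-vary
  because they enter via shared mineral raw materials; deliberately added
  metals (Hg) vary independently of them.

`cosmetrisk` implements the full analysis pipeline for such surveys:
censored data model → descriptive summaries → guidance-value exceedance
screening → PCA source characterization → probabilistic (two-dimensional
Monte Carlo) dermal risk assessment, plus a synthetic survey generator so
that every stage is testable without access to raw measurement data.

## Censored data model

A survey is a long table of (sample, metal) determinations with a
detection flag and an LOD. Conventions:

* **Imputation.** Non-detects are imputed as LOD/√2 wherever a numeric
  value is required (descriptives on the log scale, PCA input). This is
  the standard substitution for moderately censored environmental data;
  it is deliberately simple and biased for heavily censored metals, which
  is why detection-rate *gates* (below) precede any distributional use.
* **Censored medians and ranges.** For reporting, non-detects rank below
  every detected value. The median is reported as ND when the median-rank
  determination is censored (for even n, when the two central ranks
  straddle the detect/non-detect boundary); the minimum is ND whenever
  any non-detect exists; the maximum is taken over detects. This
  reproduces survey-table conventions without inventing values below the
  LOD.
* **Detection-rate gates.** Distribution fitting and descriptive medians
  use metals with detection rate ≥ 50% in the stratum; PCA admits metals
  with rate > 40%. Both thresholds are arguments, not constants.
* **Rounding.** Detection percentages are presented to one decimal,
  rounding half away from zero (52.3077 → 52.3), matching how such tables
  are printed.

## Exceedance screening

A sample exceeds a guidance value only when a *quantified* concentration
is strictly greater than the limit; non-detects count as non-exceedances.
Where the LOD exceeds the limit (with the shipped default LODs: As, Cd,
Sb against the strictest limits) the resulting proportions are therefore
minimum estimates, and results carry a `minimum_estimate_flag`. The
shipped table uses the German BVL guidance values (Hg 0.1, As 0.5, Cd
0.1, Sb 0.5 mg/kg; Pb 2 face / 5 eye) with Korean MFDS nickel limits (10
face / 35 eye) because BVL publishes none for Ni; an ASEAN table (Pb 10,
As 5, Hg 0.5, Cd 0.3) is included as an alternative. Total Cr has no
numerical guidance value and is reported with an explicit
"no guidance value" marker rather than silently dropped. All tables are
user-overridable; no position is taken on jurisdictional applicability.

## PCA source characterization

Concentrations are imputed, natural-log transformed (the base is
irrelevant after standardization), column-standardized, and decomposed
via the correlation matrix. Choices that matter:

* **Correlation, not covariance.** Metals span incommensurate scales
  (Hg up to 10^4^ mg/kg, Cd below 1 mg/kg); correlation PCA weights them
  equally. Eigenvalues then sum to the number of metals, and "variance
  explained" fractions are eigenvalue / p.
* **Determinism.** Components are ordered by descending eigenvalue and
  signed so the largest-magnitude loading of each component is positive.
* **Retention.** Components with eigenvalue > 1 are kept; a component
  with eigenvalue within 0.05 of 1 may additionally be kept when needed
  to reach 70% cumulative variance. This reproduces the common practice
  of retaining a "close to 1" second component when the first alone
  explains too little.
* **Varimax.** Rotation operates on factor loadings (eigenvectors ×
  √eigenvalue), with Kaiser row normalization, via pairwise planar
  rotations; convergence when a full sweep gains less than 10^-6^ in the
  varimax criterion, capped at 1000 sweeps. Communalities are preserved
  to well below 10^-8^. The implementation is intentionally self-contained
  and is cross-checked in the tests against both a brute-force grid over
  the rotation angle and `stats::varimax` (which it matches up to column
  sign/order, occasionally attaining a marginally higher criterion
  because of the tighter stopping rule).

With the planted structure of the synthetic generator (common As/Cr/Ni
log-correlation 0.6, independent Hg) the rotated solution isolates Hg on
its own component with |loading| > 0.8 in over 95% of seeds at n = 150 —
the recovery property that makes the "separate Hg signature"
interpretation testable.

## Dose and risk equations

For dermal exposure to a product containing concentration $C$ (mg/kg):

$$\mathrm{SED} = \frac{C \cdot AA \cdot ABS}{BW} \times 10^{-3}
\quad \text{(mg/kg-bw/day)}$$

where $AA$ is the daily applied amount (g/day), $ABS$ the dermal
absorption fraction, $BW$ body weight (kg); the $10^{-3}$ converts the
µg/kg-bw/day product of mg/kg with g/day into mg/kg-bw/day.

$$\mathrm{HQ} = \frac{\mathrm{SED}}{\mathrm{RfD}_{ABS}},
\qquad \mathrm{RfD}_{ABS} = \mathrm{RfD}_o \times ABS_{GI},
\qquad \mathrm{LCR} = \mathrm{SED} \times \mathrm{CSF}$$

HQ > 1 flags possible systemic non-cancer effects; LCR is screened
against the EPA acceptable band 10^-6^–10^-4^.

Shipped parameter defaults (every one overridable through
`tox_registry()` / `exposure_defaults()`):

| parameter | default | rationale |
|---|---|---|
| CSF As | 32 (mg/kg/day)^-1^ | the value arithmetically consistent with the published LCR tables; the updated EPA IRIS 31.7 is available as the `as_csf_31.7` profile |
| CSF Ni / Pb / Cd | 0.91 / 0.0085 / 6.7 | standard slope factors for the sulfate/soluble forms |
| Pb non-cancer reference | 5×10^-4^ mg/kg/day | BMDL~10~ of 0.5 µg/kg/day, used because the EPA has established no RfD for Pb |
| RfD~ABS~ Hg / As | 3×10^-4^ / 6×10^-5^ mg/kg/day | absorbed reference doses consistent with published SED→HQ pairs; the As value does not factor as an obvious IRIS RfD~o~ × ABS~GI~ product and is therefore shipped directly, labelled |
| RfD~ABS~ Cd / Cr(III) / Ni / Sb | 2.5×10^-5^ / 1.95×10^-2^ / 8×10^-4^ / 6×10^-5^ | EPA RfD~o~ × ABS~GI~ products |
| AA | 1.54 / 0.51 / 0.025 / 0.02 g/day | facial cream / foundation / mascara / eye shadow, standard cosmetic exposure guidance |
| ABS | 0.01 (all metals) | generic conservative dermal absorption fraction; metal- and matrix-specific values are poorly constrained, so a single transparent default is used |
| BW | normal(55, 5) kg, truncated at 30 kg | adult female body weight for Asian populations; truncation avoids non-physical draws (the truncation floor is a package choice, 5 sd below the mean, and is numerically irrelevant at the default sd) |

## Two-dimensional Monte Carlo

The engine separates *variability* (concentration heterogeneity across
products, lognormal fitted by MLE — mean and population sd of logs — to
detected values only) from *uncertainty* (body weight, truncated
normal). Defaults: 5000 variability × 200 uncertainty iterations = 10^6^
cells.

Design points:

* **Draw order is part of the contract.** Concentration draws are taken
  first, then body-weight draws, so a 1-D simulation on the same seed
  reproduces each grid column exactly when body-weight sd is 0 — the
  oracle-equivalence property the tests exploit.
* **Summaries.** p50, p95 and max over all cells, with quantile type 7
  (linear interpolation). "Max" is the simulated maximum over cells, not
  a deterministic estimate at the largest measured concentration; both
  conventions are defensible and the simulated one is used throughout.
* **Exact equivariance.** HQ and LCR summaries are computed from the SED
  summaries through the monotone maps SED/RfD~ABS~ and SED×CSF, so the
  identity holds exactly rather than statistically.
* **Uncertainty bands.** `summarize_by_uncertainty()` reports, for each
  variability percentile, the median and central 95% band of the
  within-column percentile across uncertainty iterations — the standard
  2-D Monte Carlo presentation.
* **Per-metal streams.** Each (metal, product type) uses a sub-seed
  derived from the run seed, so single-metal results are reproducible in
  isolation.
* **Censored fitting.** Fitting to detects only overstates the central
  tendency of the full concentration distribution when censoring is
  heavy; that is the documented convention here (it mirrors how such
  assessments are usually run), and the detection gate keeps the worst
  cases out. A censored-likelihood fit is deliberately not the default.

## Synthetic survey generator

`asia7_config()` defines the shipped scenario: 180 samples in 18
(country × product type) strata matching the per-product-type sizes of a
real seven-country collection, a jointly lognormal As/Cr/Ni block
(correlation 0.6; higher As in eye products), a two-population Hg mixture
in facial creams with country-specific spike prevalence (0.69 in the
Philippines down to 0.02; spike centered at 15,400 mg/kg, log-sd 0.9,
clean background centered at 0.002 mg/kg), sparse Cd/Pb/Sb, and
left-censoring at the default LOD registry. Parameters were chosen once
to reproduce the qualitative published patterns (about half of face
products Hg-detected; Philippine face-cream detected-Hg medians within a
factor of two of 15,400 mg/kg; the four PCA metals passing the >40%
pooled gate) and are not adjusted thereafter.

What the generator does *not* emulate: per-sample real values, within-
country brand clustering, analytical measurement error, correlated
censoring across metals, or usage-pattern variability (applied amounts
are point estimates, as in the assessment it supports). Passing tests
therefore demonstrate that the machinery recovers known structure from
data *shaped like* such a survey — not that any specific market estimate
is reproduced.

## Numerical and testing choices

* Degenerate inputs are errors, not silent results: empty strata,
  zero-variance PCA columns, fewer than two detects for fitting,
  non-positive-definite planted covariances, ABS~GI~ > 1.
* Eigenvalues are clipped at 0 to absorb −10^-16^-scale noise in exact
  rank-deficient cases.
* The test suite uses problem sizes chosen for tight statistical bounds
  at interactive runtimes: n = 5000 for MLE recovery (3 SE), 5000 × 200
  grids for quantile accuracy (3 bootstrap SE), 40 seeds at n = 150 for
  the PCA recovery rate, and n = 2000–4000 for correlation and censoring
  convergence.

## Known limitations

* LOD/√2 substitution and detects-only fitting are conventions, not
  estimators; for heavily censored metals the reported medians and
  fitted distributions are conditional on detection.
* Single-metal HQ/LCR ignores co-exposure; no mixture index is computed.
* No metal speciation (total Cr, total As), hence no Cr(VI)-specific
  toxicity interpretation.
* Exceedance screening is a numeric comparison against configurable
  limits; it is not a statement about legal applicability of any
  jurisdiction's rules.
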