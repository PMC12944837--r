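# cosmetrisk

Probabilistic health-risk assessment of heavy-metal impurities in
cosmetics, for researchers and regulators analyzing market-survey data of
face and eye products.

Surveys of this kind face left-censored concentrations (non-detects at
metal-specific LODs), extreme heterogeneity (mercury adulteration of
skin-lightening creams spans eight orders of magnitude), and mixed
contamination sources (pigment-borne As/Cr/Ni versus deliberately added
Hg). `cosmetrisk` provides the full pipeline:

* **Censored data model** — long-format survey tables with detection
  flags, LOD/√2 imputation, detection-rate gates, and censored
  median/range summaries (`read_survey()`, `summarize_stratum()`,
  `select_metals_by_detection()`).
* **Compliance screening** — exceedance proportions against configurable
  guidance values (BVL, MFDS Ni, ASEAN shipped), with non-detects
  conservatively counted as non-exceedances and minimum-estimate flags
  where the LOD exceeds the limit (`exceedance_table()`).
* **Source characterization** — correlation-matrix PCA on
  log-transformed imputed concentrations, eigenvalue/cumulative-variance
  retention, and a self-contained Kaiser-normalized varimax rotation
  (`fit_pca()`, `retain_components()`, `varimax_rotate()`).
* **Risk engine** — the dermal dose equations
  SED = C·AA·ABS/BW·10⁻³ (mg/kg-bw/day), HQ = SED/RfD_ABS with
  RfD_ABS = RfD_o·ABS_GI, LCR = SED·CSF, with a sourced, overridable
  parameter registry (`compute_sed()`, `tox_registry()`).
* **Two-dimensional Monte Carlo** — lognormal concentration variability
  (MLE on detected values) crossed with truncated-normal body-weight
  uncertainty, 5000 × 200 iterations by default, percentile/maximum
  summaries and P[HQ > 1] (`run_mc2d()`, `risk_report()`).
* **Synthetic survey generator** — multi-country datasets with planted
  correlation structure, an Hg adulteration mixture and censoring, so the
  whole pipeline is testable without raw data (`asia7_config()`,
  `generate_survey()`).

## Worked example

```r
library(cosmetrisk)

ds <- generate_survey(asia7_config(seed = 1))

summarize_stratum(ds, "Hg", country = "Philippines", category = "face")
#>   metal n_total n_detected df_pct median min   max
#>      Hg      46         33   71.7   9102  NA 90183
```

Philippine face products show the planted adulteration signature: the
detected-Hg median sits near the 15,400 mg/kg spike center, the minimum
is ND (censored), and the maximum reaches 9 × 10⁴ mg/kg.

```r
fit <- fit_pca(prepare_matrix(ds, c("Hg", "As", "Cr", "Ni")))
retain_components(fit)
#> [1] 2
round(varimax_rotate(fit$factor_loadings, 2)$loadings, 3)
#>       RC1    RC2
#> Hg -0.052  0.958
#> As  0.852 -0.103
#> Cr  0.734  0.379
#> Ni  0.896 -0.136
```

Two components are retained (eigenvalues 2.07 and 1.09 of 4). After
varimax rotation the geogenic metals load together on RC1 while Hg loads
alone on RC2 — the statistical fingerprint distinguishing intentional
adulteration from pigment-borne contamination.

```r
risk_report(ds, "facial_cream", cfg = mc2d_config(seed = 1))
#>   metal n_fitted   hq_p50   hq_p95  lcr_p50  lcr_p95 p_hq_gt_1
#>      Hg       61 9.82e-02 5.55e+03       NA       NA     0.365
#>      Cr      111 2.19e-05 8.65e-05       NA       NA     0.000
#>      Ni      106 3.12e-04 1.36e-03 2.27e-07 9.93e-07     0.000
```

The two-dimensional Monte Carlo run shows the adulteration mixture
driving Hg's upper tail: the median HQ is below 1 but the 95th percentile
is orders of magnitude above it, with a 36.5% probability of exceeding
HQ = 1 in this scenario, while Cr and Ni stay far below both the HQ and
the 10⁻⁶ LCR benchmarks.

A full run (generate → describe → comply → pca → risk, with a manifest
and seed-stamped outputs) is one call:

```r
run_pipeline(run_config(out = "runs/demo", scenario = "asia7", seed = 1))
```

or from a shell via the thin wrapper `inst/cli/cosmetrisk.R`.

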