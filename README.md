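# urbanfrailty

Tools for studying how the quality of the urban environment relates to
frailty, nutritional status and blood markers in community-dwelling older
adults — together with a fully synthetic city-and-cohort generator so the
entire analysis can be developed, tested and reproduced without access to any
real cohort or GIS database.

## Who this is for

Epidemiologists and health-geography researchers who score *urban quality* as
an additive facility-accessibility index and relate it to clinical outcomes.
The package implements, as reusable tidyverse-style functions:

* **The urban-quality summary index.** Each of 7 facility types (fresh-food
  shops, senior centres, pharmacies, emergency health centres, squares and
  parks, family health centres, exercise facilities) is represented as a
  point layer. For each layer a Euclidean distance surface is computed on a
  50-m raster and reclassified into three access zones with scores
  s ∈ {3, 2, 1} (close → 3, distant → 1; for example fresh-food shops use
  < 300 m / 300–600 m / > 600 m). The summary index is the cellwise sum

  I(c) = Σₖ sₖ(c), k = 1..7,  I ∈ [7, 21],

  extracted at each participant's location by spatial join and stratified
  into empirical quartiles Q1–Q4.

* **Clinical scoring.** The Frailty Trait Scale 5 (five domains, each 0–10;
  frail ⇔ total > 25), its shortened FTS-3 subscale, and the CONUT
  nutritional-risk score (graded subscores for serum albumin, total
  lymphocytes and total cholesterol; categories normal 0–1, light 2–4,
  moderate 5–8, severe ≥ 9).

* **The statistical surface.** Welch t / Mann-Whitney two-group contrasts
  with an explicit, logged auto-selection rule; Yates-corrected chi-square
  with Wilson intervals for proportions; Spearman correlations (Pearson on
  midranks, t-approximated p); OLS fits with `tidy()`/`glance()`/`autoplot()`
  methods; and `build_report()`, which assembles the demographic table,
  quartile table, analyte correlation panel and facility-distance contrasts
  in one deterministic, order-invariant object.

* **A calibrated generator.** `simulate_study()` draws a synthetic city
  (homogeneous Poisson facility layers, six sociodemographic clusters) and a
  cohort of 251 older adults whose frailty prevalence (17.5%), group BMI
  (31.5 vs 28.5 kg/m²), quartile handgrip means (22.8 vs 19.1 kg) and
  analyte-vs-index Spearman correlations (e.g. bilirubin 0.33, serum iron
  0.27, CONUT 0.25) are calibrated via a logistic frailty model and a
  Gaussian copula (latent correlation `2 sin(π ρₛ / 6)`).

## Worked example

```r
library(urbanfrailty)
library(dplyr)

study  <- simulate_study(seed = 1)
cohort <- study$cohort |>
  bind_cols(participant_distances(study$cohort[, c("x", "y")],
                                  study$city$layers)) |>
  score_cohort()

report <- build_report(cohort)
report
#> <uf_report> n = 251 (40 frail, 15.9%); 27 analytes in correlation panel
#>   FTS-5 ~ index: slope 0.595, r = 0.136, p = 0.03073

report$table4 |> filter(analyte == "bilirubin")
#> # A tibble: 1 × 4
#>   analyte     rho p_value     n
#>   <chr>     <dbl>   <dbl> <int>
#> 1 bilirubin 0.259  0.0302    70
```

`report` holds tibbles for each panel: `table2` (demographics by frailty
status), `table3` (FTS-5, handgrip, gait and BMI by index quartile with the
Q4-vs-Q1 contrast), `table4` (Spearman ρ of the index against the full
biochemical/haematological panel in the n = 70 laboratory subset), `fig3`
(distance to each facility type by frailty status) and the `fig4`/`fig6`
regression summaries. In this run the frail prevalence is 15.9% and
bilirubin correlates ρ = 0.26 with the index in the laboratory subset —
single-seed draws scatter around the calibrated targets (17.5%, 0.33);
averaged over 200 seeds they land on them (see below).
`autoplot(report, "correlations")` draws the correlation panel;
`autoplot(study$city)` maps the index surface with the facility layers.

The full pipeline (simulate → index → score → analyze) with file artifacts
(GeoJSON layers, ESRI ASCII index raster, cohort CSV, report JSON,
provenance record):

```r
run_pipeline(pipeline_config(seed = 1), "out/")
```

or from a shell, `Rscript inst/cli/urbanfrailty.R all --seed 1 --out out/`.

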