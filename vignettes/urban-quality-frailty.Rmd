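---
title: "Urban quality, frailty and blood markers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Urban quality, frailty and blood markers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(urbanfrailty)
```

This vignette is the package's account of the science it implements: the
accessibility index, the clinical scores, the statistical surface, and —
because no real cohort ships with the package — the synthetic generator whose
calibrated defaults stand in for a study population. It also records the
design decisions taken where more than one defensible choice existed.

## 1. The urban-quality summary index

The index treats urban quality as *access effort*: how far a resident must
travel, in a straight line, to reach each of seven kinds of facility that
matter to older adults. For facility type $k$ with point set $P_k$, the
distance surface on a raster of 50-m cells is

$$ d_k(c) \;=\; \min_{p \in P_k} \lVert \mathrm{centre}(c) - p \rVert_2 , $$

computed exactly (no chamfer or approximate distance transform — the grids
involved are small enough that exactness costs nothing and makes the
brute-force oracle test strict). Each surface is reclassified into three
zones with scores 3/2/1 via two thresholds per type (fresh-food shops
300/600 m, senior centres and pharmacies 500/1000 m, emergency health
centres 1000/2000 m, squares and parks 200/400 m, family health centres
700/1400 m, exercise facilities 400/600 m). The summary index is the
cellwise sum, an integer in $[7, 21]$ for the full layer set, with higher
values meaning better urban quality.

Conventions fixed here, because the zone definitions alone do not fix them:

* **Band boundaries.** The close and distant zones are defined by strict
  inequalities ($d < \text{near}$, $d > \text{mid}$), so a distance exactly
  on either threshold falls in the *medium* zone and scores 2.
* **Distances from cell centres.** The surface value of a cell is the
  distance from its centre, not from its nearest corner or an area average.
* **Point extraction.** Participants receive the value of the cell that
  contains them, with half-open cell extents $[x_0, x_0 + s) \times
  [y_0, y_0 + s)$ — no interpolation (the surface is integer-valued, so
  interpolation would manufacture impossible values), and a point on a
  shared edge belongs to exactly one cell.
* **Coordinates** are planar metres in a local projected frame. A free-text
  CRS tag is carried through I/O but never acted on; the method needs only
  Euclidean geometry.
* **Quartiles** are empirical participant-level quartiles with Q1 closed on
  both sides and Q2–Q4 right-closed, $Q_k = (e_{k-1}, e_k]$. Tied index
  values therefore always share a bin. If all values coincide the edges are
  degenerate: everything is labelled Q1 and a warning is raised.

Because the index is integer-valued with roughly ten occupied levels,
empirical quartile bins are *not* guaranteed to hold 25% each: the whole tie
group at a bin edge goes to the lower bin, which systematically inflates Q1
by up to half the mass of the edge value. This is a property of any coarse
discrete index, not of the implementation; the tests assert the exact
tie-aware bound (cumulative counts exceed $kn/4$ by less than the edge tie
group) rather than a balance the arithmetic cannot deliver.

## 2. Clinical scores

**FTS-5.** Five domains — nutrition, physical activity, nervous system,
strength, gait speed — each scored 0–10, summed to a 0–50 total; frailty is
a *strictly greater than 25* total, so exactly 25 is non-frail. The package
consumes domain scores directly and does not re-derive the instrument
conversion charts from raw measurements (those charts belong to the
instrument, not to this analysis). The shortened FTS-3 sums a configurable
subset of domains; the default is the three physical-performance domains
(physical activity, strength, gait speed), which is an assumption — FTS-3
compositions vary between deployments — and is therefore exposed as a
parameter rather than hard-wired.

**CONUT.** Graded subscores for serum albumin (0/2/4/6 at ≥3.50 /
3.00–3.49 / 2.50–2.99 / <2.50 g/dL), total lymphocytes (0/1/2/3 at ≥1600 /
1200–1599 / 800–1199 / <800 per mm³) and total cholesterol (0/1/2/3 at
≥180 / 140–179 / 100–139 / <100 mg/dL); categories normal (0–1), light
(2–4), moderate (5–8), severe (≥9). The graded bands are the default —
simplified single-cutoff variants in circulation cannot produce totals ≥9
and so cannot express the severe category — but every band edge is
configurable, so a single-cutoff variant can be reproduced by collapsing
bands.

## 3. The statistical surface

* Two-group contrasts use Welch's t (robust to unequal variances) or the
  Mann-Whitney U test. The `auto` policy applies a Shapiro normality screen
  at α = 0.05 per group and falls back to Mann-Whitney when either group
  fails; the decision and its reason are recorded in every result row, and
  the policy can be overridden per call. Mann-Whitney p-values are exact
  (enumeration-equivalent) when both groups have fewer than 50 untied
  observations, and otherwise use the tie-corrected normal approximation
  with continuity correction.
* Proportions are compared with the 2×2 chi-square with Yates continuity
  correction and reported with 95% Wilson score intervals (Wald available).
* Correlations default to Spearman, computed literally as Pearson on
  midranks, with the two-sided p from $t = r\sqrt{(n-2)/(1-r^2)}$.
* Significance is read at α = 0.05 with no multiple-testing correction,
  matching the analysis style the package reproduces; `stats::p.adjust` can
  of course be applied to any result column.
* `build_report()` sorts by participant id before computing anything, so
  the report is invariant to input row order; contrasts whose groups are
  empty or degenerate are emitted as `not_computable` rows, keeping the
  report machine-readable even for pathological cohorts.

## 4. What the synthetic generator emulates

The generator exists so every downstream stage has realistic, fully
reproducible input. It emulates a mid-sized city and an observational cohort
of older adults as a *generative recasting* of a cross-sectional study
design; the real-world analogue is observational, so the causal arrows here
(index → frailty probability, index → analytes) are a modelling convenience,
not a claim.

**City.** A 100×100 grid of 50-m cells (5 × 5 km). Facility layers are
homogeneous Poisson point processes; under that model the nearest-facility
distance satisfies $P(d < r) = 1 - e^{-\lambda \pi r^2}$, and each type's
default intensity is

$$ \lambda \;=\; \frac{\sqrt{\ln 1.5 \cdot \ln 3}}{\pi \, r_{\text{near}}
   r_{\text{mid}}}, $$

the compromise that places both the close-zone and the distant-zone
probabilities as near to 1/3 as the band ratio allows. This yields dense
everyday amenities (parks ≈ 2.7/km²) and sparse emergency centres
(≈ 0.1/km²) and, importantly, spreads the summary index over its range
instead of saturating it. Six cluster seeds partition the grid by nearest
seed; their socioeconomic labels are cosmetic metadata and no SES covariate
enters any generative model.

**Cohort.** For $n = 251$ participants (70 in the laboratory subset):

1. a cluster is drawn by weight and the location scattered
   Normal(seed, 600 m) truncated to the extent;
2. the summary index is computed *through the raster pipeline* at each
   location and standardized to $z$;
3. frailty is Bernoulli with $\operatorname{logit} p = \alpha + \beta z$,
   β = 0.25 per index SD; α is re-solved each cohort by monotone
   root-finding so the cohort-mean probability equals the target prevalence
   0.175 exactly — the marginal prevalence is calibrated while the index
   dependence is preserved;
4. the latent FTS-5 total is a truncated normal — non-frail
   $N(11 + 1.5z,\,6)$ on $[0, 25]$, frail $N(28.5 + 1.5z,\,3.5)$ on
   $(25, 50]$ — drawn by inverse-CDF sampling, so *frail ⇔ total > 25 holds
   by construction*; the total is split into five domain scores by a
   Dirichlet(4) proportion vector with bounded rejection against the 0–10
   domain cap and an equal-split fallback (always feasible for totals ≤ 50).
   The index slope 1.5 makes the index-vs-FTS-5 regression reliably
   positive and significant at this sample size (≈ 90% of seeds), which is
   a designed property of the default scenario;
5. BMI is Normal(31.5, 4.4) for frail and Normal(28.5, 4.5) otherwise; age
   analogous (75.6/7.4 vs 73.8/5.2); handgrip and gait speed are linear in
   $z$ with Gaussian noise. The handgrip coefficients (base 21.22 kg, slope
   −1.44 kg per index SD, noise SD 6.5) were obtained by moment matching:
   the quartile means are linear in (base, slope), so estimating the mean
   $z$ within Q1 and Q4 across simulated cohorts
   (`calibrate_handgrip_slope()`) lets the two target means — 22.8 kg in
   Q1, 19.1 kg in Q4 — be solved exactly rather than searched for;
6. each analyte is drawn from a Gaussian copula with the index: the index
   ranks are mapped to normal scores, mixed with fresh noise at the latent
   correlation $\rho_P = 2\sin(\pi \rho_S / 6)$, and pushed through the
   inverse CDF of the analyte's truncated-normal marginal. Marginal means
   and SDs are typical clinical values for community-dwelling older adults;
   the Spearman targets for the correlated markers are 0.33 (bilirubin),
   0.27 (serum iron), 0.24 (transferrin saturation), 0.26 (RBC), 0.23
   (RDW), with the remaining panel members given the small values a null-ish
   panel shows. The lymphocyte channel (−0.40) is the one *derived* target:
   the CONUT score reacts to the index only through its three banded
   analytes, and with albumin (+0.10) and cholesterol (−0.13) fixed, the
   lymphocyte correlation is the free knob; −0.40 induces a CONUT-vs-index
   Spearman correlation of ≈ 0.25–0.27 after the heavy discretisation of
   the banding, matching the 0.25 target within its tolerance;
7. the laboratory subset is a uniform subsample; analytes outside it are NA.

Everything is driven by a single integer seed; the cohort stream is derived
from the city stream by an integer hash so the two stages never replay the
same random numbers. Identical configuration and seed give byte-identical
CSV/JSON artifacts.

**What it does not emulate.** Street networks and route distances (straight
lines only); spatial clustering of facilities (real amenities co-locate,
which would widen the index distribution); selective migration or
aging-in-place dynamics; inter-analyte dependence beyond what the shared
index factor induces; any causal structure. Tests passing on this generator
show the *pipeline* is correct and the *calibration* reproducible — they say
nothing about real cities or real cohorts.

## 5. Numerical choices and degenerate inputs

* Truncated normals are sampled by inverse CDF (exact, monotone, no
  rejection loops); analyte supports truncate at physiological floors and,
  for transferrin saturation, at 100%.
* The copula uses midrank normal scores of the observed (tied) index;
  discretisation attenuates realised Spearman correlations by roughly 2–4%
  relative to the continuous-copula identity, which is inside every stated
  tolerance and is left uncorrected rather than inflated against.
* Logistic-intercept calibration brackets α in [−50, 50] and solves to
  1e-10; with β = 0 the closed form logit(p) is used.
* Zero-variance inputs error in `correlate()` and `linear_fit()` (slope on
  a constant response is reported with an NA correlation rather than a
  warning); constant index values degrade quartiles to Q1-with-warning.
* Score/index rasters validate their value sets on construction, so a
  mis-wired pipeline fails at the raster boundary, not in a downstream
  table.

## 6. Problem sizes

The default study (100×100 grid, 7 Poisson layers, 251 participants)
simulates in ≈ 0.15 s, so the calibration checks average 200 independent
cohorts — enough to estimate a prevalence to ±0.3 points and a Spearman
mean to ±0.005 — and the exactness checks run the 50×50 brute-force oracle,
the full 0–50 FTS-5 scan and 1000-replicate null simulations of both
two-group tests. These sizes are the package's chosen test conditions, kept
small enough to re-run routinely.

## 7. Known limitations

* The additive equal-weight index oversimplifies the relative importance of
  facility types; weighted or PCA-based variants are out of scope.
* Spatial autocorrelation and the modifiable areal unit problem are not
  addressed; the report treats participants as exchangeable observations.
* The generator's homogeneous facility processes cap the attainable index
  spread (Section 1's discreteness note); a clustered point process would
  be the natural extension.
* FTS-3 composition and the handgrip/gait dependence structure are
  assumptions exposed as configuration, not estimates.
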