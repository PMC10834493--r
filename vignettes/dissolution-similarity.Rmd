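---
title: "Dissolution profile similarity: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissolution profile similarity: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dissim)
```

## The problem

When a generic immediate-release tablet reaches the market, regulators ask
whether it releases its active ingredient the way the brand product does.
For highly soluble, highly permeable (BCS class I) drugs such as
vildagliptin, an in vitro dissolution comparison can stand in for an in
vivo bioequivalence trial: tablets are stirred in a compendial vessel (here
USP apparatus 2, paddle, 50 rpm, 1000 mL of 0.01 N HCl at 37 °C), aliquots
are drawn on a fixed schedule, and the cumulative percent of the label
claim released is read off by HPLC against an external standard. `dissim`
implements the downstream analysis of such a run.

## The similarity statistics

Two mean profiles $R_t$ (reference) and $T_t$ (test), aligned on $n$
sampling times, are compared with the Moore–Flanner factors:

$$f_1 = \frac{\sum_{t=1}^{n} |R_t - T_t|}{\sum_{t=1}^{n} R_t} \times 100,
\qquad
f_2 = 50 \log_{10}\!\left\{\left[1 + \tfrac{1}{n}\sum_{t=1}^{n}
      (R_t - T_t)^2\right]^{-0.5} \times 100\right\}.$$

$f_1$ is the relative cumulative absolute difference (0 for identity,
asymmetric because the reference normalises the sum); $f_2$ is a
logarithmic reciprocal-square-root transform of the mean squared
difference (100 for identity, symmetric, and equal to
$50\log_{10}(100/\sqrt{1+\delta^2})$ under a uniform offset $\delta$, so it
crosses 50 almost exactly at a 10% average offset). The logarithm is base
10; with natural logs the identity value would not be 100 and published
factor tables could not be recovered. Verdicts use the conventional FDA
bands, applied conjunctively by default: *similar* iff $f_1 \le 15$ **and**
$f_2 \ge 50$. An `rule = "f2_only"` escape hatch exists because some
agencies decide on $f_2$ alone. Factors are computed at full floating
precision; only reporting rounds to two decimals, and verdicts always use
the unrounded values.

### Time-point policy

Regulatory practice truncates the comparison one point past the time at
which the reference releases 85%, to stop a long flat plateau from
inflating $f_2$. For very fast-releasing products, however, published
factor tables — including the packaged vildagliptin study, where every
product exceeds 85% at the first sampling time — are computed over the full
grid. The package therefore defaults to `policy = "all"` and offers
`"until_85_plus_one"` behind a flag; the truncation rule always keeps at
least the first point. With the packaged data the truncated policy would
keep only the 10 and 15 min points.

### Prerequisite variability screen

Mean-based $f_2$ is only meaningful when replicate scatter is modest;
`screen_variability()` applies the usual bounds (CV ≤ 20% at the first
time point, ≤ 10% thereafter). Summary-only profiles are screened from
their stored SDs; a profile with no SD (single replicate) is reported *not
assessable* rather than passed or failed.

## Quantitation from peak areas

The working standard concentration follows the two-step volumetric
dilution: `std_mass_mg · purity / std_stock_vol_ml ·
(std_aliquot_ml / std_final_vol_ml)`; the packaged config
(12.84 mg → 25 mL, 2 mL → 20 mL) gives 0.05136 mg/mL. Sample
concentrations are single-point external-standard ratios
$C_i = C_{std} A_i / A_{std}$.

Each withdrawn aliquot (10 mL here) removes drug from the vessel, so
cumulative release at the $i$-th sampling must add back the removed mass:

$$\%_i = 100\,\frac{C_i V_i + w \sum_{j<i} C_j}{\text{label claim}},$$

with $w$ the withdrawal volume and $V_i$ the vessel volume at sampling
$i$ — the full medium volume when withdrawn medium is replaced (the
commonest compendial practice, and the default), or shrinking by $w$ per
prior sampling otherwise. Both modes coincide at $w = 0$. For identical
measured concentrations the no-replacement estimate is never larger,
because only $V_i$ differs and it shrinks. A useful check of the sign
conventions: a profile flat at 100% implies strictly *decreasing* vessel
concentrations under replacement (each replacement dilutes) and exactly
*constant* concentrations without it. Computed cells above 120% of label
claim are flagged (warning plus a per-cell attribute) but not rejected,
since a QC tool must report suspicious runs rather than refuse them;
ordinary profile containers, by contrast, reject values above 120% as
likely fraction-vs-percent unit errors (values modestly above 100% are
normal assay variability and are accepted).

## The synthetic-study generator

Real dissolution data are scarce in public form, so the generator emulates
the structure of a fast-release tablet study: mean curves from a Weibull
model $m(t) = f_\infty(1 - e^{-(t/\tau)^\beta})$ with an optional linear
post-peak decline $d\,(t - t_{peak})$ starting at the first sampling time
where the Weibull term reaches 95% of $f_\infty$. The decline term exists
because real profiles of this kind can drift down ~1–2% late in the run
(degradation/adsorption); a pure monotone model could not mimic that.
Replicates add independent Gaussian noise, truncated at zero, with a
scalar or per-time SD vector so heteroscedastic patterns (e.g. SD 3.5% at
the first point, ~0.8% later) can be copied directly.

The shipped `vildagliptin50` preset uses $f_\infty = 99$, $\tau = 3$ min,
$\beta = 1$, $d = 0.04$%/min, the reference SD column of the packaged
study, $n = 3$ replicates, and six test products with small kinetic
perturbations — chosen once to land generated studies in the same f1/f2
region as the packaged data (f2 roughly 70–98 against the reference).
Seeds are mandatory throughout the generator API and the caller's RNG
stream is saved and restored, so studies are bit-reproducible and no
hidden global state exists. What passing tests on generated data show is
that the *pipeline arithmetic* is correct under realistic magnitudes; the
generator does not emulate inter-batch variance components, tablet-level
content uniformity, or correlated vessel effects, so it says nothing about
how a particular real formulation will behave.

`generate_area_table()` inverts the quantitation chain (solving the
mass-balance recursion forward in time for vessel concentrations, then
scaling to detector areas), which gives the round-trip identity
`percent_released(generate_area_table(p, cfg), cfg) = p` used to test both
replacement modes to 10⁻⁹.

## Numerical and design choices

- **SD convention.** Sample SD ($n-1$ denominator) throughout — the pharma
  QC norm; with $n = 3$ replicates the two conventions differ enough to
  matter, so the choice is pinned by tests.
- **Grid.** At least three strictly increasing positive times; both factors
  are defined for any $n \ge 1$, but fewer than three points is not a
  profile comparison worth reporting.
- **Matched grids.** Profiles are compared only on identical sampling
  schedules; no interpolation is attempted.
- **Reference designation** is always explicit (argument or CLI flag),
  never inferred from label text.
- **Degenerate inputs.** $\sum R_t = 0$ makes $f_1$ undefined and raises;
  a single replicate reports SD as absent, not zero; empty input files fail
  with "no profiles parsed".
- **Round-trip I/O.** Study CSVs are written with 17 significant digits so
  write-then-read preserves doubles exactly.
- **Verdicts are data.** The pipeline runners exit successfully on
  `not_similar` products; only malformed input is an error. A `--strict`
  CLI flag turns failing verdicts into exit status 2 for CI gates.

## Problem sizes

The test suite and the reproduction script use the packaged seven-product
study (5 time points, summary-only), 1000 random profile pairs for the
brute-force factor cross-check, 100 seeded profiles for the quantitation
round trip, and 200 seeds for the generator realism check — sizes at which
every check runs in seconds while Monte-Carlo rates are stable to a few
percent.

## Known limitations

No model-dependent comparison (Weibull/Higuchi fitting to data),
multivariate distance metrics, or bootstrap confidence intervals for
$f_2$; the factors are point statistics of mean profiles, as in standard
regulatory practice. Chromatographic raw data are out of scope — peak
areas enter as a plain table under single-point external-standard
calibration. Whether replicate columns represent vessels or batches is not
modelled; the replicate axis is generic.
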