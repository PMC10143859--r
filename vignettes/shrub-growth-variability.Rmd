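---
title: "Methods: cross-dating and growth-variability analysis for multi-stemmed shrubs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-dating and growth-variability analysis for multi-stemmed shrubs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrubrings)
```

## The problem

Tall multi-stemmed shrubs such as green alder form eccentric, often
elliptical growth rings: on one stem disc the four measured radii
(*a* on the lower, ascending side — usually the longest —, *b* opposite,
*c*/*d* orthogonal) can differ several-fold in width. A clonal individual
(*stock*) carries tens of shoots, and nearby stocks occupy different
microsites (wind-exposed ridge, avalanche gully, intermediate slopes). Any
dendroecological inference — climate response, long-term trend, sampling
design — therefore has to ask first: *at which hierarchical level is the
year-to-year growth signal coherent, and how strongly?*

`shrubrings` answers that with three nested comparisons (radii within a
shoot, shoots within a stock, stock against stock), each built from the
same primitives: conservative detrending, non-parametric and parametric
cross-dating scores, and chronology homogeneity statistics.

## Data model

A `rws` is one dated radius measurement sequence: widths in micrometres
(the measurement precision of stage micrometer systems), one value per
consecutive calendar year, with `0` encoding a ring that is absent at the
measured radius but was inserted during cross-dating. Physically missing
*years* cannot be represented — that distinction (a data error versus a
recorded missing ring) is deliberate. Collections index series by
site/stock/shoot/radius; radial combinations `ab`, `cd`, `abcd` are
per-year arithmetic means of widths (zeros included as true zeros),
computed **on widths, not on indices**, because mean-of-radii series are
themselves objects of interest (their width level matters), and indices
are formed afterwards per series.

Tucson decadal (`.rwl`) files are written at 0.001 mm precision with the
`-9999` terminator; on reading, `999`-terminated (0.01 mm) records are
scaled ×10. An eight-character id convention (site chars 1–2, stock index
char 3, shoot chars 4–5, radius letter char 6) carries the hierarchy
through the format; a delimited sidecar table overrides it when ids cannot.

## Detrending

The age/size trend is removed conservatively, as in classical tree-ring
standardization:

1. modified negative exponential `w(τ) = a·e^(−bτ) + k`, `a, b > 0`,
   `k ≥ 0`, fitted by Levenberg–Marquardt least squares
   (`minpack.lm::nlsLM`, 200 iterations, `ftol` 1e-8), initialized from
   the first/last width contrast, `b₀ = 2/n`, `k₀` at the tail mean;
2. if that fails, is non-declining (decline below 1e-4 of the mean width —
   a numerically flat fit), not everywhere positive, or violates the
   parameter constraints: an OLS line, accepted only with slope ≤ 0 and
   positive predictions;
3. otherwise a horizontal line at the series mean.

Indices are `observed / fitted`; they are dimensionless, scale-equivariant
(`c·w` gives identical indices) and equal 1 exactly for a constant series.
Zero widths stay in the fit (they carry level information) and index to 0.
No spline, RCS or signal-free methods are offered: for series of 19–35
years from shrubs, anything more flexible than the conservative pair
would eat the common signal the analysis is trying to measure.

The Baillie–Pilcher standardization behind `t_BP` is
`ln(100 · w / MA₅(w))` with a centred 5-year moving average; the first and
last two years are dropped rather than shrinking the window, so every
retained value rests on a complete window. Zero widths are floored at 1 µm
before the log (the spacing of the measurement scale), affecting only the
rare inserted missing rings.

The long-term trend filter is a plain discrete-Fourier low-pass: all
coefficients with period strictly shorter than the cutoff (default 3
years) are zeroed, without taper or padding. The DC component is untouched
(output mean equals input mean), and the operator is linear and
idempotent — properties the tests assert directly.

## Synchrony statistics

**Gleichläufigkeit** compares signs of year-to-year changes over the
shared years; a tie (either difference exactly zero) scores ½ — the
classical convention; ties are rare in micrometre data. Significance is
one-sided (synchrony is directional). Under independence each of the
`m = n − 1` intervals is a fair coin, but adjacent intervals share a ring:
for continuous iid series the sign of consecutive differences has lag-1
correlation −1/3, so the agreement indicator of two independent series has
lag-1 autocovariance (−1/3)²/4 = 1/36. The null used is therefore
`Glk ~ N(50, 100²·(m/4 + (m−1)/18)/m²)` (percent scale). The naive
`50/√m` standard deviation, still common in the literature, over-rejects
(about 9–10 % at a nominal 5 % for m ≈ 30); with the first-order
correction the empirical size over 2000 simulated independent pairs stays
within [0.03, 0.07], which the acceptance suite checks.

**t_BP** correlates the two BP-standardized series over their shared
retained years and converts with `t = r·√(N−2)/√(1−r²)`. Correlations
within 1e-12 of ±1 are reported as an infinity *flag* (identical series
produce `cor()` of 1 minus rounding error); flagged values are excluded
from group means, which must stay finite. The conventional acceptance
threshold 3.5 is annotated wherever group means are reported. No p-value
is attached to t_BP itself: autocorrelation and dating multiplicity make a
nominal conversion misleading.

The **misdating screen** is a deliberately simple whole-series
leave-one-out check (not a segment-wise dating program): each series' BP
values are correlated against the mean of the others at lags −2…+2; a best
lag ≠ 0 or a lag-0 correlation below 0.32 (a common dating-control cutoff,
exposed as an argument) flags the series. A positive best lag means the
series matches better when read from later years — its dates appear too
late (e.g. a false ring); the complementary shift marks a missed ring.

## Chronology statistics and sampling design

All Table-style statistics operate on detrended indices. Mean sensitivity
`100·mean(2|xₜ−xₜ₋₁|/(xₜ+xₜ₋₁))` is bounded in [0, 200] % and attains 200
against a missing ring; pairs of consecutive zeros are skipped with a
count. AC is the lag-1 Pearson correlation. Rbar averages pairwise
correlations, by default each over that pair's maximal shared years —
fixed-interval mode exists and is what the eigenvector computation uses,
since a PCA needs a complete matrix. EV comes from the correlation (not
covariance) matrix: indices are dimensionless but heteroscedastic, and
"common variance" should not be dominated by the most variable series.
`S/N = N·r̄/(1−r̄)` and `EPS = S/N/(1+S/N)` are kept as two functions whose
identity the tests pin down exactly; `recommend_n` inverts EPS for the
smallest `N` reaching a target (default 0.85), with a guard loop against
floating rounding at the boundary. Chronologies report unweighted
arithmetic means with median, quartile and 5/95 bands — no biweight
robust mean, matching how such data are usually summarised.

## The pipeline

`run_pipeline` produces, per stock: a sample description (shoot counts,
age and mean ring width with compact significance letters from pairwise
pooled t tests at p ≤ 0.01; letters come from maximal cliques of the
"not-significantly-different" graph), the homogeneity statistics per
radius/combination, the three synchrony levels, extreme-year records and
low-pass trends. Stages fail independently and deterministically; the
report bundle serialises to fixed-format TSV so that two runs on the same
collection are byte-identical.

Two design points were genuinely open:

* **Extreme-year test.** "Different from the preceding year" is tested
  *paired* across shoots (the same shoots are measured in both years);
  an unpaired switch exists. A second, independent-samples test compares
  the year against all other years pooled. No family-wise correction is
  applied by default, matching conventional reporting in this field.
* **Trend classification.** The final five smoothed years are classified
  by their OLS slope with a dead-band of 1 % of the series mean per year;
  below it the trend is "constant". Any verbal
  increasing/constant/decreasing label needs such an operational cutoff;
  1 %/yr is small against the ~40 % mean sensitivity of these series.

## The synthetic stand generator

`generate_stand` draws ring widths multiplicatively:

`W = (a·e^(−bτ) + k) · site_s · radius_r · dist_{s,t} · pulse_t ·
exp(c_t + u_sh + ε)`

with a stand-wide climate year effect `c_t ~ N(0, σ_climate)`, a per-shoot
level effect `u_sh ~ N(0, σ_shoot)`, per-radius-year noise
`ε ~ N(0, σ_noise)`, stock-level disturbance pulses (probability, depth,
duration — mimicking snow-load or avalanche events shared by a stock's
shoots) and optional stand-wide extreme-year pulses. Widths are rounded to
integral micrometres, and values below a threshold become inserted missing
rings (0). The multiplicative (lognormal) structure is the natural one:
widths are positive and the statistics of interest (MS, ratio indices) are
relative. On the log scale two series of one stock have correlation
`σ_climate²/(σ_climate² + σ_noise²)`, which gives the parameter-recovery
tests an analytic target. The draw order (climate; per stock: disturbance;
per shoot: age, level; per radius: noise) is part of the API so seeds stay
stable across refactors.

The frozen defaults (`scenario_paper_like()`) emulate a three-stock
treeline campaign: 15/16/16 shoots × 4 radii, ages 19–35 yr ending 2021,
growth curve (550, 0.08, 300) µm, site multipliers 0.78/1.02/1.09 (the
wind-exposed stock distinctly narrower), radius multipliers
a 1.3 / b 0.8 / c 0.95 / d 0.95 (asymmetric, a-dominant growth),
σ_climate 0.22, σ_shoot 0.15, σ_noise 0.28, disturbance (0.02, 0.5, 2 yr),
pulses ×1.4 in 2003 and ×0.71 in 2016. These were fixed once, by
simulation, to land the generated stands in the regime the analysis
assumes: stock mean widths around 450–650 µm, detrended mean sensitivity
mostly within 35–50 %, low first-order autocorrelation, single-radius Rbar
near 0.4–0.5 and EPS of 15-shoot groups well above 0.85. Most of the
year-to-year variance sits in the radius-year noise rather than the
common climate effect: with ~20 usable intervals per series, a
climate-dominated mean sensitivity would be a property of one realized
climate path and swing wildly between seeds, whereas noise-driven
variability averages across 60 series per stock.

What the generator does **not** emulate: temporal autocorrelation of the
climate signal (generated AC is near 0; field AC can reach ~0.4), false
rings, wedging or lobed growth, within-shoot correlation of radii beyond
the shared year effects, age-dependent noise, and any process-based
growth mechanism. Tests passing on these stands therefore validate the
*statistical machinery* — estimator definitions, calibration, power —
not the biology of any particular field data set.

## Numerical conventions and test scale

Degenerate inputs have defined behaviour rather than surprises: constant
series detrend to indices of exactly 1; zero-variance samples give
`t = 0, p = 1` (equal means) or an infinity flag (unequal); a correlation
of ±1 is flagged, not an exception; validators report findings instead of
raising. Glk values are exact multiples of ½ and are compared bit-exactly
against a brute-force oracle in the tests.

The test suite's simulation sizes were chosen to make the checks sharp but
quick: 1000 random pairs for the Glk oracle, 2000 pairs for its null
calibration, 500 white-noise pairs for the t_BP null, 50 scenario
replicates for parameter recovery, and 200 replicates each for the power
and size of the extreme-year test (power against a ×1.6 single-year pulse
with no other common signal and a flat age curve; size on the matching
null stands — with an age-declining curve adjacent years differ truly, so
rejections there would not be type-I errors). The full suite and the
acceptance script run in a few minutes on one core.

## Limitations

* The dating screen is whole-series; it will miss a dating error confined
  to a short early segment of a long series.
* EPS/SNR treat series as exchangeable within a group; systematic
  radius-level differences are handled by analysing radii separately (as
  the pipeline does), not by a mixed model.
* The Glk null assumes continuous, serially exchangeable changes; strong
  autocorrelation in real indices makes the test anti-conservative, which
  is one reason t_BP (overlap-adjusted, threshold-based) is reported
  alongside.
* `basal area increment` is out of scope: with strongly eccentric rings a
  reliable BAI needs full-disc geometry, not four radii.
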