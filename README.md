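# shrubrings

Growth-ring analysis for tall multi-stemmed shrubs.

Dendroecological work on shrubs such as green alder (*Alnus alnobetula*) at
the alpine treeline faces a replication problem that classic tree-ring
software ignores. Stems grow ascending and eccentric, so the four radii
(`a` = lower stem side and usually longest, `b` = opposite, `c`/`d`
orthogonal) of one stem disc can differ strongly in width; one clonal
individual (a *stock*) carries dozens of *shoots*; and neighbouring stocks
sit in different microsites and disturbance regimes. Before ring widths can
be used for climate or trend inference one has to know **at which level of
the hierarchy the year-to-year signal is coherent** — and how many radii,
shoots and stocks a sampling design therefore needs.

`shrubrings` implements that analysis end to end:

* **Series management & IO** — dated ring-width series in micrometres
  (`rws`), hierarchical collections with selection by
  site/stock/shoot/radius, Tucson decadal `.rwl` and delimited wide-table
  readers/writers, a metadata sidecar, radial combinations
  (`ab`, `cd`, `abcd` means) and a structural validator. A missing ring is
  an explicit zero.
* **Conservative detrending** — a modified negative exponential
  `w(τ) = a·e^(−bτ) + k` (falling back to a non-positive-slope line, then a
  horizontal mean) turns widths into dimensionless indices
  `observed / fitted`; plus the Baillie–Pilcher log standardization
  `ln(100·w / MA₅(w))` and an FFT low-pass trend filter.
* **Cross-dating synchrony** — Gleichläufigkeit
  (`Glk`, % of agreeing year-to-year signs, ties scoring ½) with a
  calibrated one-sided significance test; the overlap-adjusted
  `t = r·√(N−2)/√(1−r²)`; the Baillie–Pilcher `t_BP` score (with the
  conventional 3.5 dating threshold); pairwise matrices and a leave-one-out
  misdating screen.
* **Chronology statistics** — mean sensitivity (MS), first-order
  autocorrelation (AC), mean inter-series correlation (Rbar),
  `S/N = N·r̄/(1−r̄)`, the expressed population signal
  `EPS = S/N / (1 + S/N)` with the 0.85 convention, first-eigenvector
  variance (EV), chronologies with spread bands, and a sample-size
  calculator that inverts the EPS formula.
* **The three-level pipeline** — radii within shoot, shoots within stock,
  stock versus stock comparisons, extreme-year tests, low-pass growth
  trends, and a deterministic report bundle.
* **A synthetic stand generator** — seeded, hierarchical, multiplicative
  (lognormal) ring-width simulation whose frozen default scenario mimics a
  three-stock treeline sampling campaign; it backs every statistical test
  in the package.

## Worked example

```r
library(shrubrings)

stand <- generate_stand(scenario_paper_like(seed = 3))
stand
#> <rws_collection> 188 series, 3 stock(s), 47 shoot(s)

## homogeneity of radius-a series within the wind-exposed stock
group_stats(select_series(stand, stock = "WE1", radius = "a"))
#> <chronology_stats> N=15 [2003-2021]  MS 41.6%  AC 0.102  Rbar 0.523  S/N 16.4  EPS 0.943  EV 56.4%

## how many radius-a series would that correlation structure need?
recommend_n(0.523)
#> [1] 6

## cross-dating two shoots of the same stock
a <- select_series(stand, stock = "WE1", shoot = "01", radius = "a")$series[[1]]
b <- select_series(stand, stock = "WE1", shoot = "02", radius = "a")$series[[1]]
tbp(a, b)
#> <sync_result> Glk 68.4% (p=0.0722, N=20), r=0.687, t_BP=3.54 (n=16)

## the full three-level report
rep <- run_pipeline(stand, list(extreme_years = c(2003, 2016)))
rep$description[, c("stock", "n_shoots", "rw_mean", "rw_sd", "rw_letters")]
#>   stock n_shoots  rw_mean    rw_sd rw_letters
#> 1   AG3       16 570.8067 97.53030          a
#> 2   IM2       16 562.9024 98.53390          a
#> 3   WE1       15 407.5010 89.76079          b
```

Reading the output: the 15 radius-a series of stock `WE1` share a mean
inter-series correlation of 0.52 over the 2003–2021 common interval, giving
a signal-to-noise ratio of 16.4 and an EPS of 0.943 — comfortably above the
0.85 acceptability threshold, which six series would already reach
(`recommend_n`). Mean sensitivity near 42 % marks a highly responsive,
environmentally forced growth signal. The two example shoots agree in 68 %
of their year-to-year changes and reach `t_BP` 3.54, just at the 3.5 dating
threshold. In the sample description, the wind-exposed stock's rings
(408 µm) are significantly narrower than the other stocks' (letters `b`
vs `a`, pooled t tests at p ≤ 0.01); `run_pipeline` further returns the
statistics table per radius/combination, all three synchrony levels,
extreme-year tests and low-pass growth trends, and
`write_report_bundle()` serialises everything as deterministic TSV.

IO works with standard formats:

```r
write_rwl(stand, "stand.rwl")          # Tucson decadal, 0.001 mm precision
stand2 <- read_rwl("stand.rwl")        # hierarchy parsed from the 8-char ids
write_rw_table(stand, "stand.tsv")     # year x series wide table
```

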