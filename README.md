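# infradian

Chronobiological analysis of menstrual cycle length series in R.

The menstrual cycle is an infradian biological rhythm: each woman's cycle
length fluctuates around a personal circa-monthly period. `infradian`
provides the toolkit a rhythm analyst would apply to series of consecutive
cycle lengths — the same procedures classically used for circadian data,
adapted to day-resolved, cycle-indexed records:

- **Normalized actograms.** For a woman with cycle lengths `d_1, ..., d_n`
  and reference period `T = mean(d_i)` (her estimated infradian period), the
  actogram offset is the cumulative sum `c_i = sum_{j<=i} (d_j - T)`, the
  phase advance/delay of each successive onset relative to a perfectly
  periodic rhythm. The offsets are decomposed additively into a long trend
  (Gaussian kernel smoothing over ~12 cycles, about one year), a
  band-limited oscillatory component (asymmetric Christiano–Fitzgerald
  band-pass filter, periods 3–12 cycles), and a residual. Oscillations
  ("wavelets" — one full excursion right then left of the reference) are
  detected as paired opposite-sign runs of the band component, keeping only
  those of 4+ cycles, and classified as *stable*, *after a phase jump* (an
  abrupt cycle lengthening), or *accompanied by fluctuations*.
- **Serial dependence.** Per-woman autocorrelation (divisor-n estimator)
  and partial autocorrelation (Durbin–Levinson) of cycle lengths to lag 6,
  averaged unweighted across women, with significance calibrated by a
  within-woman permutation Monte Carlo null: each replicate independently
  permutes every woman's lengths, recomputes the average, and the observed
  average's rank among the replicates gives the p-value (two-sided,
  Bonferroni-corrected across lags).
- **Lunar phase association.** Onset dates are mapped to lunar phase angles
  (constant 29.53059-day synodic month from a reference new moon) and
  binned into the eight canonical 45°-wide phases centered on new moon,
  waxing crescent, ..., waning crescent. Uniformity is tested with Pearson
  chi-square (7 df), the Rayleigh test on grouped data (`Z = N * Rbar²`
  with unit vectors at bin centers and the finite-sample-corrected
  p-value), a per-woman Rayleigh test on circular mean onset phases, and a
  Monte Carlo *series-shift* test whose null shifts each woman's whole
  series by a uniform 0–29-day offset, preserving her internal cycle
  structure while destroying lunar alignment.
- **Synthetic cohorts.** A generator producing series with a per-woman mean
  period, sinusoidal oscillations, AR(1) noise, occasional jump cycles, and
  optional von Mises coupling of onsets to the lunar cycle — so the whole
  pipeline is testable end-to-end without any external data.

## Worked example

```r
library(infradian)

p <- simulation_params(mu = 29, sigma = 2, osc_amplitude = 2, osc_period = 6,
                       ar1 = 0.3, jump_prob = 0.03, jump_magnitude = 12,
                       n_cycles = 24, seed = 1)
co <- generate_cohort(150, p, seed = 20)
co
#> <cycle_cohort> 150 women, 3600 cycles [synthetic]

res <- cohort_wavelets(co, min_series_len = 18)
res$summary$by_context
#>            stable        after_jump with_fluctuations
#>               352               102                90
```

3600 cycles from 150 women; the pipeline detects 544 wavelets (3.6 per
woman), most in a stable state — oscillation of the cycle length around the
personal period without any triggering long cycle, the signature of
relative coordination.

```r
permutation_test(co, "acf", n_perm = 1000, seed = 30, min_series_len = 13)
#> Within-woman permutation test of average ACF (150 women, 1000 replicates)
#>  lag observed null_mean null_sd      z     p significant
#>    1   0.1984   -0.0417  0.0151  15.94 0.002           *
#>    2  -0.1240   -0.0396  0.0142  -5.95 0.002           *
#>    3  -0.2463   -0.0378  0.0143 -14.61 0.002           *
#>    ...
```

The generator's AR(1)+sinusoid structure shows up as average
autocorrelations far outside the permutation null (note the null mean is
not 0: permutation of short series has a finite-sample negative bias, which
is exactly why the test calibrates against permuted data rather than
against 0).

```r
tab <- count_onsets_by_phase(co)
chi_square_uniformity(tab)
#> chi_square: statistic = 9.4089, n = 3600, p = 0.2246
rayleigh_grouped(tab)
#> rayleigh_grouped: statistic = 1.9486, n = 3600, p = 0.1425
monte_carlo_shift_test(co, n_iter = 1000, seed = 40)$ranks["new"]
#>   new
#> 0.487
```

This cohort was generated without lunar coupling, and all three tests
agree: onset phases are uniform. Regenerate with `lunar_kappa = 2,
lunar_mu = 0` and the new-moon bin's shift-test rank rises above 0.975.

Published 8-bin onset counts for two large cohort studies (European and
North American) ship as a plain-text fixture (`published_onset_counts()`)
and reproduce their printed test results, e.g. chi-square p = 0.0214 and
grouped Rayleigh p = 0.0056 on the 26,912 European cycles.

A thin command-line wrapper over the same functions is at
`inst/cli/infradian.R` (subcommands `simulate`, `select`, `actogram`,
`autocorr`, `lunar`).

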