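---
title: "Methods: infradian analysis of menstrual cycle series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infradian analysis of menstrual cycle series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infradian)
```

This vignette documents the statistical model behind each stage of the
package, the conventions and default parameters, and the design choices
made where several reasonable options existed. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The analysis problem

The unit of analysis is one woman's series of consecutive menstrual cycle
lengths `d_1, ..., d_n` (whole days; the first day of menstrual bleeding is
the first day of a cycle), anchored to the calendar date of the first
onset. Three questions are asked of such series:

1. Does the cycle length oscillate around a personal period in a structured
   way (trends, phase jumps, transient oscillations resembling relative
   coordination)?
2. Is the length of a cycle correlated with the lengths of the preceding
   cycles?
3. Are onset dates aligned with the 29.53-day synodic lunar cycle?

## Cohort selection

`apply_selection()` truncates each series at the cycle *preceding* its
first cycle longer than 60 days — an abnormally long cycle typically marks
a pregnancy or another censoring event, so the offending cycle and
everything after it are dropped, not just the one cycle — and then removes
series left shorter than a minimum length (18 cycles for wavelet
statistics, 13 or 7 for the correlation analyses, depending on how long the
cohort's series are). `subset_by_mean_length()` implements the [28, 30]-day
sensitivity subset as a *per-woman mean* filter with closed bounds,
comparing the exact rational mean (a per-cycle filter on 28–30-day cycles
would be a different analysis; the per-woman version is the one that
matches cohort-level count tables). Original-study eligibility filters
(age, pregnancy outcomes) are out of scope: the schema carries no such
fields.

## Actograms

The actogram normalizes each woman to her own rhythm. Her reference period
`T` is the arithmetic mean cycle length — the natural estimate of the
infradian period, playing the role the 24-h day plays in circadian rasters
— and the offset series is the cumulative sum `c_i = sum_{j<=i} (d_j - T)`.
Because `T` is the sample mean, `c_n = 0` identically: the actogram
describes excursions around the period, not the period itself. Offsets are
decomposed additively as

```
offsets = trend + band + residual
```

with the residual defined as the remainder, so the reconstruction is exact
by construction.

**Long trend.** The package uses Nadaraya–Watson regression on cycle index
with a Gaussian kernel whose full width at half maximum is the trend
window (default 12 cycles, about one year), i.e. bandwidth
`sd = 12 / (2 sqrt(2 ln 2)) ≈ 5.1` cycles. Weights are renormalized at the
series ends rather than padding the series; the smoother preserves
constants exactly and reproduces linear drifts in the interior.

**Band-pass.** Oscillations are isolated with the asymmetric
Christiano–Fitzgerald approximation to the ideal band-pass filter (the
random-walk variant, whose endpoint weights make every weight row sum to
zero, so constants map to zero and the filter is linear and usable up to
the series ends, at the cost of increased distortion there). The default
band passes periods of 3 to 12 cycles: the upper edge matches the trend
window (oscillations of interest last less than a year), the lower edge
sits above the 2-cycle Nyquist floor so that pure alternation is treated
as noise. The implementation was verified against an independent reference
implementation of the same filter during development; its gain properties
(pass-band gain within 20% of unity, Nyquist attenuation below 25% in RMS)
are asserted in the test suite with injected sinusoids.

**Wavelets.** A wavelet is one full oscillation: a pair of adjacent
opposite-sign runs of the band component (an excursion to one side of the
reference and the return excursion). Its duration is the total cycle count
of the two runs; unpaired terminal runs are dropped; wavelets shorter than
4 cycles are discarded as irregularities. Amplitude is the *peak* absolute
band value inside the wavelet (not peak-to-peak): "an amplitude of k days"
reads as a one-sided excursion of k days from the reference, and the
3-day large-amplitude flag is inclusive at the threshold.

**Context classification.** Each wavelet receives exactly one label.
*after_jump*: a jump cycle — length exceeding the reference period by more
than `jump_threshold` days (default 5; the threshold is a free parameter
because "abrupt lengthening" has no canonical quantitative definition, and
it is exposed on every interface) — occurs within the 2 cycles before the
wavelet or in its first half. *with_fluctuations*: the RMS of the residual
inside the wavelet exceeds the wavelet's amplitude, i.e. the unstructured
variability is larger than the oscillation it accompanies. Otherwise
*stable* — the configuration of interest, an oscillation arising without
any triggering event.

## Serial dependence

**Estimators.** Per-woman ACF uses the divisor-n (biased) estimator, the
standard time-series convention; PACF comes from the Durbin–Levinson
recursion on those autocorrelations (the Yule–Walker solution), which the
test suite checks against a direct Toeplitz-system solve on short random
series. Constant series have undefined correlations; they are flagged,
excluded, and counted. No de-trending is applied before the ACF — none is
part of the procedure being implemented.

**Averaging.** The cohort statistic is the *unweighted* mean of per-woman
values over eligible women (series of at least `min_series_len` cycles):
each woman contributes equally regardless of series length.

**Permutation null.** Exchangeability within woman is the null: each
replicate independently and uniformly permutes every woman's lengths and
recomputes the cross-woman average. Permuting preserves each woman's
multiset of lengths — which is why this null, unlike a comparison against
0, automatically absorbs the finite-sample negative bias of the ACF
estimator on short series. Per-woman RNG substreams are derived
deterministically from the master seed, so results are reproducible and
independent of cohort ordering. Per lag, each tail's p is the add-one rank
`(1 + #exceedances) / (n_perm + 1)` with ties counted as exceedances; the
smaller tail is doubled and capped at 1 (two-sided reporting; the doubling
convention is stated here because a symmetric-tail-count alternative
exists and gives slightly different values). The z-score is
`(observed − null mean) / null SD` from the same null sample. Significance
flags are Bonferroni-corrected across the 6 lags at family level 0.05,
i.e. 0.025 per side before correction. The default 5000 replicates give a
minimum two-sided p of about 4e-4; the calibration suite uses 500
replicates, which is sufficient to test size at the 0.05 level.

## Lunar phase analysis

**Phase rule.** Phase is arithmetic: `angle = 360 * frac((date − epoch) /
29.53059)` degrees, with the reference new moon at 2000-01-06 18:14 UTC
and onsets taken at civil midnight (day-resolved records carry no time of
day). A true ephemeris deviates from the constant-period rule by less than
±0.6 day, well under the 3.69-day half-width of a phase bin; both epoch
and period are configurable, so an ephemeris backend can replace the rule
behind the same interface.

**Bins.** The eight phases are 45° wide and *centered* on the principal
angles: the new moon bin spans [337.5°, 22.5°). This convention is not
arbitrary: with bin-center unit vectors it makes the grouped Rayleigh test
reproduce, from the published count tables shipped in
`inst/extdata/onset_phase_counts.csv`, the p-values printed alongside them
(0.0056 and 0.0226 for the two total cohorts) — which is the acceptance
check run by `scripts/acceptance.R`.

**Tests.** Pearson chi-square against equal expected counts (7 df) treats
the bins as unordered categories. The grouped Rayleigh test respects their
circular order: `Rbar` is the mean resultant length of the count-weighted
bin-center unit vectors, `Z = N * Rbar²`, and the p-value uses the
standard finite-sample correction (Zar's series), clamped to [0, 1] with
the clamp logged. The per-woman Rayleigh test addresses the
non-independence of cycles within woman: each woman is reduced to the
circular mean of her onset angles (undefined on antipodal cancellation,
resultant < 1e-9; such women are excluded and counted) and the same
test is applied, unbinned, to those means.

**Series-shift Monte Carlo.** The shift test keeps every woman's observed
cycle lengths — hence all within-series structure — and randomizes only
the alignment of her series with the lunar cycle, adding an independent
uniform integer 0–29 days to her first start date per replicate. Per
phase, the observed count's position within the replicate distribution is
reported as a rank in [0, 1] using the mid-tie convention
`(#{sim < obs} + (#{sim = obs} + 1)/2) / (n_iter + 1)`: counts are
discrete, and counting ties to one side would bias ranks and break their
null uniformity, which the calibration suite verifies by a
Kolmogorov–Smirnov test on pooled ranks. A phase is flagged at rank
< 0.025 or > 0.975; Bonferroni across the 8 phases is off by default,
since the per-phase positions are reported in full.

**Smoothing for display.** `circular_smooth()` is a von Mises kernel
density on the bin counts, renormalized so its numerical integral equals
the total count. The default 30° kernel SD is chosen so that exactly
uniform counts smooth to a flat density (ripple < 0.3%); narrower kernels
re-expose the 45° binning as spurious ripple.

## The synthetic generator

`generate_series()` is a stand-in for endogenous cycle dynamics, not a
fitted physiological model. Around a per-woman mean `mu` it adds,
additively: a sinusoid (amplitude in days, period in cycles) emulating
relative-coordination oscillations; an AR(1) residual (innovation SD
`sigma`, coefficient `ar1`) applied after removing the sinusoid, giving
controlled serial correlation; and memoryless Bernoulli jump cycles
(probability `jump_prob`, magnitude `jump_magnitude` days) emulating
occasional abrupt lengthenings. Lengths are rounded half-up to whole days
— the records being emulated are day-resolved — and clipped at a 10-day
floor (clips are counted and reported; they occur only under extreme
parameters). Lunar coupling is implemented by *placement of the series
start date* via a von Mises draw (concentration `lunar_kappa`, preferred
angle `lunar_mu`), never by altering lengths — mirroring the logic of the
shift-test null, which likewise moves whole series. Start dates are
otherwise uniform over 1960–1997 (the collection era of the classic
European cycle databases; ~470 synodic periods, so day-resolved uniform
draws are uniform in phase).

What the generator does **not** emulate: age-related drift of the mean
period, heteroscedastic noise, asymmetric (shortening) jumps, correlation
between a woman's mean and her variability, and any hormonal mechanism.
Tests passing on synthetic cohorts therefore validate the *statistical
machinery* — calibration, power against the encoded alternatives,
invariants — not claims about real populations.

Scenario parameters used by the calibration and power suites, chosen once
as realistic study conditions: null cohorts of 100 women × 20 iid cycles
(mu 28 d, sigma 2 d) for permutation-test size, 200 such cohorts at 500
replicates; power cohorts with `ar1 = 0.4` (100 women × 20 cycles, 50
runs); lunar-null cohorts of 100 women × 10 cycles (200 cohorts, 500
iterations); lunar-power cohorts of 200 women × 15 cycles with
`lunar_kappa = 2`, `lunar_mu = 0` and mean period 29.5 d with sigma 1 d —
cycles must track the synodic period for entrainment to remain observable
over a series, which is the same reason the sensitivity subset restricts
to near-synodic [28, 30]-day means.

## Numerical conventions and degenerate inputs

- Rounding of simulated lengths: half away from zero (`floor(x + 0.5)`),
  so a mean of 29.5 yields 30-day cycles, not banker's rounding.
- Quantiles in cohort summaries: type 7 (linear interpolation), R's
  default.
- Half-way phase angles (22.5° etc.) round *up* into the next bin.
- `build_actogram()` needs only 2 cycles; trend and band are NA when the
  series is shorter than the trend window or twice the minimum band
  period, and wavelet statistics enforce 18+ cycles.
- Zero-variance series: flagged NA in ACF/PACF, excluded and counted in
  averages and permutation tests (permutation cannot un-flatten them).
- Empty cohorts are legal everywhere except `summarize_cohort()` and the
  test statistics, which raise informative errors.
- All Monte Carlo machinery takes explicit integer seeds; identical seeds
  give bit-identical results, and per-woman substreams keep cohorts
  order-independent.

## Known limitations

- The arithmetic lunar phase rule drifts up to ~0.6 day from a true
  ephemeris within the supported era; irrelevant at 45° bins, but an
  ephemeris should replace it for finer binning.
- The grouped Rayleigh p-value correction is asymptotic in N and can
  exceed [0, 1] for tiny N with extreme concentration; it is clamped and
  the clamp reported.
- Wavelet duration is measured between zero crossings of the filtered
  band, so edge wavelets (within ~half a band period of the series ends)
  are distorted by the asymmetric filter; interior wavelets are the
  reliable ones, and the recovery tests assert exactly that.
- The permutation test assumes within-woman exchangeability under the
  null; a woman with a strong trend violates it, which is a feature (the
  test detects structure) but means "significant" is not specific to
  autocorrelation at one lag.
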