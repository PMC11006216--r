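Package: infradian
Title: Infradian Rhythm Analysis of Menstrual Cycle Length Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for chronobiological analysis of series of consecutive
    menstrual cycle lengths. Builds per-woman normalized actograms
    (cumulative deviation from the individual mean period), decomposes them
    into a long-term trend (kernel smoothing) and a band-limited oscillatory
    component (asymmetric Christiano-Fitzgerald band-pass filter), and
    detects and classifies oscillations ("wavelets"). Tests serial
    dependence of successive cycle lengths with per-woman ACF/PACF averaged
    across women and calibrated by a within-woman permutation Monte Carlo
    null. Tests association between menstruation onset and the 29.53-day
    synodic lunar cycle with Pearson chi-square, grouped and per-woman
    Rayleigh tests, and a Monte Carlo series-shift null. Includes a
    synthetic cohort generator with per-woman mean period, autocorrelated
    oscillations, phase jumps, and optional von Mises lunar phase coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
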