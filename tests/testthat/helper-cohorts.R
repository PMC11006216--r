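# Shared builders for test cohorts.

constant_series <- function(len = 28, n = 20, id = "w1",
                            start = "2000-01-01") {
  cycle_series(id, start, rep(len, n))
}

# iid-noise cohort: no oscillation, no AR, no jumps
iid_cohort <- function(n_women = 100, n_cycles = 20, sigma = 2, seed = 1) {
  generate_cohort(n_women,
                  simulation_params(mu = 28, sigma = sigma,
                                    n_cycles = n_cycles),
                  seed = seed)
}

# lunar_config giving exact phase control: epoch at civil midnight so a
# Date k days after the epoch has phase exactly 360*k/period
midnight_config <- function(period) {
  lunar_config(synodic_period = period,
               epoch = as.POSIXct("2000-01-06 00:00:00", tz = "UTC"))
}

table3_counts <- function(which_row) {
  f <- published_onset_counts()
  phase_count_table(as.integer(f[which_row, lunar_phases]))
}
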