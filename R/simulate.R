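#' Parameters for the synthetic cycle-series generator
#'
#' The generator emulates the three qualitative regimes seen in real
#' normalized actograms: long-term stability with occasional abrupt
#' lengthenings (phase jumps), stability with superimposed oscillations
#' shorter than a year (relative coordination), and stability with rapid
#' random fluctuations. Around a per-woman mean period \code{mu} it adds,
#' additively: a sinusoid of amplitude \code{osc_amplitude} (days) and
#' period \code{osc_period} (cycles); an AR(1) residual with coefficient
#' \code{ar1} and innovation SD \code{sigma} (days); and memoryless
#' Bernoulli jump cycles of probability \code{jump_prob} adding
#' \code{jump_magnitude} days. Lengths are rounded to whole days (half up)
#' and floored at 10 days.
#'
#' @param mu mean cycle length, days (> 0). Default 28.
#' @param sigma innovation SD of the noise/AR residual, days (>= 0).
#' @param osc_amplitude oscillation amplitude, days (>= 0).
#' @param osc_period oscillation period, cycles (>= 2 when amplitude > 0).
#' @param ar1 lag-1 autoregressive coefficient, |ar1| < 1.
#' @param jump_prob per-cycle probability of an abrupt lengthening, in [0,1].
#' @param jump_magnitude added length of a jump cycle, days.
#' @param lunar_kappa von Mises concentration of onset coupling to the lunar
#'   cycle (0 = no coupling).
#' @param lunar_mu preferred lunar phase angle, degrees (0 = new moon,
#'   180 = full moon).
#' @param n_cycles series length, cycles (>= 1).
#' @param seed integer RNG seed.
#' @return A validated list of class \code{simulation_params}.
#' @export
simulation_params <- function(mu = 28, sigma = 0, osc_amplitude = 0,
                              osc_period = 6, ar1 = 0, jump_prob = 0,
                              jump_magnitude = 10, lunar_kappa = 0,
                              lunar_mu = 0, n_cycles = 20, seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("simulation_params: '%s' %s", field, msg),
                  call. = FALSE)
  }
  chk(is.numeric(mu) && mu > 0, "mu", "must be > 0")
  chk(is.numeric(sigma) && sigma >= 0, "sigma", "must be >= 0")
  chk(is.numeric(osc_amplitude) && osc_amplitude >= 0, "osc_amplitude",
      "must be >= 0")
  chk(osc_amplitude == 0 || osc_period >= 2, "osc_period",
      "must be >= 2 cycles when osc_amplitude > 0")
  chk(is.numeric(ar1) && abs(ar1) < 1, "ar1", "must satisfy |ar1| < 1")
  chk(is.numeric(jump_prob) && jump_prob >= 0 && jump_prob <= 1,
      "jump_prob", "must be in [0, 1]")
  chk(is.numeric(jump_magnitude), "jump_magnitude", "must be numeric")
  chk(is.numeric(lunar_kappa) && lunar_kappa >= 0, "lunar_kappa",
      "must be >= 0")
  chk(is.numeric(lunar_mu), "lunar_mu", "must be numeric degrees")
  chk(is.numeric(n_cycles) && n_cycles >= 1 && n_cycles == round(n_cycles),
      "n_cycles", "must be an integer >= 1")
  structure(list(mu = mu, sigma = sigma, osc_amplitude = osc_amplitude,
                 osc_period = osc_period, ar1 = ar1, jump_prob = jump_prob,
                 jump_magnitude = jump_magnitude, lunar_kappa = lunar_kappa,
                 lunar_mu = lunar_mu, n_cycles = as.integer(n_cycles),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Generate one synthetic cycle series
#'
#' Cycle length i is
#' \code{round(mu + A*sin(2*pi*i/P + phi0) + r_i + jump_i)}, where
#' \code{phi0} is a random initial phase, \code{r_i} is an AR(1) residual
#' (\code{r_i = ar1*r_{i-1} + eps_i}, \code{eps_i ~ N(0, sigma^2)}) applied
#' after removing the sinusoid, and \code{jump_i} is a Bernoulli jump.
#' Rounding is half up and lengths are clipped at a 10-day floor (a clip is
#' reported via a message and counted in the \code{"n_clipped"} attribute).
#' Output is bit-identical for identical parameters and seed.
#'
#' @param params a \code{\link{simulation_params}} object.
#' @param first_start calendar date of the first onset.
#' @param woman_id identifier for the emitted series.
#' @return A \code{\link{cycle_series}}.
#' @examples
#' p <- simulation_params(mu = 28, sigma = 0, n_cycles = 5)
#' generate_series(p, "2000-01-01")$lengths  # all 28
#' @export
generate_series <- function(params, first_start = as.Date("2000-01-01"),
                            woman_id = "sim") {
  if (!inherits(params, "simulation_params"))
    params <- do.call(simulation_params, as.list(params))
  n <- params$n_cycles
  raw <- .with_seed(params$seed, {
    phi0 <- runif(1, 0, 2 * pi)
    osc <- if (params$osc_amplitude > 0)
      params$osc_amplitude * sin(2 * pi * seq_len(n) / params$osc_period + phi0)
    else rep(0, n)
    eps <- if (params$sigma > 0) rnorm(n, 0, params$sigma) else rep(0, n)
    r <- numeric(n)
    prev <- 0
    for (i in seq_len(n)) {
      prev <- params$ar1 * prev + eps[i]
      r[i] <- prev
    }
    jump <- if (params$jump_prob > 0)
      rbinom(n, 1L, params$jump_prob) * params$jump_magnitude
    else rep(0, n)
    params$mu + osc + r + jump
  })
  lengths <- .round_half_up(raw)
  clipped <- lengths < 10
  if (any(clipped)) {
    message(sprintf("generate_series: %d length(s) clipped to the 10-day floor",
                    sum(clipped)))
    lengths[clipped] <- 10
  }
  out <- cycle_series(woman_id, first_start, lengths)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Generate a synthetic cohort
#'
#' Each woman gets an independent RNG substream derived from the master
#' seed, a first onset date drawn uniformly from \code{start_window} (so
#' onset lunar phases are uniform when no coupling is requested), and a
#' series from \code{\link{generate_series}}. If \code{lunar_kappa > 0} in
#' her parameters, \code{\link{apply_lunar_coupling}} then places her series
#' start so onsets concentrate around \code{lunar_mu}.
#'
#' @param n_women number of women (>= 1).
#' @param params a \code{\link{simulation_params}} used for every woman, or
#'   NULL if \code{params_sampler} is given.
#' @param params_sampler optional \code{function(i)} returning the
#'   \code{simulation_params} for woman i (its \code{seed} field is
#'   overridden by the derived per-woman seed).
#' @param seed master integer seed.
#' @param start_window two dates between which first onsets are drawn;
#'   default 1960-01-01 to 1997-12-31, the collection era of classic
#'   European cycle databases (about 470 synodic periods, so day-resolved
#'   uniform draws are uniform in lunar phase).
#' @param label cohort label.
#' @return A \code{\link{cohort}} of \code{n_women} series.
#' @export
generate_cohort <- function(n_women, params = simulation_params(),
                            params_sampler = NULL, seed = 1L,
                            start_window = as.Date(c("1960-01-01",
                                                     "1997-12-31")),
                            label = "synthetic") {
  if (n_women < 1)
    stop("generate_cohort: n_women must be >= 1", call. = FALSE)
  start_window <- as.Date(start_window)
  span <- as.integer(start_window[2] - start_window[1])
  series <- vector("list", n_women)
  for (i in seq_len(n_women)) {
    p <- if (is.null(params_sampler)) params else params_sampler(i)
    if (!inherits(p, "simulation_params"))
      p <- do.call(simulation_params, as.list(p))
    si <- .derive_seed(seed, i)
    p$seed <- si
    first <- .with_seed(.derive_seed(si, 0L),
                        start_window[1] + sample.int(span + 1L, 1L) - 1L)
    s <- generate_series(p, first, woman_id = sprintf("w%04d", i))
    if (p$lunar_kappa > 0)
      s <- apply_lunar_coupling(s, p$lunar_kappa, p$lunar_mu,
                                seed = .derive_seed(si, 1L))
    series[[i]] <- s
  }
  cohort(series, label = label)
}

#' Couple a series' onset phase to the lunar cycle
#'
#' Shifts the series' first start date (cycle lengths are untouched) so that
#' the first onset's lunar phase is a draw from a von Mises distribution
#' centered on \code{preferred_phase} with concentration \code{kappa}. With
#' \code{kappa = 0} the start is shifted by a uniform random integer in
#' 0..29 days, the same null used by \code{\link{monte_carlo_shift_test}}.
#' The shift is the integer day offset in 0..29 whose resulting phase is
#' circularly closest to the drawn angle (day resolution quantizes phase to
#' ~12.2 degrees, a third of a phase bin).
#'
#' @param series a \code{\link{cycle_series}}.
#' @param kappa von Mises concentration (>= 0).
#' @param preferred_phase preferred lunar phase angle, degrees.
#' @param seed integer seed.
#' @param config a \code{\link{lunar_config}}.
#' @return A new \code{cycle_series} with identical lengths.
#' @export
apply_lunar_coupling <- function(series, kappa, preferred_phase = 0,
                                 seed = 1L, config = lunar_config()) {
  stopifnot(inherits(series, "cycle_series"))
  if (kappa < 0)
    stop("apply_lunar_coupling: 'kappa' must be >= 0", call. = FALSE)
  shift <- .with_seed(seed, {
    if (kappa == 0) {
      sample(0:29, 1L)
    } else {
      theta <- .rvonmises(1, preferred_phase * pi / 180, kappa) * 180 / pi
      cand <- 0:29
      ang <- lunar_phase_angle(series$first_start_date + cand, config)
      d <- abs(((ang - theta + 180) %% 360) - 180)
      cand[which.min(d)]
    }
  })
  cycle_series(series$woman_id, series$first_start_date + shift,
               series$lengths)
}
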