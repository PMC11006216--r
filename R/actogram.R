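#' Build a normalized actogram
#'
#' The actogram normalizes a woman's series to her own mean cycle length
#' (the estimate of her infradian period): \code{offsets[i]} is the
#' cumulative sum of \code{lengths[1..i] - reference_period}, i.e. the
#' advance (negative) or delay (positive) of the start of cycle i+1 relative
#' to a perfectly periodic reference. Because the reference is the sample
#' mean, the final offset is always 0. The offsets are decomposed additively
#' into \code{trend} (Gaussian kernel smoothing over ~\code{trend_window}
#' cycles, see \code{\link{long_trend}}), \code{band} (asymmetric
#' Christiano-Fitzgerald band-pass passing periods of \code{band[1]} to
#' \code{band[2]} cycles, see \code{\link{bandpass_cf}}), and the remaining
#' \code{residual}; by construction \code{trend + band + residual} equals
#' \code{offsets} exactly.
#'
#' For series shorter than \code{trend_window} (or \code{2*band[1]}) cycles
#' the corresponding component is NA: those smoothings are not estimable.
#'
#' @param series a \code{\link{cycle_series}} with >= 2 cycles.
#' @param trend_window long smoothing window, cycles (default 12, about one
#'   year of cycles).
#' @param band band-pass period range in cycles, default \code{c(3, 12)}:
#'   oscillations shorter than the trend window but above the 2-cycle
#'   Nyquist floor.
#' @return An object of class \code{actogram}: list with \code{woman_id},
#'   \code{reference_period}, \code{lengths}, \code{offsets}, \code{trend},
#'   \code{band}, \code{residual}.
#' @examples
#' a <- build_actogram(cycle_series("w", "2000-01-01", c(28, 30, 26, 28)))
#' a$offsets  # 0  2 -2  0 (reference 28)
#' @export
build_actogram <- function(series, trend_window = 12, band = c(3, 12)) {
  stopifnot(inherits(series, "cycle_series"))
  n <- length(series$lengths)
  if (n < 2)
    stop("build_actogram: need at least 2 cycles", call. = FALSE)
  ref <- mean(series$lengths)
  offsets <- cumsum(series$lengths - ref)
  trend <- if (n >= trend_window) long_trend(offsets, trend_window)
           else rep(NA_real_, n)
  bp <- if (n >= 2 * band[1]) bandpass_cf(offsets, band[1], band[2])
        else rep(NA_real_, n)
  structure(list(woman_id = series$woman_id,
                 reference_period = ref,
                 lengths = series$lengths,
                 offsets = offsets,
                 trend = trend,
                 band = bp,
                 residual = offsets - trend - bp,
                 trend_window = trend_window,
                 band_range = band),
            class = "actogram")
}

#' @export
print.actogram <- function(x, ...) {
  cat(sprintf("<actogram> woman %s: %d cycles, reference period %.2f d\n",
              x$woman_id, length(x$offsets), x$reference_period))
  invisible(x)
}

#' Long-term trend by Gaussian kernel smoothing
#'
#' Nadaraya-Watson regression of the offsets on cycle index with a Gaussian
#' kernel whose full width at half maximum equals \code{window} cycles
#' (bandwidth sd = window / (2*sqrt(2*log 2))). Weights are renormalized at
#' the boundaries (no padding). Constants are preserved exactly and linear
#' trends are reproduced in the interior of the series.
#'
#' @param offsets numeric series (cumulative actogram offsets, days).
#' @param window effective smoothing window, cycles; default 12.
#' @return Smoothed series of the same length.
#' @export
long_trend <- function(offsets, window = 12) {
  n <- length(offsets)
  if (n < window)
    stop(sprintf("long_trend: series length %d is shorter than window %d",
                 n, window), call. = FALSE)
  h <- (window / 2) / sqrt(2 * log(2))
  idx <- seq_len(n)
  w <- dnorm(outer(idx, idx, "-"), sd = h)
  as.vector((w %*% offsets) / rowSums(w))
}

#' Asymmetric Christiano-Fitzgerald band-pass filter
#'
#' Extracts the component of a series with cyclical periods between
#' \code{min_period} and \code{max_period} observations, using the
#' full-sample asymmetric Christiano-Fitzgerald approximation to the ideal
#' band-pass filter under the random-walk assumption (the filter is optimal
#' for an I(1) input and, near the series ends, uses endpoint weights that
#' make each row of weights sum to zero). A constant input therefore maps to
#' zero, and the filter is linear in its input.
#'
#' @param offsets numeric series.
#' @param min_period,max_period pass band in observations (cycles);
#'   \code{2 <= min_period < max_period}.
#' @return Filtered series of the same length.
#' @export
bandpass_cf <- function(offsets, min_period = 3, max_period = 12) {
  if (!(min_period >= 2 && min_period < max_period))
    stop("bandpass_cf: need 2 <= min_period < max_period", call. = FALSE)
  n <- length(offsets)
  if (n < 2 * min_period)
    stop(sprintf("bandpass_cf: series length %d < 2*min_period", n),
         call. = FALSE)
  a <- 2 * pi / max_period
  b <- 2 * pi / min_period
  j <- seq_len(n)
  B <- c((b - a) / pi, (sin(j * b) - sin(j * a)) / (pi * j)) # B[k+1] = B_k
  # endpoint weight making the weights sum to zero (random-walk case):
  # Btilde_k = -B_0/2 - sum_{j=1}^{k-1} B_j
  Btilde <- -B[1] / 2 - c(0, cumsum(B[-1]))[seq_len(n)] # Btilde[k] for k>=1
  out <- numeric(n)
  for (t in seq_len(n)) {
    # interior: B0 x_t + full B_j on both sides + endpoint weights Btilde;
    # at t = 1 and t = n the series end coincides with t and B0 is halved
    acc <- (if (t == 1L || t == n) B[1] / 2 else B[1]) * offsets[t]
    nf <- n - t - 1L # full forward weights
    if (nf > 0)
      acc <- acc + sum(B[2:(nf + 1)] * offsets[(t + 1):(t + nf)])
    if (t < n)
      acc <- acc + Btilde[n - t] * offsets[n]
    nb <- t - 2L # full backward weights
    if (nb > 0)
      acc <- acc + sum(B[2:(nb + 1)] * offsets[(t - 1):(t - nb)])
    if (t > 1)
      acc <- acc + Btilde[t - 1] * offsets[1]
    out[t] <- acc
  }
  out
}

#' Detect wavelets in the band-pass component
#'
#' A wavelet is one full oscillation of the band-pass-filtered offsets: a
#' pair of adjacent opposite-sign runs between zero crossings (a delay
#' excursion followed by an advance excursion, or vice versa). Its duration
#' is the total number of cycles covered by the two runs and its amplitude
#' is the maximum absolute band value inside it (peak, not peak-to-peak).
#' Unpaired terminal runs are dropped, and wavelets shorter than
#' \code{min_duration} cycles are discarded as irregularities rather than
#' oscillations.
#'
#' @param x an \code{\link{actogram}} or the numeric band-pass series.
#' @param min_duration minimum wavelet duration in cycles; default 4.
#' @return data frame with columns \code{start_index}, \code{end_index}
#'   (1-based, inclusive), \code{duration}, \code{amplitude}, \code{context}
#'   (NA until \code{\link{classify_wavelets}}).
#' @export
detect_wavelets <- function(x, min_duration = 4) {
  band <- if (inherits(x, "actogram")) x$band else as.numeric(x)
  empty <- data.frame(start_index = integer(0), end_index = integer(0),
                      duration = integer(0), amplitude = numeric(0),
                      context = character(0), stringsAsFactors = FALSE)
  if (length(band) == 0 || anyNA(band)) return(empty)
  s <- sign(band)
  s[abs(band) < 1e-12] <- 0
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nz <- which(r$values != 0)
  out <- list()
  i <- 1L
  while (i < length(nz)) {
    r1 <- nz[i]; r2 <- nz[i + 1L]
    # adjacent opposite-sign runs form one full oscillation
    if (r2 == r1 + 1L && r$values[r1] == -r$values[r2]) {
      st <- starts[r1]; en <- ends[r2]
      dur <- r$lengths[r1] + r$lengths[r2]
      if (dur >= min_duration)
        out[[length(out) + 1L]] <-
          data.frame(start_index = st, end_index = en,
                     duration = as.integer(dur),
                     amplitude = max(abs(band[st:en])),
                     context = NA_character_, stringsAsFactors = FALSE)
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Classify wavelets by their context
#'
#' Each wavelet gets exactly one label: \code{"after_jump"} if a jump cycle
#' (length exceeding the reference period by more than \code{jump_threshold}
#' days) occurs in the two cycles before the wavelet or inside its first
#' half; otherwise \code{"with_fluctuations"} if the RMS of the residual
#' (offsets - trend - band) inside the wavelet exceeds the wavelet
#' amplitude; otherwise \code{"stable"}.
#'
#' @param wavelets wavelet table from \code{\link{detect_wavelets}}.
#' @param actogram the \code{\link{actogram}} the wavelets were detected in.
#' @param jump_threshold days above the reference period that define an
#'   abrupt cycle lengthening; default 5.
#' @return The wavelet table with the \code{context} column filled.
#' @export
classify_wavelets <- function(wavelets, actogram, jump_threshold = 5) {
  stopifnot(inherits(actogram, "actogram"))
  n <- length(actogram$lengths)
  if (nrow(wavelets) == 0) return(wavelets)
  if (any(wavelets$end_index > n) || any(wavelets$start_index < 1))
    stop("classify_wavelets: wavelet indices outside the series", call. = FALSE)
  jumps <- which(actogram$lengths >
                   actogram$reference_period + jump_threshold)
  ctx <- character(nrow(wavelets))
  for (k in seq_len(nrow(wavelets))) {
    st <- wavelets$start_index[k]
    en <- wavelets$end_index[k]
    half_end <- floor((st + en) / 2)
    window <- max(1L, st - 2L):half_end
    if (any(jumps %in% window)) {
      ctx[k] <- "after_jump"
    } else {
      res <- actogram$residual[st:en]
      rms <- if (anyNA(res)) NA_real_ else sqrt(mean(res^2))
      ctx[k] <- if (!is.na(rms) && rms > wavelets$amplitude[k])
        "with_fluctuations" else "stable"
    }
  }
  wavelets$context <- ctx
  wavelets
}

#' Flag large-amplitude wavelets
#'
#' @param wavelets wavelet table from \code{\link{detect_wavelets}}.
#' @param threshold amplitude threshold in days, inclusive; default 3.
#' @return list with \code{count} (number of wavelets with amplitude >=
#'   threshold) and \code{wavelets} (the table with a logical
#'   \code{large_amp} column).
#' @export
flag_large_amplitude <- function(wavelets, threshold = 3) {
  flag <- if (nrow(wavelets)) wavelets$amplitude >= threshold else logical(0)
  wavelets$large_amp <- flag
  list(count = sum(flag), wavelets = wavelets)
}

#' Render an actogram raster
#'
#' One row per cycle, stacked downward as in circadian raster plots; the
#' horizontal position of each cycle's bar is its onset offset wrapped
#' modulo the reference period, so a cycle much longer than the reference
#' displaces all subsequent rows to the right. Optionally overlays the
#' long-trend (brown) and band (orange) smoothings. Also builds a
#' plain-text grid (one character row per cycle, \code{*} marking the
#' wrapped onset), returned invisibly.
#'
#' @param actogram an \code{\link{actogram}}.
#' @param file optional path; if given, a PNG is written there.
#' @param smoothed overlay trend and band curves when available.
#' @param width character width of the text grid.
#' @return Invisibly, the character vector text grid (one row per cycle).
#' @export
render_actogram <- function(actogram, file = NULL, smoothed = TRUE,
                            width = 60) {
  stopifnot(inherits(actogram, "actogram"))
  ref <- actogram$reference_period
  n <- length(actogram$lengths)
  onset_off <- c(0, actogram$offsets[-n]) # onset offset of cycle i
  pos <- onset_off %% ref

  draw <- function() {
    plot.new()
    plot.window(xlim = c(0, 2 * ref), ylim = c(n + 1, 0))
    title(main = sprintf("woman %s (reference %.1f d)", actogram$woman_id,
                         ref),
          xlab = "days (modulo reference period, double-plotted)",
          ylab = "cycle")
    axis(1); axis(2)
    for (i in seq_len(n)) {
      len <- actogram$lengths[i]
      segments(pos[i], i, min(pos[i] + len, 2 * ref), i, col = "steelblue",
               lwd = 2)
    }
    abline(v = ref, col = "black")
    if (smoothed && !anyNA(actogram$trend))
      lines(ref + actogram$trend, seq_len(n), col = "brown", lwd = 2)
    if (smoothed && !anyNA(actogram$band))
      lines(ref + actogram$band, seq_len(n), col = "orange", lwd = 1.5)
  }
  if (!is.null(file)) {
    png(file, width = 700, height = 500)
    on.exit(dev.off())
    draw()
  } else {
    draw()
  }

  col <- pmin(pmax(1L, 1L + as.integer(round(pos / ref * (width - 1)))), width)
  grid <- vapply(seq_len(n), function(i) {
    row <- rep(".", width)
    row[col[i]] <- "*"
    paste(row, collapse = "")
  }, character(1))
  invisible(grid)
}

#' Per-cohort wavelet table and summary
#'
#' Runs the full actogram pipeline (build, detect, classify, flag) for every
#' eligible series of a cohort and tabulates the results.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param min_series_len minimum series length for wavelet statistics;
#'   default 18 (shorter series do not support the 12-cycle trend
#'   estimation).
#' @param trend_window,band,min_duration,jump_threshold,amp_threshold see
#'   the individual operations.
#' @return list with \code{wavelets} (per-wavelet data frame including
#'   \code{woman_id}), \code{summary} (counts and percentages by context,
#'   mean wavelets per woman, large-amplitude count), \code{n_women}.
#' @export
cohort_wavelets <- function(cohort, min_series_len = 18, trend_window = 12,
                            band = c(3, 12), min_duration = 4,
                            jump_threshold = 5, amp_threshold = 3) {
  stopifnot(inherits(cohort, "cycle_cohort"))
  keep <- vapply(cohort$series, function(s) length(s$lengths) >=
                   min_series_len, logical(1))
  series <- cohort$series[keep]
  tabs <- lapply(series, function(s) {
    a <- build_actogram(s, trend_window, band)
    w <- detect_wavelets(a, min_duration)
    w <- classify_wavelets(w, a, jump_threshold)
    w <- flag_large_amplitude(w, amp_threshold)$wavelets
    if (nrow(w)) cbind(woman_id = s$woman_id, w) else NULL
  })
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  wav <- if (length(tabs)) do.call(rbind, tabs) else
    data.frame(woman_id = character(0), start_index = integer(0),
               end_index = integer(0), duration = integer(0),
               amplitude = numeric(0), context = character(0),
               large_amp = logical(0))
  rownames(wav) <- NULL
  ctx <- table(factor(wav$context,
                      levels = c("stable", "after_jump", "with_fluctuations")))
  list(wavelets = wav,
       summary = list(
         n_wavelets = nrow(wav),
         by_context = ctx,
         pct_by_context = if (nrow(wav)) 100 * ctx / nrow(wav) else ctx,
         mean_per_woman = if (length(series)) nrow(wav) / length(series)
                          else NA_real_,
         n_large_amplitude = sum(wav$large_amp)),
       n_women = length(series))
}
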