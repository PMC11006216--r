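# Serial dependence of successive cycle lengths: per-woman ACF/PACF to lag
# 6, cross-woman averages, and a within-woman permutation Monte Carlo null.

# Row-wise divisor-n ACF of a matrix (one series per row, equal lengths):
# rho_k = sum_{i<=n-k} (x_i - xbar)(x_{i+k} - xbar) / sum_i (x_i - xbar)^2.
# Rows with zero variance come back as NA.
.acf_rows <- function(X, max_lag) {
  n <- ncol(X)
  xc <- X - rowMeans(X)
  denom <- rowSums(xc^2)
  denom[denom == 0] <- NA_real_
  out <- matrix(NA_real_, nrow(X), max_lag)
  for (k in seq_len(max_lag))
    out[, k] <- rowSums(xc[, 1:(n - k), drop = FALSE] *
                          xc[, (k + 1):n, drop = FALSE]) / denom
  out
}

# Row-wise Durbin-Levinson PACF from a matrix of ACF values (rows =
# series, columns = lags 1..K). Vectorized across rows.
.pacf_rows <- function(Rho) {
  K <- ncol(Rho)
  nr <- nrow(Rho)
  out <- matrix(NA_real_, nr, K)
  out[, 1] <- Rho[, 1]
  phi <- matrix(Rho[, 1], nr, 1)
  if (K >= 2) {
    for (m in 2:K) {
      prev <- seq_len(m - 1)
      num <- Rho[, m] - rowSums(phi * Rho[, rev(prev), drop = FALSE])
      den <- 1 - rowSums(phi * Rho[, prev, drop = FALSE])
      pm <- num / den
      phi <- cbind(phi - pm * phi[, rev(prev), drop = FALSE], pm)
      out[, m] <- pm
    }
  }
  out
}

#' Autocorrelation of one series of cycle lengths
#'
#' Divisor-n (biased) estimator, the standard time-series convention:
#' \code{rho_k = sum_{i=1}^{n-k} (x_i - xbar)(x_{i+k} - xbar) /
#' sum (x_i - xbar)^2}. Lag 0 is identically 1 and is not returned.
#'
#' @param lengths numeric series (cycle lengths in days).
#' @param max_lag maximum lag; default 6.
#' @return Numeric vector \code{rho_1..rho_max_lag}. A constant
#'   (zero-variance) series returns all NA with attribute
#'   \code{zero_variance = TRUE}.
#' @examples
#' acf_lengths(rep(c(28, 30), 4))[1]  # -7/8
#' @export
acf_lengths <- function(lengths, max_lag = 6) {
  n <- length(lengths)
  if (n <= max_lag)
    stop(sprintf("acf_lengths: series length %d must exceed max_lag %d",
                 n, max_lag), call. = FALSE)
  r <- drop(.acf_rows(matrix(as.numeric(lengths), 1), max_lag))
  names(r) <- paste0("lag", seq_len(max_lag))
  if (anyNA(r)) attr(r, "zero_variance") <- TRUE
  r
}

#' Partial autocorrelation of one series of cycle lengths
#'
#' PACF via the Durbin-Levinson recursion on the divisor-n ACF (i.e. the
#' Yule-Walker solution); \code{phi_11} equals \code{rho_1}, and
#' \code{phi_kk} is the direct correlation between cycles k apart after
#' removing the influence of the intermediate cycles.
#'
#' @inheritParams acf_lengths
#' @return Numeric vector \code{phi_11..phi_KK}; NA with a
#'   \code{zero_variance} attribute for constant series.
#' @export
pacf_lengths <- function(lengths, max_lag = 6) {
  rho <- acf_lengths(lengths, max_lag)
  p <- drop(.pacf_rows(matrix(rho, 1)))
  names(p) <- paste0("lag", seq_len(max_lag))
  if (anyNA(p)) attr(p, "zero_variance") <- TRUE
  p
}

# Eligible series for correlation analyses: long enough and non-constant.
.eligible_lengths <- function(cohort, min_series_len, max_lag) {
  need <- max(min_series_len, max_lag + 1)
  xs <- lapply(cohort$series, `[[`, "lengths")
  long_enough <- vapply(xs, length, integer(1)) >= need
  xs <- xs[long_enough]
  nonconst <- vapply(xs, function(x) stats::var(x) > 0, logical(1))
  list(series = xs[nonconst], n_zero_var = sum(!nonconst),
       n_too_short = sum(!long_enough))
}

# Per-woman statistic matrix (women x lags), grouping equal-length series
# for vectorization.
.per_woman_stats <- function(xs, statistic, max_lag) {
  ns <- vapply(xs, length, integer(1))
  out <- matrix(NA_real_, length(xs), max_lag)
  for (n in unique(ns)) {
    rows <- which(ns == n)
    X <- do.call(rbind, xs[rows])
    A <- .acf_rows(X, max_lag)
    out[rows, ] <- if (statistic == "pacf") .pacf_rows(A) else A
  }
  out
}

#' Cross-woman average ACF or PACF
#'
#' Computes the chosen statistic per woman and averages it, unweighted,
#' across the eligible women (series at least \code{min_series_len} cycles
#' long; constant series are excluded and counted).
#'
#' @param cohort a \code{\link{cohort}}.
#' @param statistic \code{"acf"} or \code{"pacf"}.
#' @param min_series_len minimum series length in cycles (e.g. 13 for at
#'   least a year of cycles; 7 for shorter-series cohorts).
#' @param max_lag maximum lag; default 6.
#' @return list with \code{mean} (per-lag average), \code{per_woman}
#'   (matrix), \code{n_women}, \code{n_zero_variance}.
#' @export
average_correlations <- function(cohort, statistic = c("acf", "pacf"),
                                 min_series_len = 13, max_lag = 6) {
  statistic <- match.arg(statistic)
  el <- .eligible_lengths(cohort, min_series_len, max_lag)
  if (length(el$series) == 0)
    stop("average_correlations: no eligible women after filtering",
         call. = FALSE)
  per <- .per_woman_stats(el$series, statistic, max_lag)
  m <- colMeans(per)
  names(m) <- paste0("lag", seq_len(max_lag))
  list(mean = m, per_woman = per, n_women = nrow(per),
       n_zero_variance = el$n_zero_var)
}

#' Permutation Monte Carlo test of serial dependence
#'
#' The observed cross-woman average ACF (or PACF) is compared with its
#' distribution under within-woman permutation: in each replicate every
#' woman's cycle lengths are independently and uniformly permuted, the
#' per-woman statistic recomputed, and the cross-woman average taken. Each
#' woman's permutations come from an independent RNG substream derived from
#' the master seed, so results do not depend on cohort ordering. Because a
#' permutation preserves the multiset of a woman's lengths, a zero-variance
#' series is constant in every replicate; such women are excluded once and
#' counted.
#'
#' Per lag, the two-sided p-value uses the add-one rank rule: each tail is
#' \code{(1 + #exceedances) / (n_perm + 1)} with ties counted as
#' exceedances, and the smaller tail is doubled and capped at 1. The
#' z-score is \code{(observed - null mean) / null SD}. Significance flags
#' are Bonferroni-corrected across the \code{max_lag} lags at family level
#' \code{alpha}.
#'
#' @inheritParams average_correlations
#' @param n_perm permutation replicates; default 5000 (a warning is issued
#'   below 100).
#' @param seed master integer seed.
#' @param alpha family-wise significance level; default 0.05 (i.e. 0.025
#'   per side before correction).
#' @return An object of class \code{perm_acf_test}: list with
#'   \code{statistic}, \code{observed_mean}, \code{null_means} (n_perm x
#'   max_lag matrix), \code{p_value}, \code{z_score},
#'   \code{significant} (Bonferroni flags), \code{n_perm}, \code{seed},
#'   \code{n_women}, \code{n_zero_variance}.
#' @export
permutation_test <- function(cohort, statistic = c("acf", "pacf"),
                             n_perm = 5000, seed = 1L, min_series_len = 13,
                             max_lag = 6, alpha = 0.05) {
  statistic <- match.arg(statistic)
  if (n_perm < 100)
    warning("permutation_test: n_perm < 100 gives a coarse null")
  el <- .eligible_lengths(cohort, min_series_len, max_lag)
  xs <- el$series
  if (length(xs) == 0)
    stop("permutation_test: no eligible women after filtering", call. = FALSE)

  observed <- colMeans(.per_woman_stats(xs, statistic, max_lag))
  null_sum <- matrix(0, n_perm, max_lag)
  for (i in seq_along(xs)) {
    x <- as.numeric(xs[[i]])
    n <- length(x)
    idx <- .with_seed(.derive_seed(seed, i), .perm_matrix(n_perm, n))
    P <- matrix(x[idx], n_perm, n)
    A <- .acf_rows(P, max_lag)
    if (statistic == "pacf") A <- .pacf_rows(A)
    null_sum <- null_sum + A
  }
  null_means <- null_sum / length(xs)

  p_up <- (1 + colSums(null_means >= rep(observed, each = n_perm))) /
    (n_perm + 1)
  p_lo <- (1 + colSums(null_means <= rep(observed, each = n_perm))) /
    (n_perm + 1)
  p <- pmin(1, 2 * pmin(p_up, p_lo))
  z <- (observed - colMeans(null_means)) / apply(null_means, 2, sd)
  names(p) <- names(z) <- paste0("lag", seq_len(max_lag))
  structure(list(statistic = toupper(statistic),
                 observed_mean = observed,
                 null_means = null_means,
                 p_value = p,
                 z_score = z,
                 significant = p < alpha / max_lag,
                 alpha = alpha,
                 n_perm = n_perm,
                 seed = seed,
                 n_women = length(xs),
                 n_zero_variance = el$n_zero_var),
            class = "perm_acf_test")
}

#' @export
print.perm_acf_test <- function(x, ...) {
  cat(sprintf("Within-woman permutation test of average %s (%d women, %d replicates)\n",
              x$statistic, x$n_women, x$n_perm))
  tab <- data.frame(lag = seq_along(x$observed_mean),
                    observed = round(x$observed_mean, 4),
                    null_mean = round(colMeans(x$null_means), 4),
                    null_sd = round(apply(x$null_means, 2, sd), 4),
                    z = round(x$z_score, 2),
                    p = signif(x$p_value, 3),
                    significant = ifelse(x$significant, "*", ""))
  print(tab, row.names = FALSE)
  cat(sprintf("Bonferroni-corrected across %d lags at family level %.2f\n",
              length(x$observed_mean), x$alpha))
  invisible(x)
}

#' Plot a permutation test result
#'
#' z-score traces of the permutation null (gray) with the observed average
#' overlaid (red); significant lags are starred.
#'
#' @param x a \code{perm_acf_test}.
#' @param n_traces number of null replicates to draw; default 100.
#' @param ... ignored.
#' @export
plot.perm_acf_test <- function(x, n_traces = 100, ...) {
  lags <- seq_along(x$observed_mean)
  mu <- colMeans(x$null_means)
  sdv <- apply(x$null_means, 2, sd)
  zn <- t((t(x$null_means) - mu) / sdv)
  keep <- seq_len(min(n_traces, nrow(zn)))
  plot.new()
  plot.window(xlim = range(lags), ylim = range(c(zn[keep, ], x$z_score, -3, 3)))
  axis(1, at = lags); axis(2)
  title(xlab = "lag (cycles)", ylab = "z-score",
        main = sprintf("Average %s vs within-woman permutation null",
                       x$statistic))
  matlines(lags, t(zn[keep, ]), col = gray(0.8), lty = 1)
  lines(lags, x$z_score, col = "red", lwd = 2)
  abline(h = c(-2, 2), lty = 2)
  if (any(x$significant))
    text(lags[x$significant], x$z_score[x$significant], "*", cex = 2,
         col = "red")
  invisible(x)
}
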