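#' Apply the cohort selection rules
#'
#' Each series is truncated at the cycle preceding its first cycle longer
#' than \code{max_cycle_len} days (the long cycle and everything after it
#' are dropped, mimicking censoring of a series at a pregnancy or another
#' event producing an abnormally long cycle). Series shorter than
#' \code{min_series_len} cycles after truncation are removed.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param min_series_len minimum number of cycles a series must retain.
#' @param max_cycle_len cycle length (days) above which a series is stopped;
#'   default 60.
#' @return A new \code{cycle_cohort}; the input is not modified. The
#'   operation is idempotent.
#' @examples
#' co <- cohort(list(cycle_series("a", "2000-01-01", c(28, 29, 65, 27))))
#' apply_selection(co, min_series_len = 1)$series[[1]]$lengths  # 28 29
#' @export
apply_selection <- function(cohort, min_series_len = 1, max_cycle_len = 60) {
  stopifnot(inherits(cohort, "cycle_cohort"))
  if (min_series_len < 1)
    stop("apply_selection: min_series_len must be >= 1", call. = FALSE)
  kept <- list()
  for (s in cohort$series) {
    long <- which(s$lengths > max_cycle_len)
    keep_n <- if (length(long)) long[1] - 1L else length(s$lengths)
    if (keep_n >= min_series_len) {
      s$lengths <- s$lengths[seq_len(keep_n)]
      kept[[length(kept) + 1L]] <- s
    }
  }
  cohort(kept, label = cohort$label)
}

#' Subset a cohort by per-woman mean cycle length
#'
#' Keeps the series whose arithmetic mean cycle length lies in the closed
#' interval [\code{low}, \code{high}]. The mean is compared exactly (no
#' pre-rounding), so a mean of exactly 28.0 is retained with the defaults.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param low,high interval bounds in days (inclusive); defaults 28 and 30,
#'   the near-synodic range used in lunar sensitivity analyses.
#' @return A new \code{cycle_cohort}.
#' @export
subset_by_mean_length <- function(cohort, low = 28, high = 30) {
  stopifnot(inherits(cohort, "cycle_cohort"))
  if (low > high)
    stop("subset_by_mean_length: low must be <= high", call. = FALSE)
  keep <- vapply(cohort$series, function(s) {
    m <- sum(s$lengths) / length(s$lengths)
    m >= low && m <= high
  }, logical(1))
  cohort(cohort$series[keep], label = cohort$label)
}

#' Summarize a cohort
#'
#' @param cohort a non-empty \code{\link{cohort}}.
#' @return A list with \code{n_women}, \code{n_cycles}, \code{pooled_quartiles}
#'   (type-7 quantiles of all cycle lengths pooled over women) and
#'   \code{mean_length_quartiles} (the distribution of per-woman mean
#'   lengths).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cycle_cohort"))
  if (length(cohort$series) == 0)
    stop("summarize_cohort: empty cohort", call. = FALSE)
  pooled <- unlist(lapply(cohort$series, `[[`, "lengths"))
  means <- vapply(cohort$series,
                  function(s) mean(s$lengths), numeric(1))
  q <- c(0, 0.25, 0.5, 0.75, 1)
  list(n_women = length(cohort$series),
       n_cycles = length(pooled),
       pooled_quartiles = quantile(pooled, q, type = 7, names = TRUE),
       mean_length_quartiles = quantile(means, q, type = 7, names = TRUE))
}
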