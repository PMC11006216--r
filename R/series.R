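#' Construct a cycle series
#'
#' A \code{cycle_series} holds one woman's ordered menstrual cycle lengths,
#' anchored to the calendar date of the first day of her first recorded
#' cycle. The first day of each menstrual bleeding is the first day of the
#' cycle; cycle i therefore starts at \code{first_start_date} plus the sum
#' of the lengths of cycles 1..i-1.
#'
#' @param woman_id identifier, coerced to character.
#' @param first_start_date calendar date of the first cycle onset
#'   (\code{Date} or ISO 8601 string).
#' @param lengths integer vector of cycle lengths in days, all >= 1.
#' @return An object of class \code{cycle_series}.
#' @examples
#' s <- cycle_series("w1", "2000-01-01", c(28, 30, 26))
#' onset_dates(s)
#' @export
cycle_series <- function(woman_id, first_start_date, lengths) {
  if (length(lengths) < 1)
    stop("cycle_series: 'lengths' must be non-empty", call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop("cycle_series: all cycle lengths must be >= 1 day", call. = FALSE)
  if (any(lengths != round(lengths)))
    stop("cycle_series: cycle lengths must be whole days", call. = FALSE)
  d <- tryCatch(as.Date(first_start_date),
                error = function(e) as.Date(NA))
  if (length(d) != 1 || is.na(d))
    stop("cycle_series: 'first_start_date' is not a valid date", call. = FALSE)
  structure(
    list(woman_id = as.character(woman_id),
         first_start_date = d,
         lengths = as.integer(lengths)),
    class = "cycle_series")
}

#' Onset dates of every cycle in a series
#'
#' @param series a \code{\link{cycle_series}}.
#' @return A \code{Date} vector with one onset (first day of menses) per
#'   cycle.
#' @export
onset_dates <- function(series) {
  stopifnot(inherits(series, "cycle_series"))
  n <- length(series$lengths)
  series$first_start_date + c(0L, cumsum(series$lengths[-n]))
}

#' @export
print.cycle_series <- function(x, ...) {
  cat(sprintf("<cycle_series> woman %s: %d cycles from %s, mean length %.1f d\n",
              x$woman_id, length(x$lengths),
              format(x$first_start_date), mean(x$lengths)))
  invisible(x)
}

#' Construct a cohort of cycle series
#'
#' @param series list of \code{\link{cycle_series}} objects; woman
#'   identifiers must be unique (only one series per woman is analyzed).
#' @param label free-text provenance tag.
#' @return An object of class \code{cycle_cohort}.
#' @export
cohort <- function(series = list(), label = "") {
  if (!all(vapply(series, inherits, logical(1), "cycle_series")))
    stop("cohort: 'series' must be a list of cycle_series objects",
         call. = FALSE)
  ids <- vapply(series, `[[`, character(1), "woman_id")
  if (anyDuplicated(ids))
    stop(sprintf("cohort: duplicated woman_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  structure(list(series = series, label = as.character(label)),
            class = "cycle_cohort")
}

#' @export
print.cycle_cohort <- function(x, ...) {
  nc <- sum(vapply(x$series, function(s) length(s$lengths), integer(1)))
  cat(sprintf("<cycle_cohort> %d women, %d cycles%s\n",
              length(x$series), nc,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
length.cycle_cohort <- function(x) length(x$series)

#' Flatten a cohort to a per-cycle data frame
#'
#' @param x a \code{cycle_cohort}.
#' @param row.names,optional,... ignored; present for the generic.
#' @return data frame with columns \code{woman_id}, \code{cycle_index},
#'   \code{start_date}, \code{cycle_length_days}.
#' @export
as.data.frame.cycle_cohort <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  if (length(x$series) == 0)
    return(data.frame(woman_id = character(0), cycle_index = integer(0),
                      start_date = as.Date(character(0)),
                      cycle_length_days = integer(0)))
  parts <- lapply(x$series, function(s) {
    data.frame(woman_id = s$woman_id,
               cycle_index = seq_along(s$lengths),
               start_date = onset_dates(s),
               cycle_length_days = s$lengths)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
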