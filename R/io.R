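#' Read a cohort from a cycle-record CSV file
#'
#' The schema is a UTF-8 CSV with header and columns \code{woman_id}
#' (string), \code{cycle_index} (1-based integer, consecutive within each
#' woman), \code{start_date} (ISO 8601 date; required for cycle_index 1 and,
#' if present on later rows, it must equal the date derived from the first
#' onset plus the preceding cycle lengths), and \code{cycle_length_days}
#' (positive integer).
#'
#' @param path path to the CSV file.
#' @return A \code{\link{cohort}}.
#' @seealso \code{\link{write_cohort}}
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_cohort: file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("woman_id", "cycle_index", "start_date", "cycle_length_days")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("read_cohort: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0) return(cohort(list(), label = basename(path)))

  ci <- suppressWarnings(as.integer(df$cycle_index))
  if (any(is.na(ci)))
    stop(sprintf("read_cohort: row %d: unparsable cycle_index '%s'",
                 which(is.na(ci))[1], df$cycle_index[which(is.na(ci))[1]]),
         call. = FALSE)
  len <- suppressWarnings(as.numeric(df$cycle_length_days))
  bad <- which(is.na(len) | len < 1 | len != round(len))
  if (length(bad))
    stop(sprintf(
      "read_cohort: row %d: cycle_length_days '%s' is not a positive integer",
      bad[1], df$cycle_length_days[bad[1]]), call. = FALSE)
  key <- paste(df$woman_id, ci, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("read_cohort: row %d: duplicated (woman_id, cycle_index) (%s, %d)",
                 d, df$woman_id[d], ci[d]), call. = FALSE)
  }

  series <- lapply(split(seq_len(nrow(df)), df$woman_id), function(rows) {
    rows <- rows[order(ci[rows])]
    idx <- ci[rows]
    wid <- df$woman_id[rows[1]]
    if (!identical(idx, seq_along(idx)))
      stop(sprintf(
        "read_cohort: woman %s: cycle_index not consecutive from 1", wid),
        call. = FALSE)
    d1 <- df$start_date[rows[1]]
    if (is.na(d1) || !nzchar(d1))
      stop(sprintf("read_cohort: woman %s: start_date missing for cycle 1",
                   wid), call. = FALSE)
    first <- suppressWarnings(as.Date(d1, format = "%Y-%m-%d"))
    if (is.na(first))
      stop(sprintf("read_cohort: woman %s: unparsable start_date '%s'",
                   wid, d1), call. = FALSE)
    s <- cycle_series(wid, first, len[rows])
    derived <- onset_dates(s)
    given <- df$start_date[rows]
    have <- !is.na(given) & nzchar(given)
    if (any(have)) {
      gd <- suppressWarnings(as.Date(given[have], format = "%Y-%m-%d"))
      if (any(is.na(gd)))
        stop(sprintf("read_cohort: woman %s: unparsable start_date '%s'",
                     wid, given[have][which(is.na(gd))[1]]), call. = FALSE)
      off <- which(gd != derived[have])
      if (length(off))
        stop(sprintf(
          "read_cohort: woman %s cycle %d: start_date %s does not match derived date %s",
          wid, idx[have][off[1]], format(gd[off[1]]),
          format(derived[have][off[1]])), call. = FALSE)
    }
    s
  })
  # split() orders by woman_id; keep that deterministic order
  cohort(unname(series), label = basename(path))
}

#' Write a cohort to the cycle-record CSV schema
#'
#' Rows are ordered by \code{woman_id} then \code{cycle_index}; every row
#' carries its derived \code{start_date}, so the file round-trips through
#' \code{\link{read_cohort}} unchanged.
#'
#' @param cohort a \code{\link{cohort}}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cycle_cohort"))
  df <- as.data.frame(cohort)
  df <- df[order(df$woman_id, df$cycle_index), , drop = FALSE]
  df$start_date <- format(df$start_date, "%Y-%m-%d")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
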