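# Miller-unit time-course datasets (real or synthetic) and their CSV format.

#' Experimental dataset of Miller-unit time courses
#'
#' Validates and classes a data frame of beta-galactosidase measurements.
#' Required columns: `scenario` (a label accepted by [parse_scenario()]),
#' `dose_uM` (>= 0), `time_min` (in `[0, 500]`), `miller_units` (finite).
#' Optional `weight` (>= 0, default 1) sets per-record least-squares weights.
#'
#' @param records a data.frame with the columns above.
#' @return The data.frame, validated, with a `weight` column and class
#'   `lsr_dataset`.
#' @export
experimental_dataset <- function(records) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  req <- c("scenario", "dose_uM", "time_min", "miller_units")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0L) stop("dataset must contain at least one record")
  if (!("weight" %in% names(records))) records$weight <- 1
  records$scenario <- as.character(records$scenario)

  check_num <- function(col, lo = -Inf, hi = Inf) {
    v <- records[[col]]
    if (!is.numeric(v)) stop("column '", col, "' must be numeric")
    bad <- which(!is.finite(v) | v < lo | v > hi)
    if (length(bad))
      stop("column '", col, "' out of range [", lo, ", ", hi, "] in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  check_num("dose_uM", lo = 0)
  check_num("time_min", lo = 0, hi = 500)
  check_num("miller_units")
  check_num("weight", lo = 0)
  for (sc in unique(records$scenario)) parse_scenario(sc)  # errors on bad label

  class(records) <- c("lsr_dataset", "data.frame")
  records
}

#' Read / write time-course datasets as CSV
#'
#' The on-disk format is a plain CSV with header columns
#' `scenario, dose_uM, time_min, miller_units[, weight]`; a missing weight
#' column defaults to 1. Reading validates every record and reports the
#' offending rows.
#'
#' @param path CSV file path.
#' @return `read_timecourse_csv()` returns an `lsr_dataset`;
#'   `write_timecourse_csv()` returns `path` invisibly.
#' @export
read_timecourse_csv <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  experimental_dataset(df)
}

#' @rdname read_timecourse_csv
#' @param data an `lsr_dataset` (or coercible data.frame).
#' @export
write_timecourse_csv <- function(data, path) {
  data <- experimental_dataset(as.data.frame(data))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
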