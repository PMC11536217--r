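#' Decimal-year midpoint of an ISO week
#'
#' Parses labels like `"2020-W05"` and returns the decimal year of the
#' week's midpoint (noon Thursday of the ISO week).
#'
#' @param year_week character vector `"YYYY-Www"`.
#' @return Decimal years.
#' @export
iso_week_midpoint <- function(year_week) {
  m <- regmatches(year_week, regexec("^(\\d{4})-W(\\d{2})$", year_week))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad))
    stop("unparseable ISO week label(s): ",
         paste(utils::head(year_week[bad], 5), collapse = ", "), call. = FALSE)
  yr <- as.integer(vapply(m, `[`, "", 2))
  wk <- as.integer(vapply(m, `[`, "", 3))
  # Jan 4 is always in ISO week 1; step back to that week's Monday
  jan4 <- as.Date(sprintf("%d-01-04", yr))
  monday1 <- jan4 - (as.integer(format(jan4, "%u")) - 1L)
  mid <- monday1 + 7L * (wk - 1L) + 3L  # Thursday
  midyear <- as.integer(format(mid, "%Y"))
  ylen <- as.numeric(as.Date(sprintf("%d-01-01", midyear + 1L)) -
                       as.Date(sprintf("%d-01-01", midyear)))
  midyear + (as.numeric(mid - as.Date(sprintf("%d-01-01", midyear))) + 0.5) / ylen
}

report_bad_rows <- function(bad, what) {
  if (any(bad))
    stop(what, " in row(s) ", paste(utils::head(which(bad), 10), collapse = ", "),
         call. = FALSE)
}

#' Read / write rate tables in the long results-tool dialect
#'
#' Long format with columns `measure`, `sex`, `age`, `year`, `val` — one
#' row per age-, sex-, year-specific estimate, as exported by burden-of-
#' disease results tools.
#'
#' @param path CSV file path.
#' @return Validated tibble.
#' @export
read_gbd_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("measure", "sex", "age", "year", "val")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  report_bad_rows(!x$sex %in% c("female", "male"), "unknown sex")
  report_bad_rows(is.na(x$age) | x$age < 0 | x$age > 95, "age outside 0-95")
  report_bad_rows(is.na(x$val) | x$val < 0, "negative or missing value")
  x[need]
}

#' @rdname read_gbd_csv
#' @param data long rate tibble as returned by [gen_consistent_history()].
#' @export
write_gbd_csv <- function(data, path) {
  readr::write_csv(data[c("measure", "sex", "age", "year", "val")], path)
  invisible(path)
}

#' Read / write population pyramid tables
#'
#' Columns `age`, `sex`, `year`, `count` and `births` (annual births of
#' that sex and year, repeated down the year's rows).
#'
#' @param path CSV file path.
#' @return A list with `pyramid` and `births` tibbles.
#' @export
read_population <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("age", "sex", "year", "count", "births")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  report_bad_rows(is.na(x$count) | x$count < 0, "negative or missing count")
  list(pyramid = x[c("age", "sex", "year", "count")],
       births = dplyr::distinct(x, .data$sex, .data$year, .data$births))
}

#' @rdname read_population
#' @param pop list with `pyramid` and `births` as from [gen_population()].
#' @export
write_population <- function(pop, path) {
  out <- dplyr::left_join(pop$pyramid, pop$births, by = c("sex", "year"))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read / write a weekly incidence series
#'
#' Surveillance-export dialect: columns `year_week` (`"YYYY-Www"`) and
#' `rate` (cases per 100,000 per week).  ISO weeks are converted to
#' decimal-year midpoints on reading.
#'
#' @param path CSV file path.
#' @return Tibble `year_week`, `time`, `rate`.
#' @export
read_survstat_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("year_week", "rate"), names(x))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  report_bad_rows(is.na(x$rate) | x$rate < 0, "negative or missing rate")
  tibble::tibble(year_week = x$year_week,
                 time = iso_week_midpoint(x$year_week),
                 rate = x$rate)
}

#' @rdname read_survstat_csv
#' @param series tibble with `year_week` and `rate`.
#' @export
write_survstat_csv <- function(series, path) {
  readr::write_csv(series[c("year_week", "rate")], path)
  invisible(path)
}
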