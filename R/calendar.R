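#' Petrel-year calendar
#'
#' The colony breeds year-round with a minimum of activity in May, so the
#' annual calendar ("petrel year") starts on 1 June and days are numbered
#' sequentially from that origin (1 June = day 1). A petrel year is 365 or
#' 366 days long depending on whether it contains a 29 February.
#'
#' @param dates a `Date` vector (or anything `as.Date()` accepts).
#' @return `petrel_year_origin()`: the 1 June starting each date's petrel
#'   year; `petrel_year_length()`: integer 365/366; `day_index()`: integer
#'   day number within the petrel year (1 June = 1).
#' @examples
#' day_index(as.Date("2016-06-02"))  # 2
#' @export
day_index <- function(dates) {
  dates <- as.Date(dates)
  as.integer(dates - petrel_year_origin(dates)) + 1L
}

#' @rdname day_index
#' @export
petrel_year_origin <- function(dates) {
  dates <- as.Date(dates)
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  as.Date(paste0(ifelse(m >= 6L, y, y - 1L), "-06-01"))
}

#' @rdname day_index
#' @export
petrel_year_length <- function(dates) {
  o <- petrel_year_origin(dates)
  y <- as.integer(format(o, "%Y"))
  as.integer(as.Date(paste0(y + 1L, "-06-01")) - o)
}

#' Inverse of [day_index()] given the petrel year's starting calendar year
#'
#' @param idx integer day index (1-based; may be negative/zero for a signed
#'   day, which then falls before the 1 June origin).
#' @param start_year calendar year in which the petrel year begins.
#' @return a `Date`.
#' @export
day_index_to_date <- function(idx, start_year) {
  as.Date(paste0(start_year, "-06-01")) + (as.integer(round(idx)) - 1L)
}

#' Signed-day encoding of one individual's repeated event dates
#'
#' Arrival/departure day numbers are circular: an individual arriving on
#' 30 May (day 364) one year and 2 June (day 2) the next is consistent, not
#' 362 days apart. When a set of event dates straddles the 1 June origin,
#' dates falling late in the petrel year are re-encoded as negative values
#' (day index minus that petrel year's length, so day 364 of a 365-day year
#' becomes -1). The encoding (raw or re-encoded) minimising the spread of
#' the values is returned; ties keep the raw positive encoding.
#'
#' @param dates `Date` vector of one individual's repeated events of one
#'   kind (all departures, or all arrivals).
#' @return numeric vector of signed day values, same length as `dates`.
#' @export
to_signed_days <- function(dates) {
  dates <- as.Date(dates)
  if (length(dates) == 0L) stop("to_signed_days(): empty input")
  d <- day_index(dates)
  len <- petrel_year_length(dates)
  alt <- ifelse(d > len / 2, d - len, d)
  if (diff(range(alt)) < diff(range(d))) alt else d
}

#' Colony season of a date or petrel-year day
#'
#' The colony's climate has two monsoon-driven seasons: austral winter
#' (May-September) and austral summer (October-April). Classification uses
#' the calendar month only.
#'
#' @param x a `Date` vector, or integer day indices (1..366) interpreted in
#'   a reference non-leap petrel year.
#' @return character vector, `"winter"` or `"summer"`.
#' @export
season_of <- function(x) {
  if (inherits(x, "Date") || is.character(x)) {
    m <- as.integer(format(as.Date(x), "%m"))
  } else {
    x <- as.integer(x)
    stopifnot(all(x >= 1L & x <= 366L))
    # reference petrel year 2017/18 (non-leap)
    m <- as.integer(format(as.Date("2017-06-01") + (pmin(x, 365L) - 1L), "%m"))
  }
  ifelse(m >= 5L & m <= 9L, "winter", "summer")
}

#' Circular difference in days between two petrel-year day indices
#'
#' Used for the "difference in departure dates" covariate: the smaller of
#' the two ways round the annual cycle, so it never exceeds half a year.
#'
#' @param a,b day indices (1..366).
#' @param year_length annual cycle length used for wrapping (default 365).
#' @return non-negative days.
#' @export
day_diff_circular <- function(a, b, year_length = 365) {
  d <- abs(a - b) %% year_length
  pmin(d, year_length - d)
}
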