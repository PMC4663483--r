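# Calendar helpers on a fixed 365-day year (leap days ignored: the method
# resolves seasons, not days, so the extra day is irrelevant).

days_in_month <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
month_start_doy <- cumsum(c(0L, days_in_month[-12])) + 1L

#' Day of year for a (month, day) date
#'
#' Converts calendar dates to day-of-year on a 365-day year (no leap days).
#' A missing day is placed mid-month (the 15th), which is the resolution
#' convention for records dated only to the month.
#'
#' @param month Integer vector, 1-12.
#' @param day Integer vector, day of month, or `NA` for month-only dates.
#' @return Integer vector of days of year in 1-365.
#' @examples
#' day_of_year(3, 12)
#' day_of_year(7, NA)
#' @export
day_of_year <- function(month, day = NA_integer_) {
  n <- max(length(month), length(day))
  month <- rep_len(as.integer(month), n)
  day <- rep_len(as.integer(day), n)
  if (any(is.na(month) | month < 1L | month > 12L)) {
    abort("`month` must be an integer in 1..12.")
  }
  day[is.na(day)] <- 15L
  bad <- day < 1L | day > days_in_month[month]
  if (any(bad)) {
    abort(sprintf(
      "invalid day of month at position(s) %s.",
      paste(which(bad), collapse = ", ")
    ))
  }
  month_start_doy[month] + day - 1L
}

# Inverse of day_of_year(); doy outside 1..365 is wrapped first.
doy_to_month_day <- function(doy) {
  doy <- ((as.integer(round(doy)) - 1L) %% 365L) + 1L
  month <- findInterval(doy, month_start_doy)
  tibble(month = month, day = doy - month_start_doy[month] + 1L)
}

# Wrap a day-of-year into 1..365.
wrap_doy <- function(doy) ((as.integer(round(doy)) - 1L) %% 365L) + 1L

#' Meteorological season of a calendar month
#'
#' Month-triplet seasons (DJF winter, MAM spring, JJA summer, SON autumn),
#' flipped for the southern hemisphere.
#'
#' @param month Integer vector, 1-12.
#' @param hemisphere `"north"` or `"south"`.
#' @return Character vector in `c("winter", "spring", "summer", "autumn")`.
#' @examples
#' season_of_month(1)
#' season_of_month(1, "south")
#' @export
season_of_month <- function(month, hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  month <- as.integer(month)
  if (any(is.na(month) | month < 1L | month > 12L)) {
    abort("`month` must be an integer in 1..12.")
  }
  north <- c(
    "winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter"
  )
  flip <- c(
    winter = "summer", spring = "autumn",
    summer = "winter", autumn = "spring"
  )
  s <- north[month]
  if (hemisphere == "south") s <- unname(flip[s])
  s
}

# TRUE when two seasons are separated by an intervening season
# (spring-autumn or winter-summer); such pairs define scenario C.
seasons_nonconsecutive <- function(s1, s2) {
  opposite <- c(
    winter = "summer", summer = "winter",
    spring = "autumn", autumn = "spring"
  )
  !is.na(opposite[s1]) && identical(unname(opposite[s1]), s2)
}
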