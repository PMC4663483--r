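# Synthetic dated scratch densities. The generator reproduces the two sources
# of variability seen in extant dated samples: heterogeneity among individuals
# that died on the same date, and a season-dependent mean density that peaks
# in spring/summer (abrasive graze intake) and bottoms out in fall/winter.

#' Seasonal diet model for the scratch-density simulator
#'
#' A single-harmonic model of the expected scratch density through the year:
#' `baseline + amplitude * cos(2 * pi * (day - peak_day) / 365)`, with
#' individual heterogeneity around that mean of standard deviation
#' `individual_sd`. For a southern-hemisphere population the peak is shifted
#' by 182 days.
#'
#' The defaults (`baseline = 15`, `amplitude = 6`, `individual_sd = 1.5`,
#' `peak_day = 121`, i.e. a May peak) are calibrated so that variability
#' points of simulated scenario sub-samples land in the envelope of the
#' reference samples (SD roughly 0.8-7 scratches per 0.16 mm^2, CV roughly
#' 0.07-0.45); see the methods vignette for the calibration rationale.
#'
#' @param baseline Annual mean scratch density (scratches per 0.16 mm^2).
#' @param amplitude Seasonal swing around the baseline (same units); the
#'   expected density ranges over `baseline +/- amplitude`.
#' @param peak_day Day of year (1-365) of the seasonal maximum.
#' @param individual_sd Within-date SD across individuals (same units).
#' @param hemisphere `"north"` or `"south"`.
#' @return An object of class `seasonal_diet_model`.
#' @examples
#' m <- seasonal_diet_model()
#' seasonal_mean(c(121, 303), m)
#' @export
seasonal_diet_model <- function(baseline = 15, amplitude = 6, peak_day = 121L,
                                individual_sd = 1.5,
                                hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  if (baseline <= 0) abort("`baseline` must be > 0.")
  if (amplitude < 0) abort("`amplitude` must be >= 0.")
  if (individual_sd <= 0) abort("`individual_sd` must be > 0.")
  if (peak_day < 1 || peak_day > 365) abort("`peak_day` must be in 1..365.")
  if (baseline - amplitude < 0) {
    warn("baseline - amplitude < 0: simulated densities will be truncated at 0.")
  }
  structure(
    list(
      baseline = baseline, amplitude = amplitude,
      peak_day = as.integer(peak_day), individual_sd = individual_sd,
      hemisphere = hemisphere
    ),
    class = "seasonal_diet_model"
  )
}

#' @export
print.seasonal_diet_model <- function(x, ...) {
  cat(sprintf(
    "<seasonal_diet_model> baseline %.3g, amplitude %.3g, peak day %d (%s), individual sd %.3g\n",
    x$baseline, x$amplitude, x$peak_day, x$hemisphere, x$individual_sd
  ))
  invisible(x)
}

#' Expected scratch density on a given day of year
#'
#' @param day_of_year Integer vector of days of year (1-365).
#' @param model A [seasonal_diet_model()].
#' @return Expected density for each day.
#' @export
seasonal_mean <- function(day_of_year, model) {
  stopifnot(inherits(model, "seasonal_diet_model"))
  day <- as.numeric(day_of_year)
  if (any(is.na(day) | day < 1 | day > 365)) {
    abort("`day_of_year` must be in 1..365.")
  }
  peak <- model$peak_day + if (model$hemisphere == "south") 182 else 0
  model$baseline +
    model$amplitude * cos(2 * pi * (day - peak) / 365)
}

#' Simulate individual records for given death dates
#'
#' For each date, draws `n_per_date` per-individual scratch densities from a
#' normal distribution centred on [seasonal_mean()] with SD
#' `model$individual_sd`, left-truncated at zero (negative draws are set to 0;
#' with realistic parameters this is a negligible-probability event). Both
#' area counts of each simulated record are set to the drawn density, so
#' [individual_density()] recovers it exactly.
#'
#' @param dates A data frame with columns `month` and `day` (one row per
#'   mortality date), or an integer vector of days of year.
#' @param n_per_date Individuals drawn per date (>= 1).
#' @param model A [seasonal_diet_model()].
#' @param seed Optional integer seed; the same seed yields identical output.
#' @param sample_id Sample identifier for the emitted records.
#' @return A records tibble (see [read_records()]).
#' @examples
#' m <- seasonal_diet_model()
#' simulate_event(data.frame(month = 3, day = 12), n_per_date = 5, m, seed = 1)
#' @export
simulate_event <- function(dates, n_per_date = 1L, model, seed = NULL,
                           sample_id = "event") {
  stopifnot(inherits(model, "seasonal_diet_model"))
  if (n_per_date < 1) abort("`n_per_date` must be >= 1.")
  if (is.data.frame(dates)) {
    if (!all(c("month", "day") %in% names(dates))) {
      abort("`dates` must have columns `month` and `day`.")
    }
    doy <- day_of_year(dates$month, dates$day)
  } else {
    doy <- as.integer(dates)
    if (any(is.na(doy) | doy < 1 | doy > 365)) {
      abort("`dates` given as days of year must be in 1..365.")
    }
  }
  run <- function() {
    doy_all <- rep(doy, each = n_per_date)
    mu <- seasonal_mean(doy_all, model)
    dens <- pmax(0, rnorm(length(doy_all), mean = mu, sd = model$individual_sd))
    md <- doy_to_month_day(doy_all)
    tibble(
      specimen_id = sprintf("%s_%04d", sample_id, seq_along(doy_all)),
      sample_id = sample_id,
      species = "simulated",
      death_year = NA_integer_,
      death_month = md$month,
      death_day = md$day,
      count_area1 = dens,
      count_area2 = dens,
      hemisphere = model$hemisphere
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Evenly spaced days of year across a window, wrapping at year end.
even_dates <- function(start, length_days, k) {
  if (k == 1) {
    return(wrap_doy(start + (length_days - 1) / 2))
  }
  wrap_doy(start + (length_days - 1) * (seq_len(k) - 1) / (k - 1))
}

# Season of a window, taken at its midpoint date.
window_season <- function(start, length_days, hemisphere) {
  mid <- wrap_doy(start + (length_days - 1) / 2)
  season_of_month(doy_to_month_day(mid)$month, hemisphere)
}

#' Simulate a scenario-typed mortality event
#'
#' Generates dated individual records whose death dates realise one of the
#' three duration scenarios:
#' * `"A"` - one window of at most 92 days (one month up to a season);
#' * `"B"` - one window of 120 to 365 days (four months up to a year);
#' * `"C"` - two windows lying in non-consecutive (opposite) seasons, with a
#'   given proportion of deaths in the first (warm) window.
#'
#' Death dates are evenly spread within each window (avoiding blank periods
#' or concentrations); densities come from [simulate_event()].
#'
#' @param label Scenario label, `"A"`, `"B"` or `"C"`.
#' @param n Total number of individuals (a warning is issued below 15, the
#'   minimum size for a statistically acceptable sub-sample).
#' @param model A [seasonal_diet_model()].
#' @param window For `"A"`/`"B"`: `list(start = <day of year>, length =
#'   <days>)`. For `"C"`: `list(warm = list(start, length), cold =
#'   list(start, length), proportion = <warm-season fraction>)`.
#' @param seed Optional integer seed.
#' @param sample_id Sample identifier for the emitted records.
#' @return A records tibble.
#' @examples
#' m <- seasonal_diet_model()
#' simulate_scenario("A", 20, m, list(start = 32, length = 59), seed = 1)
#' @export
simulate_scenario <- function(label, n, model, window, seed = NULL,
                              sample_id = NULL) {
  label <- match.arg(as.character(label), scenario_levels)
  stopifnot(inherits(model, "seasonal_diet_model"))
  n <- as.integer(n)
  if (n < 2) abort("`n` must be >= 2.")
  if (n < 15) {
    warn(sprintf(
      "n = %d is below the minimum training sub-sample size of 15.", n
    ))
  }
  sample_id <- sample_id %||% paste0("sim", label)

  if (label %in% c("A", "B")) {
    if (!all(c("start", "length") %in% names(window))) {
      abort("`window` must be list(start =, length =) for scenarios A and B.")
    }
    len <- window$length
    if (label == "A" && (len < 1 || len > 92)) {
      abort("scenario A windows span at most 92 days (one month to a season).")
    }
    if (label == "B" && (len < 120 || len > 365)) {
      abort("scenario B windows span 120 to 365 days (four months to a year).")
    }
    doy <- even_dates(window$start, len, n)
    return(simulate_event(doy, 1L, model, seed = seed, sample_id = sample_id))
  }

  # scenario C: two windows in non-consecutive seasons
  if (!all(c("warm", "cold") %in% names(window))) {
    abort("`window` must be list(warm =, cold =, proportion =) for scenario C.")
  }
  p <- window$proportion %||% 0.5
  if (p <= 0 || p >= 1) abort("`proportion` must lie strictly in (0, 1).")
  s_warm <- window_season(window$warm$start, window$warm$length, model$hemisphere)
  s_cold <- window_season(window$cold$start, window$cold$length, model$hemisphere)
  if (!seasons_nonconsecutive(s_warm, s_cold)) {
    abort(sprintf(
      "scenario C windows must lie in non-consecutive seasons; got %s and %s.",
      s_warm, s_cold
    ))
  }
  n_warm <- max(1L, min(n - 1L, as.integer(round(p * n))))
  n_cold <- n - n_warm
  run <- function() {
    warm <- simulate_event(
      even_dates(window$warm$start, window$warm$length, n_warm),
      1L, model,
      sample_id = sample_id
    )
    cold <- simulate_event(
      even_dates(window$cold$start, window$cold$length, n_cold),
      1L, model,
      sample_id = sample_id
    )
    out <- dplyr::bind_rows(warm, cold)
    out$specimen_id <- sprintf("%s_%04d", sample_id, seq_len(nrow(out)))
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
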