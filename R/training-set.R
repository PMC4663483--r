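# Construction of the classifier training set: scenario-labelled variability
# points extracted from dated record sets under admissibility rules, or
# assembled for scenario C by replicating one season's records to sweep the
# warm/cold proportion.

default_min_size <- 15L

# Records' death dates as days of year (missing day -> mid-month).
record_doy <- function(records) {
  day_of_year(records$death_month, records$death_day)
}

#' Extract scenario-labelled training sub-samples from dated records
#'
#' Applies the training-set admissibility rules to user-declared time windows
#' over a set of dated individual records. A window's sub-sample is kept only
#' if:
#' * it holds at least `min_size` individuals (default 15; below that the
#'   sample SD is biased downward, see [sd_vs_n_bias()]) - this rule is never
#'   relaxed;
#' * the window length is consistent with its scenario (A: at most 92 days;
#'   B: 120-365 days);
#' * unless `relax = TRUE`, the deaths are evenly distributed: no blank gap
#'   (between consecutive deaths or from a window edge to the nearest death)
#'   exceeds `max_gap_frac` of the window length, and no single bin of
#'   `n_bins` equal divisions of the window holds more than `max_bin_frac`
#'   of the deaths.
#'
#' Discarded windows are logged with the violated rule in the `"log"`
#' attribute of the result.
#'
#' @param records A records tibble (see [read_records()]).
#' @param windows A data frame with columns `window_id`, `scenario` (`"A"` or
#'   `"B"`), `start_day` and `end_day` (days of year; windows may wrap the
#'   year end).
#' @param min_size Minimum sub-sample size (default 15).
#' @param relax Disable the evenness checks (never the size check).
#' @param max_gap_frac Maximum blank period as a fraction of window length.
#' @param n_bins,max_bin_frac Concentration rule: the window is split into
#'   `n_bins` equal bins and no bin may hold more than `max_bin_frac` of the
#'   deaths.
#' @inheritParams variability_point
#' @return A tibble of labelled variability points (`sample_id`, `n`, `mean`,
#'   `sd`, `cv`, `label`), possibly empty, with attribute `"log"`: a tibble
#'   of every window's admissibility decision and reason.
#' @examples
#' m <- seasonal_diet_model()
#' recs <- simulate_scenario("A", 20, m, list(start = 32, length = 59), seed = 1)
#' w <- data.frame(window_id = "feb_mar", scenario = "A",
#'                 start_day = 32, end_day = 90)
#' extract_subsamples(recs, w)
#' @export
extract_subsamples <- function(records, windows, min_size = default_min_size,
                               relax = FALSE, max_gap_frac = 1 / 3,
                               n_bins = 6L, max_bin_frac = 1 / 2,
                               sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  records <- validate_records(records)
  windows <- as_tibble(windows)
  req <- c("window_id", "scenario", "start_day", "end_day")
  if (!all(req %in% names(windows))) {
    abort(sprintf("`windows` needs columns %s.", paste(req, collapse = ", ")))
  }
  doy <- record_doy(records)
  dens <- individual_density(records$count_area1, records$count_area2)

  assess <- function(w) {
    len <- (w$end_day - w$start_day) %% 365 + 1
    offset <- (doy - w$start_day) %% 365
    inside <- offset < len
    n_in <- sum(inside)
    reason <- NULL
    if (w$scenario == "A" && len > 92) {
      reason <- "window longer than 92 days is inconsistent with scenario A"
    } else if (w$scenario == "B" && (len < 120 || len > 365)) {
      reason <- "window length outside 120-365 days is inconsistent with scenario B"
    } else if (n_in < min_size) {
      reason <- sprintf("only %d individuals; minimum sub-sample size is %d",
        n_in, min_size)
    } else if (!relax) {
      off <- sort(offset[inside])
      gaps <- c(off[1], diff(off), (len - 1) - off[n_in])
      bins <- pmin(floor(off / (len / n_bins)) + 1, n_bins)
      if (max(gaps) > max_gap_frac * len) {
        reason <- sprintf(
          "blank period of %.0f days exceeds %.0f%% of the %d-day window",
          max(gaps), 100 * max_gap_frac, round(len)
        )
      } else if (max(tabulate(bins, n_bins)) > max_bin_frac * n_in) {
        reason <- sprintf(
          "more than %.0f%% of deaths concentrated in one sixth of the window",
          100 * max_bin_frac
        )
      }
    }
    list(inside = inside, n = n_in, reason = reason)
  }

  points <- list()
  logs <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    a <- assess(w)
    ok <- is.null(a$reason)
    logs[[i]] <- tibble(
      window_id = as.character(w$window_id), scenario = w$scenario,
      n = a$n, admissible = ok,
      reason = if (ok) NA_character_ else a$reason
    )
    if (ok) {
      pt <- variability_point(dens[a$inside], w$window_id,
        sd_denominator = sd_denominator)
      pt$label <- w$scenario
      points[[length(points) + 1]] <- pt
    }
  }
  out <- if (length(points) > 0) {
    dplyr::bind_rows(points)
  } else {
    tibble(
      sample_id = character(), n = integer(), mean = numeric(),
      sd = numeric(), cv = numeric(), label = character()
    )
  }
  attr(out, "log") <- dplyr::bind_rows(logs)
  out
}

#' Assemble scenario-C training points by replicating one season's records
#'
#' Scenario C (two short events in opposite seasons) is rarely observed with
#' balanced group sizes, so training points covering the spectrum of
#' warm/cold proportions are assembled by replicating records of one of the
#' two groups until the warm-season fraction matches each target proportion.
#' Replication changes relative frequencies only: no density value absent
#' from the input is introduced.
#'
#' @param group_warm,group_cold Records tibbles of the two death groups; each
#'   group must lie within a single season and the two seasons must be
#'   non-consecutive (spring/autumn or winter/summer).
#' @param proportions Target warm-season fractions, strictly in (0, 1). The
#'   default nine-value grid 0.1-0.9 covers the spectrum of possibilities.
#' @param min_size Minimum pooled size; proportions whose pooled sub-sample
#'   falls below it are skipped.
#' @param sample_prefix Prefix for the emitted `sample_id`s.
#' @inheritParams variability_point
#' @return A tibble of labelled variability points (label `"C"`), one row per
#'   achievable proportion, with a `proportion` column.
#' @export
build_scenario_c <- function(group_warm, group_cold,
                             proportions = seq(0.1, 0.9, by = 0.1),
                             min_size = default_min_size,
                             sample_prefix = "C",
                             sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  group_warm <- validate_records(group_warm)
  group_cold <- validate_records(group_cold)
  if (nrow(group_warm) == 0 || nrow(group_cold) == 0) {
    abort("both groups must be non-empty.")
  }
  if (any(proportions <= 0 | proportions >= 1)) {
    abort("`proportions` must lie strictly in (0, 1).")
  }
  group_season <- function(g, which) {
    s <- unique(season_of_month(g$death_month, g$hemisphere[1]))
    if (length(s) != 1) {
      abort(sprintf("the %s group must lie within a single season.", which))
    }
    s
  }
  s_warm <- group_season(group_warm, "warm")
  s_cold <- group_season(group_cold, "cold")
  if (!seasons_nonconsecutive(s_warm, s_cold)) {
    abort(sprintf(
      "group seasons must be non-consecutive (opposite); got %s and %s.",
      s_warm, s_cold
    ))
  }
  d_warm <- individual_density(group_warm$count_area1, group_warm$count_area2)
  d_cold <- individual_density(group_cold$count_area1, group_cold$count_area2)
  n_w <- length(d_warm)
  n_c <- length(d_cold)

  purrr::map_dfr(proportions, function(p) {
    # replicate whichever group is under-represented relative to p,
    # cycling through its members so frequencies change but values do not
    if (p > n_w / (n_w + n_c)) {
      m_w <- max(1L, as.integer(round(p / (1 - p) * n_c)))
      m_c <- n_c
    } else {
      m_w <- n_w
      m_c <- max(1L, as.integer(round((1 - p) / p * n_w)))
    }
    if (m_w + m_c < min_size) {
      return(tibble())
    }
    pooled <- c(
      d_warm[rep(seq_len(n_w), length.out = m_w)],
      d_cold[rep(seq_len(n_c), length.out = m_c)]
    )
    pt <- variability_point(pooled, sprintf("%s_p%.2f", sample_prefix, p),
      sd_denominator = sd_denominator)
    pt$label <- "C"
    pt$proportion <- p
    pt
  })
}

#' Default calibrated synthetic training set
#'
#' Generates the scenario-labelled training points used by the classifier's
#' default training path: simulated mortality events under a
#' [seasonal_diet_model()], passed through the admissibility rules of
#' [extract_subsamples()] (scenarios A and B) and through
#' [build_scenario_c()] (scenario C).
#'
#' The window layout samples each scenario's definition across the seasonal
#' cycle: scenario A uses windows of 31, 61 and 92 days centred on the
#' seasonal peak, the trough and the two intermediate nodes; scenario B uses
#' windows of 240, 300 and 365 days at varied positions; scenario C pools a
#' one-month event at the peak with one at the trough, swept over the
#' nine-value proportion grid.
#'
#' @param model A [seasonal_diet_model()].
#' @param seed Optional integer seed; sub-seeds for each simulated window are
#'   drawn from a single stream seeded once with it.
#' @param n_per_subsample Individuals per simulated window (default 30).
#' @param min_size Minimum sub-sample size (default 15).
#' @return A tibble of labelled variability points (`sample_id`, `n`, `mean`,
#'   `sd`, `cv`, `label`).
#' @examples
#' pts <- simulate_training_points(seed = 1)
#' dplyr::count(pts, label)
#' @export
simulate_training_points <- function(model = seasonal_diet_model(),
                                     seed = NULL, n_per_subsample = 30L,
                                     min_size = default_min_size) {
  stopifnot(inherits(model, "seasonal_diet_model"))
  run <- function() {
    peak <- model$peak_day
    centres <- c(
      peak = peak, node1 = peak + 91, trough = peak + 182, node2 = peak + 273
    )
    a_spec <- tidyr::expand_grid(
      centre = names(centres), length = c(31, 61, 92)
    )
    b_spec <- dplyr::bind_rows(
      tidyr::expand_grid(centre = names(centres), length = 240),
      tidyr::expand_grid(centre = c("peak", "node1", "trough"), length = 300),
      tibble(centre = c("peak", "trough"), length = 365)
    )
    sim_one <- function(scenario, centre, length) {
      start <- wrap_doy(centres[[centre]] - (length - 1) / 2)
      id <- sprintf("%s_%s_%dd", scenario, centre, length)
      recs <- simulate_scenario(
        scenario, n_per_subsample, model,
        list(start = start, length = length),
        seed = sample.int(.Machine$integer.max, 1), sample_id = id
      )
      w <- tibble(
        window_id = id, scenario = scenario,
        start_day = start, end_day = wrap_doy(start + length - 1)
      )
      extract_subsamples(recs, w, min_size = min_size)
    }
    sub_a <- purrr::pmap(
      a_spec, function(centre, length) sim_one("A", centre, length)
    )
    sub_b <- purrr::pmap(
      b_spec, function(centre, length) sim_one("B", centre, length)
    )
    logs <- purrr::map_dfr(c(sub_a, sub_b), attr, "log")
    pts_a <- dplyr::bind_rows(sub_a)
    pts_b <- dplyr::bind_rows(sub_b)
    warm <- simulate_event(
      even_dates(wrap_doy(peak - 15), 31, n_per_subsample), 1L, model,
      seed = sample.int(.Machine$integer.max, 1), sample_id = "C_warm"
    )
    cold <- simulate_event(
      even_dates(wrap_doy(peak + 167), 31, n_per_subsample), 1L, model,
      seed = sample.int(.Machine$integer.max, 1), sample_id = "C_cold"
    )
    pts_c <- build_scenario_c(warm, cold, min_size = min_size)
    out <- dplyr::bind_rows(pts_a, pts_b, pts_c[, names(pts_a)])
    attr(out, "log") <- logs
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
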