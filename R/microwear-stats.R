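# Per-individual scratch densities and per-sample variability coordinates.
# A sample's (SD, CV) pair is the point the classifier works on: SD is the
# x-coordinate, CV = SD / mean the y-coordinate of the variability plane.

#' Scratch density of one individual
#'
#' Two standard 0.16 mm^2 areas are counted per tooth and averaged; when only
#' one area was countable the single count is used as-is.
#'
#' @param count_area1 Non-negative scratch count of the first area (required).
#' @param count_area2 Non-negative scratch count of the second area, or `NA`.
#' @return The per-individual scratch density (scratches per 0.16 mm^2),
#'   vectorised over the inputs.
#' @examples
#' individual_density(17, 19)
#' individual_density(20, NA)
#' @export
individual_density <- function(count_area1, count_area2 = NA_real_) {
  n <- max(length(count_area1), length(count_area2))
  c1 <- rep_len(as.numeric(count_area1), n)
  c2 <- rep_len(as.numeric(count_area2), n)
  if (any(is.na(c1))) {
    abort(sprintf(
      "count_area1 is missing in row(s) %s; at least one area count is required.",
      paste(which(is.na(c1)), collapse = ", ")
    ))
  }
  if (any(c1 < 0 | !is.finite(c1)) || any(!is.na(c2) & (c2 < 0 | !is.finite(c2)))) {
    abort("scratch counts must be finite and >= 0.")
  }
  ifelse(is.na(c2), c1, (c1 + c2) / 2)
}

#' Variability coordinates of one sample
#'
#' Computes the sample mean, standard deviation and coefficient of variation
#' of a vector of per-individual scratch densities. The SD uses the sample
#' formula (denominator n - 1) by default; `sd_denominator = "n"` switches to
#' the population formula. CV is reported as a dimensionless ratio
#' (`sd / mean`), not a percentage.
#'
#' @param densities Numeric vector of per-individual densities, length >= 2.
#' @param sample_id Identifier carried into the output.
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return A one-row tibble with columns `sample_id`, `n`, `mean`, `sd`, `cv`.
#' @examples
#' variability_point(c(8, 10, 12), "toy")
#' @export
variability_point <- function(densities, sample_id = "sample",
                              sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  densities <- as.numeric(densities)
  if (any(!is.finite(densities))) abort("densities must be finite.")
  n <- length(densities)
  if (n < 2) abort("sd undefined: at least 2 densities are required.")
  m <- mean(densities)
  if (m <= 0) abort("cv undefined: mean density must be > 0.")
  s <- stats::sd(densities)
  if (sd_denominator == "n") s <- s * sqrt((n - 1) / n)
  tibble(
    sample_id = as.character(sample_id), n = n,
    mean = m, sd = s, cv = s / m
  )
}

#' Per-sample variability from individual records
#'
#' Data-frame-first wrapper: derives each specimen's scratch density via
#' [individual_density()] and summarises the variability coordinates per
#' group.
#'
#' @param records A records tibble (see [read_records()]).
#' @param by Grouping column name (default `"sample_id"`).
#' @inheritParams variability_point
#' @return A tibble with one row per group: `sample_id`, `n`, `mean`, `sd`,
#'   `cv`.
#' @examples
#' recs <- tibble::tibble(
#'   specimen_id = paste0("s", 1:4), sample_id = "ev1", species = "sp",
#'   death_year = NA_integer_, death_month = 3L, death_day = 1L,
#'   count_area1 = c(8, 10, 12, 10), count_area2 = NA_real_,
#'   hemisphere = "north"
#' )
#' sample_variability(recs)
#' @export
sample_variability <- function(records, by = "sample_id",
                               sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  records <- as_tibble(records)
  if (!by %in% names(records)) {
    abort(sprintf("grouping column '%s' not found.", by))
  }
  records$.density <- individual_density(
    records$count_area1, records$count_area2
  )
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      variability_point(d$.density, sd_denominator = sd_denominator)[
        ,
        c("n", "mean", "sd", "cv")
      ]
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(sample_id = dplyr::all_of(by))
}

#' Small-sample bias of the standard deviation
#'
#' Monte-Carlo illustration of why very small sub-samples are excluded from
#' classifier training: the expected sample SD of a subset decreases as the
#' subset shrinks, so SD correlates negatively with sub-sample size. For each
#' requested size the mean sample SD over `reps` random subsets (drawn
#' without replacement) is returned.
#'
#' @param population Numeric vector to subsample.
#' @param sizes Integer subset sizes, each <= `length(population)`.
#' @param reps Number of random subsets per size (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `n` and `mean_sd`, one row per size.
#' @examples
#' sd_vs_n_bias(rnorm(200, 15, 2), sizes = c(5, 15, 50), reps = 200, seed = 1)
#' @export
sd_vs_n_bias <- function(population, sizes, reps = 1000L, seed = NULL) {
  population <- as.numeric(population)
  sizes <- as.integer(sizes)
  if (length(reps) != 1 || is.na(reps) || reps < 1) {
    abort("`reps` must be a positive integer.")
  }
  if (any(sizes < 2)) abort("every size must be >= 2 for the SD to exist.")
  if (any(sizes > length(population))) {
    abort("sizes must not exceed the population length.")
  }
  run <- function() {
    purrr::map_dfr(sizes, function(n) {
      s <- vapply(
        seq_len(reps),
        function(i) stats::sd(sample(population, n)), numeric(1)
      )
      tibble(n = n, mean_sd = mean(s))
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
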