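# Builders for in-code fixtures.

# A records tibble from densities and dates; both area counts carry the
# density so individual_density() recovers it exactly.
make_records <- function(densities, month, day = 15L, sample_id = "s1",
                         hemisphere = "north", year = NA_integer_) {
  n <- length(densities)
  tibble::tibble(
    specimen_id = sprintf("%s_%03d", sample_id, seq_len(n)),
    sample_id = sample_id,
    species = "test",
    death_year = rep_len(as.integer(year), n),
    death_month = rep_len(as.integer(month), n),
    death_day = rep_len(as.integer(day), n),
    count_area1 = densities,
    count_area2 = densities,
    hemisphere = rep_len(hemisphere, n)
  )
}

# Densities with exact sample mean m and sample sd s (n >= 3).
densities_with_stats <- function(n, m, s, seed = 1) {
  v <- withr::with_seed(seed, stats::rnorm(n))
  z <- (v - mean(v)) / stats::sd(v)
  m + s * z
}

# Labelled (sd, cv) training points with exactly known per-class Gaussians
# is impossible; this draws them from known Gaussians for recovery tests.
draw_labelled_points <- function(n_per_class, pars, seed = 1) {
  withr::with_seed(seed, purrr::map_dfr(names(pars), function(l) {
    p <- pars[[l]]
    tibble::tibble(
      sample_id = sprintf("%s%03d", l, seq_len(n_per_class)),
      sd = stats::rnorm(n_per_class, p$mu_x, p$sigma_x),
      cv = stats::rnorm(n_per_class, p$mu_y, p$sigma_y),
      label = l
    )
  }))
}

# Hand-placed training points giving a well-separated fitted model with
# identical axis sigmas across classes (A-B boundary = vertical bisector).
separable_points <- function() {
  grid4 <- function(cx, cy) {
    tibble::tibble(
      sd = cx + c(-0.1, 0.1, -0.1, 0.1),
      cv = cy + c(-0.01, -0.01, 0.01, 0.01)
    )
  }
  dplyr::bind_rows(
    dplyr::mutate(grid4(1, 0.10), label = "A"),
    dplyr::mutate(grid4(3, 0.10), label = "B"),
    dplyr::mutate(grid4(10, 0.40), label = "C")
  )
}
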