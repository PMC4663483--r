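# Three-class Gaussian naive-Bayes classifier on the SD-CV plane.
#
# Each duration scenario k in {A, B, C} gets an axis-aligned bivariate
# Gaussian G_k(x, y) = p_k N(x; mu_xk, sigma_xk) N(y; mu_yk, sigma_yk),
# x = SD and y = CV being treated as independent features. The plane is
# partitioned into three regions by argmax_k G_k; the total mixture
# G = sum_k G_k supports the probability isolines and the uncertainty map.

#' Evaluation grid over the SD-CV plane
#'
#' Bounds and resolution of the rectangular grid used for boundary
#' extraction, the uncertainty map, isoline levels and all numerical
#' integrals. Bounds left `NULL` are resolved at fit time to cover both the
#' reference-sample envelope (SD 0-8, CV 0-0.45) and six class standard
#' deviations around every class mean, so that the mixture's probability
#' mass is captured to numerical precision (this includes a small negative
#' margin: the Gaussian model assigns negligible mass to negative SD or CV).
#'
#' @param xlim,ylim Numeric length-2 bounds for SD and CV, or `NULL` to
#'   resolve from the fitted classes.
#' @param nx,ny Number of grid cells per axis (default 500 x 500).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(xlim = NULL, ylim = NULL, nx = 500L, ny = 500L) {
  if (nx < 50 || ny < 50) abort("grid resolution must be at least 50 x 50.")
  structure(
    list(xlim = xlim, ylim = ylim, nx = as.integer(nx), ny = as.integer(ny)),
    class = "grid_spec"
  )
}

resolve_grid <- function(grid, classes) {
  lim <- function(user, mu, sigma, hi_default) {
    if (!is.null(user)) {
      return(as.numeric(user))
    }
    c(
      min(0, min(mu - 6 * sigma)) - 1e-9,
      max(hi_default, max(mu + 6 * sigma))
    )
  }
  grid$xlim <- lim(grid$xlim, classes$mu_x, classes$sigma_x, 8)
  grid$ylim <- lim(grid$ylim, classes$mu_y, classes$sigma_y, 0.45)
  grid
}

# Cell-centre coordinates and cell area of a resolved grid.
grid_axes <- function(grid) {
  dx <- diff(grid$xlim) / grid$nx
  dy <- diff(grid$ylim) / grid$ny
  list(
    x = grid$xlim[1] + (seq_len(grid$nx) - 0.5) * dx,
    y = grid$ylim[1] + (seq_len(grid$ny) - 0.5) * dy,
    cell = dx * dy, dx = dx, dy = dy
  )
}

#' Fit the three-class naive-Bayes classifier on (SD, CV) points
#'
#' For each scenario class the Gaussian parameters are the sample mean and
#' sample standard deviation of the training points' `sd` (x) and `cv` (y)
#' coordinates; the naive independence assumption means no covariance is
#' estimated. Priors default to 1/3 each, reflecting the absence of prior
#' information on real case frequencies; informative priors can be supplied.
#'
#' @param points A tibble of labelled variability points with columns `sd`,
#'   `cv` and `label` (values `"A"`, `"B"`, `"C"`), e.g. from
#'   [simulate_training_points()] or [extract_subsamples()].
#' @param priors Named numeric vector of class weights (names `A`, `B`, `C`),
#'   normalised to sum to 1. Default: equal weights.
#' @param grid A [grid_spec()]; `NULL` bounds are resolved from the fit.
#' @return An object of class `microwear_nb` with elements `classes` (tibble
#'   of per-class `label`, `prior`, `mu_x`, `sigma_x`, `mu_y`, `sigma_y`,
#'   `n`), `grid` (resolved), and `n_train`.
#' @examples
#' pts <- simulate_training_points(seed = 1)
#' fit <- fit_microwear_classifier(pts)
#' fit
#' @export
fit_microwear_classifier <- function(points, priors = NULL, grid = grid_spec()) {
  points <- as_tibble(points)
  if (!all(c("sd", "cv", "label") %in% names(points))) {
    abort("`points` needs columns sd, cv and label.")
  }
  if (!all(points$label %in% scenario_levels)) {
    abort("labels must be 'A', 'B' or 'C'.")
  }
  if (!all(scenario_levels %in% points$label)) {
    abort(sprintf(
      "training points for every class are required; missing: %s.",
      paste(setdiff(scenario_levels, points$label), collapse = ", ")
    ))
  }
  if (any(!is.finite(points$sd)) || any(!is.finite(points$cv))) {
    abort("training coordinates must be finite.")
  }
  priors <- priors %||% setNames(rep(1 / 3, 3), scenario_levels)
  if (!all(scenario_levels %in% names(priors)) || any(priors <= 0)) {
    abort("`priors` must be positive and named A, B, C.")
  }
  priors <- priors[scenario_levels] / sum(priors[scenario_levels])

  classes <- points |>
    dplyr::group_by(label = factor(.data$label, scenario_levels)) |>
    dplyr::summarise(
      n = dplyr::n(),
      mu_x = mean(.data$sd), sigma_x = stats::sd(.data$sd),
      mu_y = mean(.data$cv), sigma_y = stats::sd(.data$cv),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = as.character(label))
  if (any(classes$n < 2)) {
    abort(sprintf(
      "each class needs >= 2 training points; got %s.",
      paste(sprintf("%s: %d", classes$label, classes$n), collapse = ", ")
    ))
  }
  degenerate <- classes$sigma_x == 0 | classes$sigma_y == 0
  if (any(degenerate)) {
    abort(c(
      sprintf(
        "zero within-class variance on an axis for class(es) %s.",
        paste(classes$label[degenerate], collapse = ", ")
      ),
      i = "add training sub-samples with distinct (sd, cv) coordinates, e.g. from more windows or seeds."
    ))
  }
  classes$prior <- unname(priors)
  classes <- classes[, c(
    "label", "prior", "mu_x", "sigma_x", "mu_y", "sigma_y", "n"
  )]
  structure(
    list(
      classes = classes,
      grid = resolve_grid(grid, classes),
      n_train = nrow(points)
    ),
    class = "microwear_nb"
  )
}

#' @export
print.microwear_nb <- function(x, ...) {
  cat(sprintf(
    "<microwear_nb> 3-class Gaussian naive-Bayes on the SD-CV plane (%d training points)\n",
    x$n_train
  ))
  print(x$classes)
  cat(sprintf(
    "grid: %d x %d over SD [%.3g, %.3g], CV [%.3g, %.3g]\n",
    x$grid$nx, x$grid$ny, x$grid$xlim[1], x$grid$xlim[2],
    x$grid$ylim[1], x$grid$ylim[2]
  ))
  invisible(x)
}

check_fitted <- function(model) {
  if (!inherits(model, "microwear_nb")) {
    abort("`model` must be a fitted `microwear_nb` object.")
  }
  model
}

#' Weighted class density at points of the SD-CV plane
#'
#' Evaluates `G_k(x, y) = prior_k * N(x; mu_xk, sigma_xk) *
#' N(y; mu_yk, sigma_yk)` for one class, vectorised over `x` and `y`.
#'
#' @param model A fitted [fit_microwear_classifier()] model.
#' @param label Class label `"A"`, `"B"` or `"C"`.
#' @param x,y SD and CV coordinates.
#' @return Non-negative densities.
#' @export
class_density <- function(model, label, x, y) {
  check_fitted(model)
  label <- match.arg(as.character(label), scenario_levels)
  k <- model$classes[model$classes$label == label, ]
  k$prior * dnorm(x, k$mu_x, k$sigma_x) * dnorm(y, k$mu_y, k$sigma_y)
}

#' Total mixture density G(x, y)
#'
#' The total probability distribution for a new mortality event to be found
#' at position (x, y) = (SD, CV): the sum of the three weighted class
#' densities.
#'
#' @inheritParams class_density
#' @return Non-negative densities, vectorised over `x` and `y`.
#' @export
mixture_density <- function(model, x, y) {
  check_fitted(model)
  Reduce(`+`, lapply(scenario_levels, function(l) class_density(model, l, x, y)))
}

# The three class-density matrices over the model grid (nx x ny each).
density_grids <- function(model) {
  ax <- grid_axes(model$grid)
  dens <- lapply(scenario_levels, function(l) {
    k <- model$classes[model$classes$label == l, ]
    k$prior * outer(
      dnorm(ax$x, k$mu_x, k$sigma_x),
      dnorm(ax$y, k$mu_y, k$sigma_y)
    )
  })
  names(dens) <- scenario_levels
  list(axes = ax, dens = dens, total = Reduce(`+`, dens))
}

# argmax class index at every grid node, ties broken in order A < B < C
# (max.col's first-tie rule), a measure-zero event kept deterministic.
region_grid <- function(dg) {
  flat <- vapply(dg$dens, as.vector, numeric(length(dg$total)))
  matrix(max.col(flat, ties.method = "first"), nrow = nrow(dg$total))
}

#' Classify samples by their position in the SD-CV plane
#'
#' Assigns each (SD, CV) point to the region whose weighted class density is
#' largest, with posterior probabilities `G_k / sum_j G_j`, the
#' classification uncertainty `error_prob = 1 - max posterior`, and the
#' innermost default probability isoline of the total mixture containing the
#' point. Ties are broken in the fixed order A < B < C.
#'
#' @param model A fitted [fit_microwear_classifier()] model.
#' @param points A data frame with columns `sd` and `cv` (e.g.
#'   [reference_samples()] or [sample_variability()] output).
#' @param isoline_masses Probability masses of the isolines used for the
#'   `inside_isoline` column, or `NULL` to skip that column.
#' @return The input tibble with added columns `region`, `posterior_A`,
#'   `posterior_B`, `posterior_C`, `error_prob` and (unless skipped)
#'   `inside_isoline` (smallest listed mass whose isoline contains the
#'   point; `Inf` if outside all).
#' @examples
#' fit <- fit_microwear_classifier(simulate_training_points(seed = 1))
#' classify_samples(fit, reference_samples("fossil"))
#' @export
classify_samples <- function(model, points,
                             isoline_masses = c(0.68, 0.95, 0.995)) {
  check_fitted(model)
  points <- as_tibble(points)
  if (!all(c("sd", "cv") %in% names(points))) {
    abort("`points` needs columns sd and cv.")
  }
  if (any(!is.finite(points$sd)) || any(!is.finite(points$cv))) {
    abort("non-finite (sd, cv) coordinates cannot be classified.")
  }
  g <- vapply(
    scenario_levels,
    function(l) class_density(model, l, points$sd, points$cv),
    numeric(nrow(points))
  )
  g <- matrix(g, nrow = nrow(points))
  post <- g / rowSums(g)
  idx <- max.col(post, ties.method = "first")
  out <- points
  out$region <- scenario_levels[idx]
  out$posterior_A <- post[, 1]
  out$posterior_B <- post[, 2]
  out$posterior_C <- post[, 3]
  out$error_prob <- 1 - post[cbind(seq_len(nrow(post)), idx)]
  if (!is.null(isoline_masses)) {
    lv <- isoline_levels(model, sort(isoline_masses))
    gtot <- rowSums(g)
    out$inside_isoline <- vapply(gtot, function(v) {
      inside <- lv$mass[v >= lv$level]
      if (length(inside) == 0) Inf else min(inside)
    }, numeric(1))
  }
  out
}

#' @rdname classify_samples
#' @param object A fitted `microwear_nb` model.
#' @param newdata Points to classify; defaults to the fossil
#'   [reference_samples()].
#' @param ... Passed to [classify_samples()].
#' @export
predict.microwear_nb <- function(object, newdata = reference_samples("fossil"),
                                 ...) {
  classify_samples(object, newdata, ...)
}

#' Decision boundary between two classes
#'
#' Extracts the locus where the two weighted class densities are equal (the
#' zero-level contour of `log G_i - log G_j`) on the model grid. The
#' boundaries used by the region partition are (A, B) and (B, C); the A-C
#' pair is computed on request with a warning, since the A and C
#' distributions barely overlap and that boundary plays no role in practice.
#'
#' @param model A fitted model.
#' @param pair Character vector of two distinct class labels.
#' @return A tibble with columns `segment`, `x` (SD), `y` (CV) tracing the
#'   boundary polyline(s).
#' @export
boundary_curve <- function(model, pair = c("A", "B")) {
  check_fitted(model)
  pair <- match.arg(pair, scenario_levels, several.ok = TRUE)
  if (length(pair) != 2 || pair[1] == pair[2]) {
    abort("`pair` must name two distinct classes.")
  }
  if (setequal(pair, c("A", "C"))) {
    warn("the A-C boundary is not used by the region partition (the two distributions barely overlap); computing it anyway.")
  }
  dg <- density_grids(model)
  z <- log(dg$dens[[pair[1]]]) - log(dg$dens[[pair[2]]])
  cl <- grDevices::contourLines(dg$axes$x, dg$axes$y, z, levels = 0)
  if (length(cl) == 0) {
    return(tibble(segment = integer(), x = numeric(), y = numeric()))
  }
  purrr::imap_dfr(cl, function(s, i) tibble(segment = i, x = s$x, y = s$y))
}

#' Classification-uncertainty map
#'
#' Evaluates, at every grid node, the probability that a case located there
#' does not belong to the region it falls in. The default measure is
#' `1 - max posterior`, which forms bands along the region boundaries (0.5 on
#' a two-class boundary, up to 2/3 at a three-class meet) and vanishes far
#' from them; `measure = "margin"` instead reports 1 minus the difference of
#' the top-two posteriors.
#'
#' @param model A fitted model.
#' @param measure `"one_minus_max"` (default) or `"margin"`.
#' @return A tibble with columns `x` (SD), `y` (CV), `region`, `error_prob`.
#' @export
error_map <- function(model, measure = c("one_minus_max", "margin")) {
  measure <- match.arg(measure)
  check_fitted(model)
  dg <- density_grids(model)
  flat <- vapply(dg$dens, as.vector, numeric(length(dg$total)))
  post <- flat / rowSums(flat)
  sorted_top <- function(p) {
    i <- max.col(p, ties.method = "first")
    top <- p[cbind(seq_len(nrow(p)), i)]
    p[cbind(seq_len(nrow(p)), i)] <- -Inf
    j <- max.col(p, ties.method = "first")
    list(idx = i, top = top, second = p[cbind(seq_len(nrow(p)), j)])
  }
  st <- sorted_top(post)
  err <- switch(measure,
    one_minus_max = 1 - st$top,
    margin = 1 - (st$top - st$second)
  )
  tibble(
    x = rep(dg$axes$x, times = model$grid$ny),
    y = rep(dg$axes$y, each = model$grid$nx),
    region = scenario_levels[st$idx],
    error_prob = err
  )
}

#' Probability-isoline levels of the total mixture
#'
#' For each target mass `m`, finds by bisection the density level `c` such
#' that the mixture mass integrated (midpoint rule on the model grid) over
#' `{G >= c}` equals `m`. The level-`c` contour of G then encloses a region
#' of total probability `m`.
#'
#' @param model A fitted model.
#' @param masses Target probability masses in (0, 1). The defaults follow the
#'   1, 2 and 3 sigma ladder: 68%, 95% and 99.5%.
#' @param tol Bisection tolerance on the enclosed mass.
#' @return A tibble with columns `mass`, `level`, `enclosed_mass` (grid
#'   integral actually achieved).
#' @export
isoline_levels <- function(model, masses = c(0.68, 0.95, 0.995), tol = 1e-6) {
  check_fitted(model)
  if (any(masses <= 0 | masses >= 1)) abort("`masses` must lie in (0, 1).")
  dg <- density_grids(model)
  g <- as.vector(dg$total)
  cell <- dg$axes$cell
  total_mass <- sum(g) * cell
  if (total_mass < max(masses)) {
    abort(sprintf(
      "the grid captures only %.4f probability mass, below the requested %.4f; enlarge the grid bounds via grid_spec().",
      total_mass, max(masses)
    ))
  }
  mass_above <- function(level) sum(g[g >= level]) * cell
  purrr::map_dfr(masses, function(m) {
    lo <- 0
    hi <- max(g)
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (mass_above(mid) >= m) lo <- mid else hi <- mid
      if (hi - lo < tol * max(g)) break
    }
    tibble(mass = m, level = lo, enclosed_mass = mass_above(lo))
  })
}

#' Probability isolines of the total mixture
#'
#' Contours of G(x, y) enclosing the target probability masses (see
#' [isoline_levels()]). Sorted ascending masses yield descending levels and
#' nested contours.
#'
#' @inheritParams isoline_levels
#' @return A tibble with columns `mass`, `level`, `segment`, `x`, `y`.
#' @export
isolines <- function(model, masses = c(0.68, 0.95, 0.995)) {
  lv <- isoline_levels(model, masses)
  dg <- density_grids(model)
  purrr::pmap_dfr(lv, function(mass, level, enclosed_mass) {
    cl <- grDevices::contourLines(dg$axes$x, dg$axes$y, dg$total,
      levels = level)
    purrr::imap_dfr(cl, function(s, i) {
      tibble(mass = mass, level = level, segment = i, x = s$x, y = s$y)
    })
  })
}

#' Expected total error of the classifier
#'
#' The sum over classes of the probability mass of each class distribution
#' lying outside its own region (beyond the decision boundaries), computed by
#' midpoint integration on the model grid. Equivalently (checked numerically
#' in the test suite) `1 - integral of max_k G_k`. The A-C overlap term -
#' mass of G_A in region C plus mass of G_C in region A - is reported
#' separately so that its negligibility can be verified.
#'
#' @param model A fitted model.
#' @return A one-row tibble with columns `total`, `error_A`, `error_B`,
#'   `error_C`, `ac_overlap`.
#' @export
expected_total_error <- function(model) {
  check_fitted(model)
  dg <- density_grids(model)
  reg <- region_grid(dg)
  cell <- dg$axes$cell
  err <- vapply(seq_along(scenario_levels), function(k) {
    sum(dg$dens[[k]][reg != k]) * cell
  }, numeric(1))
  ac <- (sum(dg$dens[["A"]][reg == 3]) + sum(dg$dens[["C"]][reg == 1])) * cell
  tibble(
    total = sum(err),
    error_A = err[1], error_B = err[2], error_C = err[3],
    ac_overlap = ac
  )
}

#' Draw random (SD, CV) points from the fitted mixture
#'
#' Samples class labels from the priors and coordinates from the selected
#' class Gaussians. This sampler is independent of the grid-based machinery
#' and serves as a Monte-Carlo oracle for the isoline mass calibration.
#'
#' @param model A fitted model.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return A tibble with columns `x` (SD), `y` (CV), `label`.
#' @export
sample_mixture <- function(model, n, seed = NULL) {
  check_fitted(model)
  run <- function() {
    k <- sample(3L, n, replace = TRUE, prob = model$classes$prior)
    cl <- model$classes[k, ]
    tibble(
      x = rnorm(n, cl$mu_x, cl$sigma_x),
      y = rnorm(n, cl$mu_y, cl$sigma_y),
      label = cl$label
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
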