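# broom-style accessors, plotting and JSON serialisation for microwear_nb.

#' Tidy the per-class parameters of a fitted classifier
#'
#' @param x A fitted `microwear_nb` model.
#' @param ... Unused.
#' @return A tibble with one row per class: `label`, `prior`, `mu_x`,
#'   `sigma_x`, `mu_y`, `sigma_y`, `n`.
#' @method tidy microwear_nb
#' @export
tidy.microwear_nb <- function(x, ...) {
  check_fitted(x)
  x$classes
}

#' One-row summary of a fitted classifier
#'
#' @param x A fitted `microwear_nb` model.
#' @param ... Unused.
#' @return A one-row tibble with `n_train`, `n_classes`,
#'   `expected_total_error` and `ac_overlap` (see [expected_total_error()]).
#' @method glance microwear_nb
#' @export
glance.microwear_nb <- function(x, ...) {
  check_fitted(x)
  e <- expected_total_error(x)
  tibble(
    n_train = x$n_train, n_classes = nrow(x$classes),
    expected_total_error = e$total, ac_overlap = e$ac_overlap
  )
}

#' Plot the classified SD-CV plane
#'
#' Draws the uncertainty heat map, the A-B and B-C decision boundaries, the
#' probability isolines of the total mixture, and (optionally) labelled
#' sample points.
#'
#' @param object A fitted `microwear_nb` model.
#' @param points Optional data frame with columns `sd`, `cv` and (if present,
#'   used for labels) `sample_id`.
#' @param masses Isoline probability masses.
#' @param xlim,ylim Plot limits; default to the reference-sample envelope.
#' @param ... Unused.
#' @return A ggplot object (SD on x, CV on y).
#' @examples
#' \donttest{
#' fit <- fit_microwear_classifier(simulate_training_points(seed = 1))
#' autoplot(fit, points = reference_samples("fossil"))
#' }
#' @method autoplot microwear_nb
#' @export
autoplot.microwear_nb <- function(object, points = NULL,
                                  masses = c(0.68, 0.95, 0.995),
                                  xlim = c(0, 8), ylim = c(0, 0.45), ...) {
  check_fitted(object)
  em <- error_map(object)
  bounds <- dplyr::bind_rows(
    dplyr::mutate(boundary_curve(object, c("A", "B")), pair = "A-B"),
    dplyr::mutate(boundary_curve(object, c("B", "C")), pair = "B-C")
  )
  iso <- isolines(object, masses)
  iso$mass_lab <- sprintf("%g%%", 100 * iso$mass)
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(
      data = em,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$error_prob)
    ) +
    ggplot2::scale_fill_viridis_c(
      name = "P(misclassified)", limits = c(0, 2 / 3), option = "inferno"
    ) +
    ggplot2::geom_path(
      data = bounds,
      ggplot2::aes(
        x = .data$x, y = .data$y,
        group = interaction(.data$pair, .data$segment)
      ),
      colour = "white", linewidth = 0.7
    ) +
    ggplot2::geom_path(
      data = iso,
      ggplot2::aes(
        x = .data$x, y = .data$y, linetype = .data$mass_lab,
        group = interaction(.data$mass, .data$segment)
      ),
      colour = "grey80"
    ) +
    ggplot2::scale_linetype_discrete(name = "isoline mass") +
    ggplot2::labs(
      x = "SD of scratch density (per 0.16 mm²)",
      y = "CV of scratch density"
    ) +
    ggplot2::coord_cartesian(xlim = xlim, ylim = ylim, expand = FALSE) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    points <- as_tibble(points)
    p <- p + ggplot2::geom_point(
      data = points,
      ggplot2::aes(x = .data$sd, y = .data$cv),
      colour = "white", shape = 21, fill = "skyblue", size = 2
    )
    if ("sample_id" %in% names(points)) {
      p <- p + ggplot2::geom_text(
        data = points,
        ggplot2::aes(x = .data$sd, y = .data$cv, label = .data$sample_id),
        colour = "white", nudge_y = 0.012, size = 3
      )
    }
  }
  p
}

#' Serialise a fitted classifier to JSON
#'
#' Writes all class-Gaussian parameters, priors and the resolved grid so that
#' maps and classifications regenerate deterministically from the file.
#'
#' @param model A fitted `microwear_nb` model.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @seealso [read_classifier()]
#' @export
write_classifier <- function(model, path) {
  check_fitted(model)
  jsonlite::write_json(
    list(
      format = "mortwear_classifier", version = 1L,
      n_train = model$n_train,
      classes = model$classes,
      grid = unclass(model$grid)
    ),
    path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a serialised classifier from JSON
#'
#' @param path Path written by [write_classifier()].
#' @return A fitted `microwear_nb` model.
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mortwear_classifier")) {
    abort(sprintf("'%s' is not a mortwear classifier file.", path))
  }
  structure(
    list(
      classes = as_tibble(obj$classes),
      grid = grid_spec(obj$grid$xlim, obj$grid$ylim, obj$grid$nx, obj$grid$ny),
      n_train = obj$n_train
    ),
    class = "microwear_nb"
  )
}
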