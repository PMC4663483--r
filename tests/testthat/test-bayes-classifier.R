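# Reference fit used across several blocks (default calibrated training).
fit_default <- fit_microwear_classifier(simulate_training_points(seed = 1))

test_that("per-class parameters are the sample mean/SD of each coordinate", {
  pts <- dplyr::bind_rows(
    tibble::tibble(sd = c(1, 3), cv = c(0.1, 0.3), label = "A"),
    tibble::tibble(sd = c(4, 5), cv = c(0.2, 0.25), label = "B"),
    tibble::tibble(sd = c(6, 7), cv = c(0.35, 0.4), label = "C")
  )
  fit <- fit_microwear_classifier(pts)
  a <- fit$classes[fit$classes$label == "A", ]
  expect_equal(a$mu_x, 2)
  expect_equal(a$sigma_x, sqrt(2))
  expect_equal(a$mu_y, 0.2)
  expect_equal(fit$classes$prior, rep(1 / 3, 3))
})

test_that("degenerate training inputs are rejected with informative errors", {
  pts <- separable_points()
  expect_error(fit_microwear_classifier(pts[pts$label != "C", ]), "missing: C")
  expect_error(
    fit_microwear_classifier(dplyr::bind_rows(
      pts[pts$label != "A", ], pts[pts$label == "A", ][1, ]
    )),
    ">= 2 training points"
  )
  flat <- pts
  flat$cv[flat$label == "A"] <- 0.1
  expect_error(fit_microwear_classifier(flat), "zero within-class variance")
})

test_that("fit recovers known class Gaussians within three standard errors", {
  pars <- list(
    A = list(mu_x = 2, sigma_x = 0.6, mu_y = 0.12, sigma_y = 0.03),
    B = list(mu_x = 4, sigma_x = 0.7, mu_y = 0.27, sigma_y = 0.05),
    C = list(mu_x = 5.5, sigma_x = 0.9, mu_y = 0.33, sigma_y = 0.08)
  )
  n <- 500L
  fit <- fit_microwear_classifier(draw_labelled_points(n, pars, seed = 21))
  for (l in names(pars)) {
    k <- fit$classes[fit$classes$label == l, ]
    p <- pars[[l]]
    expect_lt(abs(k$mu_x - p$mu_x), 3 * p$sigma_x / sqrt(n))
    expect_lt(abs(k$mu_y - p$mu_y), 3 * p$sigma_y / sqrt(n))
    expect_lt(abs(k$sigma_x - p$sigma_x), 3 * p$sigma_x / sqrt(2 * (n - 1)))
    expect_lt(abs(k$sigma_y - p$sigma_y), 3 * p$sigma_y / sqrt(2 * (n - 1)))
  }
})

test_that("fit matches an independent naive-Bayes implementation", {
  skip_if_not_installed("e1071")
  pts <- draw_labelled_points(60, list(
    A = list(mu_x = 2, sigma_x = 0.6, mu_y = 0.12, sigma_y = 0.03),
    B = list(mu_x = 4, sigma_x = 0.7, mu_y = 0.27, sigma_y = 0.05),
    C = list(mu_x = 5.5, sigma_x = 0.9, mu_y = 0.33, sigma_y = 0.08)
  ), seed = 33)
  fit <- fit_microwear_classifier(pts)
  ref <- e1071::naiveBayes(
    factor(label) ~ sd + cv,
    data = as.data.frame(pts[, c("sd", "cv", "label")])
  )
  expect_equal(unname(fit$classes$mu_x), unname(ref$tables$sd[, 1]))
  expect_equal(unname(fit$classes$sigma_x), unname(ref$tables$sd[, 2]))
  expect_equal(unname(fit$classes$mu_y), unname(ref$tables$cv[, 1]))
  expect_equal(unname(fit$classes$sigma_y), unname(ref$tables$cv[, 2]))
  # identical hard labels on a query grid (equal class sizes -> equal priors)
  q <- tidyr::expand_grid(sd = seq(0.5, 7.5, by = 0.5),
    cv = seq(0.05, 0.45, by = 0.05))
  ours <- classify_samples(fit, q, isoline_masses = NULL)$region
  theirs <- as.character(predict(ref, newdata = as.data.frame(q)))
  expect_equal(ours, theirs)
})

test_that("class densities equal the weighted product of the axis normals", {
  fit <- fit_default
  # brute-force oracle written out from the Gaussian formula
  oracle <- function(k, x, y) {
    nx <- exp(-(x - k$mu_x)^2 / (2 * k$sigma_x^2)) / (k$sigma_x * sqrt(2 * pi))
    ny <- exp(-(y - k$mu_y)^2 / (2 * k$sigma_y^2)) / (k$sigma_y * sqrt(2 * pi))
    k$prior * nx * ny
  }
  withr::with_seed(5, {
    x <- stats::runif(20, 0, 8)
    y <- stats::runif(20, 0, 0.45)
  })
  for (l in c("A", "B", "C")) {
    k <- fit$classes[fit$classes$label == l, ]
    expect_equal(class_density(fit, l, x, y), oracle(k, x, y),
      tolerance = 1e-10)
  }
  # mode value and tail decay
  a <- fit$classes[fit$classes$label == "A", ]
  expect_equal(
    class_density(fit, "A", a$mu_x, a$mu_y),
    a$prior / (2 * pi * a$sigma_x * a$sigma_y)
  )
  expect_lt(class_density(fit, "A", 1e4, a$mu_y), 1e-300)
  expect_equal(
    mixture_density(fit, x, y),
    class_density(fit, "A", x, y) + class_density(fit, "B", x, y) +
      class_density(fit, "C", x, y)
  )
})

test_that("each weighted class density integrates to its prior on the grid", {
  dg <- mortwear:::density_grids(fit_default)
  for (l in c("A", "B", "C")) {
    mass <- sum(dg$dens[[l]]) * dg$axes$cell
    expect_equal(mass, 1 / 3, tolerance = 1e-6)
  }
})

test_that("posteriors are a valid distribution and regions partition the grid", {
  fit <- fit_default
  withr::with_seed(8, {
    q <- tibble::tibble(sd = stats::runif(200, 0, 8),
      cv = stats::runif(200, 0, 0.45))
  })
  res <- classify_samples(fit, q, isoline_masses = NULL)
  post <- as.matrix(res[, c("posterior_A", "posterior_B", "posterior_C")])
  expect_true(all(post >= 0))
  expect_equal(rowSums(post), rep(1, 200))
  expect_equal(res$error_prob, 1 - apply(post, 1, max))
  expect_true(all(res$error_prob >= 0 & res$error_prob <= 2 / 3))
  # every grid node belongs to exactly one region
  em <- error_map(fit)
  expect_equal(nrow(em), fit$grid$nx * fit$grid$ny)
  expect_true(all(em$region %in% c("A", "B", "C")))
  expect_true(all(c("A", "B", "C") %in% em$region))
  # scaling all priors by a common factor leaves assignments unchanged
  fit2 <- fit_microwear_classifier(
    simulate_training_points(seed = 1),
    priors = c(A = 5, B = 5, C = 5)
  )
  res2 <- classify_samples(fit2, q, isoline_masses = NULL)
  expect_equal(res2$region, res$region)
  expect_equal(res2$posterior_A, res$posterior_A)
  expect_error(classify_samples(fit, tibble::tibble(sd = NA_real_, cv = 0.1)),
    "non-finite")
})

test_that("equal-variance classes meet at the perpendicular bisector", {
  fit <- fit_microwear_classifier(separable_points())
  b <- boundary_curve(fit, c("A", "B"))
  expect_gt(nrow(b), 10)
  # identical sigmas and priors: the A-B boundary is the vertical line x = 2
  expect_true(all(abs(b$x - 2) < diff(fit$grid$xlim) / fit$grid$nx))
  # on-boundary point splits its posterior equally
  res <- classify_samples(fit, tibble::tibble(sd = 2, cv = 0.1),
    isoline_masses = NULL)
  expect_equal(res$posterior_A, res$posterior_B)
  expect_equal(res$error_prob, res$posterior_B, tolerance = 1e-6)
  # an exact density tie (coincident classes) resolves in the order A < B < C
  same <- tibble::tibble(sd = c(2.9, 3.1, 3.0), cv = c(0.19, 0.21, 0.2))
  coincident <- fit_microwear_classifier(dplyr::bind_rows(
    dplyr::mutate(same, label = "A"),
    dplyr::mutate(same, label = "B"),
    dplyr::mutate(same, sd = sd + 10, cv = cv + 0.2, label = "C")
  ))
  tie <- classify_samples(coincident, tibble::tibble(sd = 3, cv = 0.2),
    isoline_masses = NULL)
  expect_equal(tie$posterior_A, tie$posterior_B)
  expect_equal(tie$region, "A")
})

test_that("boundary vertices satisfy the equal-density condition", {
  fit <- fit_default
  for (pair in list(c("A", "B"), c("B", "C"))) {
    b <- boundary_curve(fit, pair)
    expect_gt(nrow(b), 0)
    d1 <- class_density(fit, pair[1], b$x, b$y)
    d2 <- class_density(fit, pair[2], b$x, b$y)
    expect_lt(max(abs(log(d1) - log(d2))), 0.02)
  }
  expect_warning(boundary_curve(fit, c("A", "C")), "not used")
  expect_error(boundary_curve(fit, c("A", "A")), "distinct")
})

test_that("the uncertainty map is low far from boundaries and 1/2 on them", {
  fit <- fit_microwear_classifier(separable_points())
  at <- function(x, y) {
    classify_samples(fit, tibble::tibble(sd = x, cv = y),
      isoline_masses = NULL)$error_prob
  }
  expect_lt(at(1, 0.1), 0.01) # at the A mode
  expect_equal(at(2, 0.1), 0.5, tolerance = 1e-6) # on the A-B boundary, C remote
  # map maxima hug the boundaries
  em <- error_map(fit_default)
  hot <- em[em$error_prob > 0.49, ]
  bounds <- dplyr::bind_rows(
    boundary_curve(fit_default, c("A", "B")),
    boundary_curve(fit_default, c("B", "C")),
    suppressWarnings(boundary_curve(fit_default, c("A", "C")))
  )
  cell <- sqrt((diff(fit_default$grid$xlim) / fit_default$grid$nx)^2 +
    (diff(fit_default$grid$ylim) / fit_default$grid$ny)^2)
  maxdist <- max(vapply(seq_len(nrow(hot)), function(i) {
    min(sqrt((hot$x[i] - bounds$x)^2 + (hot$y[i] - bounds$y)^2))
  }, numeric(1)))
  expect_lt(maxdist, 2 * cell)
  # margin variant is bounded by [0, 1] and also peaks at the boundary
  emm <- error_map(fit_default, measure = "margin")
  expect_true(all(emm$error_prob >= 0 & emm$error_prob <= 1))
})

test_that("isoline levels are nested and enclose their stated mass", {
  fit <- fit_default
  lv <- isoline_levels(fit, c(0.68, 0.95, 0.995))
  expect_true(all(diff(lv$level) < 0)) # ascending mass, descending level
  expect_equal(lv$enclosed_mass, lv$mass, tolerance = 1e-4)
  iso <- isolines(fit, c(0.68, 0.95))
  expect_true(all(c(0.68, 0.95) %in% iso$mass))
  # Monte-Carlo oracle: draw from the mixture with plain rnorm and count
  cls <- fit$classes
  withr::with_seed(99, {
    k <- sample(3, 2e5, replace = TRUE, prob = cls$prior)
    x <- stats::rnorm(2e5, cls$mu_x[k], cls$sigma_x[k])
    y <- stats::rnorm(2e5, cls$mu_y[k], cls$sigma_y[k])
  })
  g <- mixture_density(fit, x, y)
  for (i in seq_len(nrow(lv))) {
    expect_equal(mean(g >= lv$level[i]), lv$mass[i], tolerance = 0.01)
  }
  expect_error(isoline_levels(fit, 1.2), "in \\(0, 1\\)")
  # a grid too small to hold the mass asks for enlargement
  tiny <- fit_microwear_classifier(
    simulate_training_points(seed = 1),
    grid = grid_spec(xlim = c(1, 3), ylim = c(0.1, 0.2))
  )
  expect_error(isoline_levels(tiny, 0.95), "enlarge the grid")
})

test_that("a collapsed mixture behaves as its single Gaussian (mass check)", {
  # three identical classes: the mixture is one bivariate normal, whose
  # m-isoline encloses exactly mass m
  one <- tibble::tibble(
    sd = c(3.4, 3.6, 3.5, 3.5, 3.3, 3.7),
    cv = c(0.2, 0.2, 0.19, 0.21, 0.2, 0.2)
  )
  pts <- dplyr::bind_rows(
    dplyr::mutate(one, label = "A"),
    dplyr::mutate(one, label = "B"),
    dplyr::mutate(one, label = "C")
  )
  fit <- fit_microwear_classifier(pts)
  lv <- isoline_levels(fit, c(0.68, 0.95))
  # closed form for an axis-aligned Gaussian: mass inside the level set of
  # density c is 1 - 2*pi*sigma_x*sigma_y*c
  sx <- fit$classes$sigma_x[1]
  sy <- fit$classes$sigma_y[1]
  expect_equal(1 - 2 * pi * sx * sy * lv$level, lv$mass, tolerance = 1e-3)
})

test_that("expected total error matches its integral identity and limits", {
  fit <- fit_default
  e <- expected_total_error(fit)
  dg <- mortwear:::density_grids(fit)
  gmax <- pmax(
    dg$dens[["A"]],
    pmax(dg$dens[["B"]], dg$dens[["C"]])
  )
  expect_equal(e$total, 1 - sum(gmax) * dg$axes$cell, tolerance = 1e-6)
  expect_true(e$total > 0 && e$total < 1)
  expect_lt(e$ac_overlap, 0.01) # A-C overlap negligible
  # infinitely separated classes: error tends to zero
  e0 <- expected_total_error(fit_microwear_classifier(separable_points()))
  expect_lt(e0$total, 1e-6)
  # two coincident classes with a remote third: half of their 2/3 mass is
  # misassigned -> total error 1/3
  same <- tibble::tibble(sd = c(2.9, 3.1, 3.0, 3.0), cv = c(0.19, 0.21, 0.2, 0.2))
  pts <- dplyr::bind_rows(
    dplyr::mutate(same, label = "A"),
    dplyr::mutate(same, label = "B"),
    dplyr::mutate(same[c(1, 2, 3, 4), ] |>
      dplyr::mutate(sd = sd + 20, cv = cv + 0.5), label = "C")
  )
  e13 <- expected_total_error(fit_microwear_classifier(pts))
  expect_equal(e13$total, 1 / 3, tolerance = 1e-3)
})

test_that("held-out reference samples classify as their known durations", {
  fit <- fit_default
  held <- dplyr::filter(
    reference_samples("extant"),
    .data$sample_id %in% c("2a", "2b", "3a", "3b", "6", "7")
  )
  res <- classify_samples(fit, held)
  expect_equal(res$region[res$sample_id != "3b"], rep("A", 5))
  expect_equal(res$region[res$sample_id == "3b"], "B")
  # the Taubach bison follows a long-term accumulation pattern
  d1 <- classify_samples(fit, tibble::tibble(sd = 4.134, cv = 0.242))
  expect_equal(d1$region, "B")
  # soft geometry check: every reference point sits inside the 99.5% isoline
  # and all fossil samples inside the 95% one
  all_res <- classify_samples(fit, reference_samples())
  expect_true(all(all_res$inside_isoline <= 0.995))
  expect_true(all(all_res$inside_isoline[all_res$source == "fossil"] <= 0.95))
})

test_that("tidy/glance/predict and JSON serialisation round-trip the model", {
  fit <- fit_default
  td <- tidy(fit)
  expect_equal(td$label, c("A", "B", "C"))
  expect_true(all(c("prior", "mu_x", "sigma_x", "mu_y", "sigma_y") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_classes, 3L)
  expect_equal(gl$expected_total_error, expected_total_error(fit)$total)
  f <- tempfile(fileext = ".json")
  write_classifier(fit, f)
  fit2 <- read_classifier(f)
  expect_equal(fit2$classes, fit$classes, tolerance = 1e-12)
  expect_equal(fit2$grid$xlim, fit$grid$xlim)
  q <- reference_samples("fossil")
  expect_equal(
    classify_samples(fit2, q, isoline_masses = NULL),
    classify_samples(fit, q, isoline_masses = NULL)
  )
  expect_equal(nrow(predict(fit)), 11L)
  expect_output(print(fit), "naive-Bayes")
})

test_that("autoplot returns a complete ggplot of the classified plane", {
  p <- autoplot(fit_default, points = reference_samples("fossil"))
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
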