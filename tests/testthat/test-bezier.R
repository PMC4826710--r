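test_that("Bernstein basis has the endpoint, rational-value and range properties", {
  expect_equal(bernstein(0, 6, 0), 1)
  expect_equal(bernstein(6, 6, 1), 1)
  expect_equal(bernstein(0, 6, 1 / 6), 15625 / 46656)
  expect_equal(bernstein(1, 6, 1 / 6), 3125 / 7776)
  expect_error(bernstein(7, 6, 0.5), "out of range")
})

test_that("Bernstein basis is a partition of unity", {
  set.seed(31)
  tt <- c(0, 1, runif(50))
  for (n in c(1, 6, 12)) {
    B <- bernstein_basis(tt, n)
    expect_equal(rowSums(B), rep(1, length(tt)), tolerance = 1e-12)
    expect_true(all(B >= 0))
  }
})

test_that("basis matrix reproduces the uniform-node interpolation matrix", {
  expect_equal(bernstein_basis(c(0, 1), 1), diag(2))
  B <- bernstein_basis((0:6) / 6, 6)
  expect_equal(B[2, 1], (5 / 6)^6)
  expect_equal(B[2, 2], 6 * (1 / 6) * (5 / 6)^5)
  expect_equal(B[1, 1], 1)
  expect_equal(B[7, 7], 1)
  expect_equal(rowSums(B), rep(1, 7))
})

test_that("interpolating fit reproduces the worked-example control points", {
  curve <- fit_control_points(as.matrix(aa_profile()$coords))
  P <- curve$control_points
  expect_equal(signif(P[, 1], 6),
               c(0, -0.574167, 1.51512, -1.55854, 1.27245, 0.8737, 1))
  expect_equal(signif(P[, 2], 5),
               c(0, -0.015433, 0.058287, -0.034215, 0.039687, 0.0072167, 0))
  # interpolation case: zero residual at the nodes
  fitted <- bezier_points(curve, (0:6) / 6)
  expect_lt(max(abs(fitted - as.matrix(aa_profile()$coords))), 1e-10)
})

test_that("least-squares machinery has linear precision and weight invariance", {
  # data on a straight line -> collinear control points
  xx <- seq(0, 1, length.out = 9)
  line <- cbind(xx, 0.3 + 0.2 * xx)
  curve <- fit_control_points(line, degree = 5)
  P <- curve$control_points
  expect_equal(P[, 2], 0.3 + 0.2 * P[, 1], tolerance = 1e-9)

  # identity weights equal no weights
  cw <- fit_control_points(line, degree = 5, weights = rep(1, 9))
  expect_equal(cw$control_points, P, tolerance = 1e-10)

  expect_error(fit_control_points(line[1:3, ], degree = 5), "at least")
})

test_that("curve derivative matches the endpoint identities and finite differences", {
  curve <- fit_control_points(as.matrix(aa_profile()$coords))
  P <- curve$control_points
  n <- curve$degree
  expect_equal(drop(bezier_derivative(curve, 0)), n * (P[2, ] - P[1, ]))
  expect_equal(drop(bezier_derivative(curve, 1)), n * (P[7, ] - P[6, ]))

  h <- 1e-6
  for (t in c(0.17, 0.42, 0.73, 0.91)) {
    fd <- (bezier_points(curve, t + h) - bezier_points(curve, t - h)) / (2 * h)
    expect_equal(drop(bezier_derivative(curve, t)), drop(fd), tolerance = 1e-6)
  }
})

test_that("outline constructions behave as documented on the worked example", {
  prof <- aa_profile()
  expect_warning(simple <- build_outline(prof, "simple7"), "self-intersect")
  expect_true(has_self_intersection(simple))

  ext <- build_outline(prof, "extended13")
  expect_equal(ext$curve$degree, 12)
  # the closed curve interpolates all 13 boundary coordinates
  co <- prof$coords
  nodes <- (0:12) / 12
  pts <- bezier_points(ext$curve, nodes)
  expect_equal(unname(pts[7, 1]), 1, tolerance = 1e-9)
  expect_equal(pts[12, ], c(x = 0.001, y = -0.004), tolerance = 1e-9,
               ignore_attr = TRUE)

  ed <- build_outline(prof, "edited")
  expect_true(ed$clipped)
  expect_false(has_self_intersection(ed))
  # retained arc starts at the posterior tip and is clipped at the vertical
  # line through the first morphometric coordinate
  expect_equal(ed$t_range[1], 0.5)
  expect_equal(unname(ed$cap["x"]), 0.001, tolerance = 1e-9)

  expect_error(build_outline(prof, "nope"))
})

test_that("the edited outline passes through the mirrored interior coordinates", {
  prof <- aa_profile()
  ed <- build_outline(prof, "edited")
  poly <- outline_coords(ed, n = 2048)
  co <- prof$coords[3:6, ]  # posterior four interior coordinates
  for (i in seq_len(nrow(co))) {
    d_lower <- min(sqrt((poly$x - co$l[i])^2 + (poly$y + co$r[i])^2))
    d_upper <- min(sqrt((poly$x - co$l[i])^2 + (poly$y - co$r[i])^2))
    expect_lt(d_lower, 1e-3)
    expect_lt(d_upper, 1e-3)
  }
  # the first coordinate sits in the linearly-capped anterior region and is
  # approximated at the sampling tolerance of the editing step
  d1 <- min(sqrt((poly$x - 0.001)^2 + (poly$y - 0.004)^2))
  expect_lt(d1, 5e-3)
})

test_that("Bezier integral estimates reproduce closed forms and the polygon oracle", {
  # degree-1 flank with constant offset: the cylinder via the line integrals
  r <- 0.05
  est <- bezier_estimates(bezier_curve(rbind(c(0, r), c(1, r))))
  expect_equal(est$v, pi * r^2, tolerance = 1e-10)
  expect_equal(est$a, 2 * r, tolerance = 1e-10)
  expect_equal(est$a_s, 2 * pi * r + 2 * pi * r^2, tolerance = 1e-10)
  expect_equal(est$p, 2 + 4 * r, tolerance = 1e-10)

  # dense polygon oracle agreement on the edited worked-example outline
  prof <- aa_profile()
  ed <- build_outline(prof, "edited")
  est <- bezier_estimates(ed)
  flank <- sample_flank(ed, n = 20000)
  orac <- revolve_oracle(flank$x, flank$y, prof$length_L)
  expect_lt(rel_err(est$p, orac$p), 1e-3)
  expect_lt(rel_err(est$a, orac$a), 1e-3)
  expect_lt(rel_err(est$a_s, orac$a_s), 1e-3)
  expect_lt(rel_err(est$v, orac$v), 1e-3)
})

test_that("quadrature equals the piecewise sums when the curve is a straight segment", {
  # one tapering segment as a degree-1 Bezier flank vs the same 2-point profile
  prof <- make_fixture("frustum", list(r1 = 0.03, r2 = 0.012), length_L = 1)
  est_b <- bezier_estimates(bezier_curve(rbind(c(0, 0.03), c(1, 0.012))))
  est_p <- piecewise_estimates(prof)
  expect_equal(est_b$p, est_p$p, tolerance = 1e-12)
  expect_equal(est_b$a, est_p$a, tolerance = 1e-12)
  expect_equal(est_b$a_s, est_p$a_s, tolerance = 1e-12)
  expect_equal(est_b$v, est_p$v, tolerance = 1e-12)
})

test_that("a constant-radius body yields an edited outline of the expected area", {
  r <- 0.02
  prof <- morphometric_profile(c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1),
                               c(0, r, r, r, r, r, 0), 1e-3)
  ed <- build_outline(prof, "edited")
  poly <- outline_coords(ed, n = 4096)
  shoelace <- abs(sum(poly$x * c(poly$y[-1], poly$y[1]) -
                      poly$y * c(poly$x[-1], poly$x[1]))) / 2
  expect_equal(shoelace, 2 * r, tolerance = 0.15)
  expect_equal(bezier_estimates(ed)$a / prof$length_L^2, shoelace,
               tolerance = 1e-3)
})

test_that("outline export writes SVG and CSV artefacts", {
  prof <- aa_profile()
  ed <- build_outline(prof, "edited")
  svg <- tmpfile("outline.svg")
  outline_svg(ed, svg, y_exaggeration = 10)
  txt <- readLines(svg)
  expect_true(any(grepl("<svg", txt)))
  expect_true(any(grepl("<path", txt)))

  csv <- tmpfile("outline.csv")
  write_outline_csv(ed, csv, n = 64)
  back <- read.csv(csv)
  expect_named(back, c("x", "y"))
  expect_gt(nrow(back), 100)
})
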