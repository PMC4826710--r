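#' Brute-force solid-of-revolution oracle
#'
#' Independent verification path for every estimator: given a densely
#' sampled upper boundary `(x_i, y_i)` with weakly increasing `x` and
#' `y >= 0` (relative units), computes the four size measures by plain
#' composite sums over the sampled polyline - trapezoid for the projected
#' area, polyline arc length (doubled, plus terminal radii) for the
#' perimeter, lateral frustum strips plus terminal discs for the surface,
#' and exact frustum volumes per strip.  The error model of these sums is
#' independent of the package's main code paths, and for a piecewise-linear
#' boundary they are exact.
#'
#' @param x weakly increasing axial samples (fractions of `L`).
#' @param y non-negative radius samples.
#' @param length_L body length in metres for scaling (default 1: relative).
#' @return a [size_estimates()] object (`method = "geometric"`).
#' @examples
#' th <- seq(0, pi, length.out = 1e5)  # unit-diameter sphere
#' revolve_oracle((1 - cos(th)) / 2, sin(th) / 2)$v  # ~ pi/6
#' @export
revolve_oracle <- function(x, y, length_L = 1) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("need matched x and y vectors with at least 2 samples")
  if (any(y < 0)) stop("negative radius sample")
  if (any(diff(x) < 0)) stop("x must be weakly increasing; re-sample the arc first")
  n <- length(x)
  p <- 0; a <- 0; s_lat <- 0; v <- 0
  for (i in seq_len(n - 1L)) {
    dx <- x[i + 1L] - x[i]
    dy <- y[i + 1L] - y[i]
    seg <- sqrt(dx * dx + dy * dy)
    p <- p + seg
    a <- a + (y[i] + y[i + 1L]) / 2 * dx
    s_lat <- s_lat + pi * (y[i] + y[i + 1L]) * seg
    v <- v + pi / 3 * (y[i]^2 + y[i] * y[i + 1L] + y[i + 1L]^2) * dx
  }
  L <- length_L
  size_estimates(p = (2 * p + 2 * (y[1L] + y[n])) * L,
                 a = 2 * a * L^2,
                 a_s = (s_lat + pi * (y[1L]^2 + y[n]^2)) * L^2,
                 v = v * L^3,
                 method = "geometric")
}

#' Sample an outline's upper flank as a monotone polyline
#'
#' Re-expresses an outline as `(x, |y|)` samples ordered by increasing `x`,
#' the form [revolve_oracle()] consumes.  For the edited construction the
#' anterior cap segment is included.
#'
#' @param outline a [build_outline()] result.
#' @param n number of arc samples.
#' @return data frame with columns `x`, `y`.
#' @export
sample_flank <- function(outline, n = 2048L) {
  stopifnot(inherits(outline, "nematode_outline"))
  tr <- outline$t_range
  tt <- seq(tr[1L], tr[2L], length.out = n)
  pts <- bezier_points(outline$curve, tt)
  x <- pts[, 1L]; y <- abs(pts[, 2L])
  if (outline$construction == "edited" && !is.null(outline$cap)) {
    x <- c(x, 0); y <- c(y, 0)  # cap closes to the anterior tip
  }
  o <- order(x)
  data.frame(x = x[o], y = y[o])
}

#' Synthetic profile fixtures
#'
#' Deterministic generator of test profiles with known closed-form measures:
#'
#' * `"cylinder"`: constant radius `r` (params `r`, default 0.01) - volume
#'   `pi r^2 L^3`, end caps included by the estimators.
#' * `"cone"`: radius `r` at the anterior tapering to a point (params `r`).
#' * `"frustum"`: radius `r1` to `r2 <= r1` (params `r1`, `r2`).
#' * `"fusiform"`: blunt anterior, pointed posterior - the three-coordinate
#'   shape with labial diameter `d`, maximum diameter `D` (both percent of
#'   `L`, as conventionally reported) peaking at fraction `lambda` (params
#'   `lambda`, `d`, `D`); the shape whose volume the position-weighted
#'   Tsalolikhin formula reproduces exactly.
#' * `"random_monotone"`: supplemented profile with `n` random interior
#'   coordinates, radii drawn in the slender-body range `(0, 0.05]` of `L`
#'   (params `n`, default 5); fully determined by `seed`.
#'
#' @param shape one of the five shapes above.
#' @param params named list of shape parameters (see above).
#' @param seed integer seed fixing the randomness of `"random_monotone"`;
#'   the caller's RNG state is left untouched.
#' @param length_L body length in metres.
#' @return a [morphometric_profile()].
#' @examples
#' make_fixture("fusiform", list(lambda = 0.64, d = 1.5, D = 3.4))
#' @export
make_fixture <- function(shape = c("cylinder", "cone", "frustum", "fusiform",
                                   "random_monotone"),
                         params = list(), seed = NULL, length_L = 1e-3) {
  shape <- match.arg(shape)
  get_par <- function(name, default = NULL) {
    if (!is.null(params[[name]])) params[[name]]
    else if (!is.null(default)) default
    else stop(sprintf("shape '%s' requires parameter '%s'", shape, name))
  }
  switch(shape,
    cylinder = {
      r <- get_par("r", 0.01)
      morphometric_profile(c(0, 1), c(r, r), length_L, label = "cylinder")
    },
    cone = {
      r <- get_par("r", 0.01)
      morphometric_profile(c(0, 1), c(r, 0), length_L, label = "cone")
    },
    frustum = {
      r1 <- get_par("r1", 0.012); r2 <- get_par("r2", 0.0095)
      if (r2 > r1) stop("'r2' must not exceed 'r1'")
      morphometric_profile(c(0, 1), c(r1, r2), length_L, label = "frustum")
    },
    fusiform = {
      lam <- get_par("lambda", 0.5)
      d <- get_par("d"); D <- get_par("D")
      if (!(lam > 0 && lam < 1)) stop("'lambda' must lie in (0, 1)")
      if (!(d > 0 && d <= D)) stop("need 0 < d <= D (percent of L)")
      morphometric_profile(c(0, lam, 1), c(d / 200, D / 200, 0), length_L,
                           label = "fusiform")
    },
    random_monotone = {
      n <- get_par("n", 5)
      if (!is.null(seed)) {
        rng <- local_rng(seed)
        on.exit(rng())
      }
      repeat {
        l <- sort(stats::runif(n, 0.01, 0.99))
        if (min(diff(l)) > 1e-3) break
      }
      r <- stats::runif(n, 0.002, 0.05)
      morphometric_profile(c(0, l, 1), c(0, r, 0), length_L,
                           label = "random_monotone")
    })
}

# Seed the RNG locally; returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  if (!is.null(seed)) set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
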