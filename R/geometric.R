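#' Measures of a conical frustum
#'
#' The conical frustum is the elementary body segment of the geometric model:
#' a cone truncated parallel to its base, with base radius `r1`, top radius
#' `r2` (`r1 >= r2`) and height `h`.  Returns its volume, total surface area
#' (lateral surface plus both end discs), and the perimeter and area of its
#' 2D projection (the trapezoidal silhouette seen under the microscope,
#' including the two parallel ends of the outline).
#'
#' Setting `r2 = r1` recovers the cylinder and `r2 = 0` the cone.
#'
#' @param r1 base radius (`>= r2`).
#' @param r2 top radius (`>= 0`).  Radii are not reordered: passing
#'   `r2 > r1` is an error, so that the caller stays in control of the
#'   orientation of each segment.
#' @param h height (`> 0`), same units as the radii.
#' @return list with components `v`, `a_s`, `p`, `a`.
#' @examples
#' frustum_measures(1, 1, 2)  # cylinder: v = 2*pi, a_s = 4*pi + 2*pi
#' frustum_measures(1, 0, 3)  # cone: v = pi
#' @export
frustum_measures <- function(r1, r2, h) {
  if (!all(is.finite(c(r1, r2, h)))) stop("arguments must be finite numbers")
  if (r2 < 0) stop("'r2' must be non-negative")
  if (r2 > r1)
    stop("'r2' must not exceed 'r1'; segment orientation is the caller's responsibility")
  if (h <= 0) stop("'h' must be positive")
  slant <- sqrt((r1 - r2)^2 + h^2)
  list(v = pi * h / 3 * (r1^2 + r1 * r2 + r2^2),
       a_s = pi * (r1 + r2) * slant + pi * (r1^2 + r2^2),
       p = 2 * (r1 + r2) + 2 * slant,
       a = (r1 + r2) * h)
}

#' Piecewise conical-frustum size estimates
#'
#' The geometric model: the body is decomposed into the conical frusta
#' defined by consecutive profile coordinates and the four size measures are
#' assembled from the frustum sums.  Writing `(l_i, r_i)` for the relative
#' coordinates,
#' \deqn{p = 2(r_0 + r_n) + 2\sum_i \sqrt{\Delta r_i^2 + \Delta l_i^2},}
#' \deqn{a = \sum_i (r_i + r_{i+1})\,\Delta l_i,}
#' \deqn{a_s = \pi(r_0^2 + r_n^2) + \pi\sum_i (r_i + r_{i+1})
#'   \sqrt{\Delta r_i^2 + \Delta l_i^2},}
#' \deqn{v = \frac{\pi}{3}\sum_i (r_i^2 + r_i r_{i+1} + r_{i+1}^2)\,
#'   \Delta l_i.}
#' The sums count both flanks of the mirror-symmetric silhouette where
#' appropriate, and the terminal terms account for the end caps (they vanish
#' for a supplemented profile, whose terminal radii are zero, and reproduce
#' the cylinder formulas for a constant-radius two-coordinate profile).
#' Interface discs between adjacent frusta cancel identically and are never
#' formed.  Everything is computed in relative units and scaled by `L`,
#' `L^2`, `L^2` and `L^3` on output.
#'
#' @param profile a [morphometric_profile()] with at least 2 coordinates.
#' @return a [size_estimates()] object (`method = "geometric"`).
#' @examples
#' piecewise_estimates(cobb_to_profile(aplectus_antarcticus()))
#' @export
piecewise_estimates <- function(profile) {
  stopifnot(inherits(profile, "morphometric_profile"))
  co <- profile$coords
  n <- nrow(co)
  if (n < 2L) stop("need at least 2 coordinates")
  l <- co$l; r <- co$r
  dl <- diff(l); dr <- diff(r)
  seg <- sqrt(dr^2 + dl^2)
  r0 <- head(r, -1L); r1 <- tail(r, -1L)
  L <- profile$length_L
  size_estimates(
    p = (2 * (r[1L] + r[n]) + 2 * sum(seg)) * L,
    a = sum((r0 + r1) * dl) * L^2,
    a_s = (pi * (r[1L]^2 + r[n]^2) + pi * sum((r0 + r1) * seg)) * L^2,
    v = pi / 3 * sum((r0^2 + r0 * r1 + r1^2) * dl) * L^3,
    method = "geometric")
}

#' Continuous-limit size estimates for a smooth radius function
#'
#' The continuous counterpart of [piecewise_estimates()]: for a piecewise
#' smooth radius function `r(l)` on `[0, 1]` (relative units), computes
#' \deqn{P = 2(r(0) + r(1)) + 2\int_0^1 ds, \quad A = 2\int_0^1 r\,dl,}
#' \deqn{S = \pi(r(0)^2 + r(1)^2) + 2\pi\int_0^1 r\,ds, \quad
#'   V = \pi\int_0^1 r^2\,dl,}
#' where `ds = sqrt(1 + r'(l)^2) dl` is the line element along the boundary,
#' by adaptive quadrature ([stats::integrate()]).
#'
#' @param radius_fn vectorised function mapping `l` in `[0, 1]` to a
#'   non-negative relative radius.
#' @param length_L body length in metres used for scaling (default 1 keeps
#'   relative units).
#' @param quadrature_tol absolute tolerance passed to the quadrature; the
#'   integrands are smooth and cheap, so a tight default is affordable.
#' @param breaks optional interior knots where `radius_fn` has kinks (for a
#'   piecewise-linear interpolant, its nodes); integration is carried out
#'   separately between consecutive knots.
#' @param deriv_fn optional vectorised derivative `r'(l)`; by default a
#'   central finite difference with step `1e-7` is used.
#' @return a [size_estimates()] object (`method = "geometric"`).
#' @examples
#' # unit-length cylinder of relative radius c: A = 2c, V = pi c^2
#' continuous_estimates(function(l) rep(0.01, length(l)))
#' @export
continuous_estimates <- function(radius_fn, length_L = 1,
                                 quadrature_tol = 1e-12, breaks = NULL,
                                 deriv_fn = NULL) {
  probe <- radius_fn(seq(0, 1, length.out = 41L))
  if (any(!is.finite(probe))) stop("'radius_fn' returned non-finite values")
  if (any(probe < -1e-12)) stop("'radius_fn' must be non-negative")
  if (is.null(deriv_fn)) {
    h <- 1e-7
    deriv_fn <- function(l) {
      lo <- pmax(l - h, 0); hi <- pmin(l + h, 1)
      (radius_fn(hi) - radius_fn(lo)) / (hi - lo)
    }
  }
  knots <- sort(unique(c(0, breaks, 1)))
  quad <- function(f) {
    tot <- 0
    for (k in seq_len(length(knots) - 1L)) {
      tot <- tot + stats::integrate(f, knots[k], knots[k + 1L],
                                    abs.tol = quadrature_tol,
                                    rel.tol = quadrature_tol,
                                    subdivisions = 400L)$value
    }
    tot
  }
  ds <- function(l) sqrt(1 + deriv_fn(l)^2)
  r0 <- radius_fn(0); r1 <- radius_fn(1)
  L <- length_L
  size_estimates(
    p = (2 * (r0 + r1) + 2 * quad(ds)) * L,
    a = 2 * quad(radius_fn) * L^2,
    a_s = (pi * (r0^2 + r1^2) + 2 * pi * quad(function(l) radius_fn(l) * ds(l))) * L^2,
    v = pi * quad(function(l) radius_fn(l)^2) * L^3,
    method = "geometric")
}

#' Piecewise-linear interpolant of a profile as a radius function
#'
#' Convenience for comparing the discrete and continuous estimators: returns
#' the linear interpolant `r(l)` of the profile coordinates (constant
#' extrapolation outside the covered span).
#'
#' @param profile a [morphometric_profile()].
#' @return a vectorised function of `l`.
#' @export
profile_interpolant <- function(profile) {
  co <- profile$coords
  function(l) stats::approx(co$l, co$r, xout = l, rule = 2)$y
}
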