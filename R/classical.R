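#' Classical shape parameters
#'
#' The handful of measurements the classical estimators run on: body length
#' `L`, maximum diameter `D`, labial-region (anterior) diameter `d` (all in
#' metres) and the fractional axial position `lambda_pos` of the maximum
#' diameter, used by the weighted Tsalolikhin variant.
#'
#' @param length_L body length in metres.
#' @param D maximum diameter, `0 < D < length_L`.
#' @param d labial (anterior) diameter, `0 < d <= D`.
#' @param lambda_pos fractional position of the maximum diameter in `(0, 1)`;
#'   defaults to the midpoint assumed by the classical formulas.
#' @return an object of class `classical_shape_params`.
#' @seealso [shape_params_from_profile()], [cylinder_estimates()],
#'   [tsalolikhin_volume()], [midlength_error()]
#' @export
classical_shape_params <- function(length_L, D, d, lambda_pos = 0.5) {
  if (!is.numeric(length_L) || length_L <= 0)
    stop("'length_L' must be positive")
  if (!(d > 0 && d <= D && D < length_L))
    stop("need 0 < d <= D < L (all in the same units)")
  if (!(lambda_pos > 0 && lambda_pos < 1))
    stop("'lambda_pos' must lie strictly in (0, 1)")
  structure(list(length_L = length_L, D = D, d = d, lambda_pos = lambda_pos),
            class = "classical_shape_params")
}

#' @export
print.classical_shape_params <- function(x, ...) {
  cat(sprintf("Classical shape parameters: L = %g m, D = %g m, d = %g m, lambda = %g\n",
              x$length_L, x$D, x$d, x$lambda_pos))
  invisible(x)
}

#' Extract classical shape parameters from a profile
#'
#' `D` is twice the largest radius, `d` twice the radius at the
#' anterior-most coordinate with a nonzero radius (the labial region), and
#' `lambda_pos` the axial position of the largest radius.
#'
#' @param profile a [morphometric_profile()] with a nonzero radius at some
#'   position `l < 1`.
#' @return a [classical_shape_params()] object.
#' @export
shape_params_from_profile <- function(profile) {
  stopifnot(inherits(profile, "morphometric_profile"))
  co <- profile$coords
  body <- which(co$l < 1 & co$r > 0)
  if (length(body) == 0L) stop("profile has no nonzero radius ahead of the tail tip")
  i_max <- body[which.max(co$r[body])]
  L <- profile$length_L
  classical_shape_params(L,
                         D = 2 * co$r[i_max] * L,
                         d = 2 * co$r[body[1L]] * L,
                         lambda_pos = max(co$l[i_max], .Machine$double.eps))
}

#' Cylinder model estimates
#'
#' Treats the body as a cylinder of length `L` and diameter `D`:
#' `v = pi L (D/2)^2`, `a_s = pi D L + pi D^2 / 2` (lateral surface plus the
#' two end discs), `p = 2L + 2D` (the rectangular silhouette) and `a = L D`.
#'
#' @param params a [classical_shape_params()] object.
#' @return a [size_estimates()] object (`method = "cylinder"`).
#' @export
cylinder_estimates <- function(params) {
  stopifnot(inherits(params, "classical_shape_params"))
  L <- params$length_L; D <- params$D
  size_estimates(p = 2 * L + 2 * D,
                 a = L * D,
                 a_s = pi * D * L + pi * D^2 / 2,
                 v = pi * L * (D / 2)^2,
                 method = "cylinder")
}

#' Andrassy's corrected cylinder volume
#'
#' The cylinder volume with the classical 4/5 correction factor:
#' `V_A = (4/5) pi L (D/2)^2`.  No perimeter, projected-area or surface-area
#' counterpart exists for this estimator.
#'
#' @param params a [classical_shape_params()] object.
#' @return volume in cubic metres.
#' @export
andrassy_volume <- function(params) {
  stopifnot(inherits(params, "classical_shape_params"))
  0.8 * pi * params$length_L * (params$D / 2)^2
}

#' Tsalolikhin's volume estimate
#'
#' `V_T = (pi L / 24) * ((d^2 + d D + D^2) + D^2)`: the average of the
#' volumes of a cone (diameter `D`, length `L`) and of a conical frustum
#' (length `L`, end diameters `D` and `d`).  Implicit is the assumption that
#' the widest point sits at the body midpoint.
#'
#' @param params a [classical_shape_params()] object.
#' @return volume in cubic metres.
#' @export
tsalolikhin_volume <- function(params) {
  stopifnot(inherits(params, "classical_shape_params"))
  L <- params$length_L; D <- params$D; d <- params$d
  pi * L / 24 * ((d^2 + d * D + D^2) + D^2)
}

#' Full size estimates for the Tsalolikhin composite shape
#'
#' The shape implied by Tsalolikhin's formula is the composite of an anterior
#' frustum (diameter `d` to `D` over the front half) and a posterior cone
#' (`D` down to a point over the rear half).  This builds the corresponding
#' 3-coordinate profile `(0, d/2L)`, `(1/2, D/2L)`, `(1, 0)` and delegates to
#' the piecewise geometric model; the volume equals [tsalolikhin_volume()]
#' exactly, and perimeter, projected area and surface area (including the
#' anterior cap disc) follow from the same frustum formulas.
#'
#' @param params a [classical_shape_params()] object.
#' @return a [size_estimates()] object (`method = "tsalolikhin"`).
#' @export
tsalolikhin_shape_estimates <- function(params) {
  stopifnot(inherits(params, "classical_shape_params"))
  L <- params$length_L
  prof <- morphometric_profile(c(0, 0.5, 1),
                               c(params$d / (2 * L), params$D / (2 * L), 0),
                               L)
  est <- piecewise_estimates(prof)
  size_estimates(est$p, est$a, est$a_s, est$v, method = "tsalolikhin")
}

#' Position-weighted Tsalolikhin volume
#'
#' Variant of Tsalolikhin's formula in which the widest point sits at the
#' fraction `lambda` of the body length instead of the midpoint:
#' `V_Tl = (pi L / 3) * (lambda (d^2 + d D) / 4 + D^2 / 4)`.  At
#' `lambda = 1/2` it reduces to [tsalolikhin_volume()].
#'
#' @param params a [classical_shape_params()] object.
#' @param lambda weighting in `(0, 1)`; defaults to `params$lambda_pos`.
#' @return volume in cubic metres.
#' @export
tsalolikhin_lambda_volume <- function(params, lambda = params$lambda_pos) {
  stopifnot(inherits(params, "classical_shape_params"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 || lambda >= 1)
    stop("'lambda' must lie strictly in (0, 1)")
  L <- params$length_L; D <- params$D; d <- params$d
  pi * L / 3 * (lambda * (d^2 + d * D) / 4 + D^2 / 4)
}

#' Relative volume error of the midlength assumption
#'
#' The relative error committed by assuming the widest point at the body
#' midpoint when it actually sits at fraction `lambda`:
#' \deqn{\varepsilon_T = \frac{V_T - V_{T\lambda}}{V_{T\lambda}} =
#'   \frac{(1 - 2\lambda)/2}{\lambda + D^2 / (d^2 + d D)}.}
#' Dimensionless; negative exactly when `lambda > 1/2` (widest point behind
#' the midpoint, volume underestimated).  Only the ratios of `d` and `D`
#' enter, so the diameters may be given in any common units.
#'
#' @param params a [classical_shape_params()] object.
#' @param lambda weighting in `(0, 1)`; defaults to `params$lambda_pos`.
#' @return dimensionless relative error.
#' @examples
#' # widest point at 0.51 L barely biases the volume:
#' p <- classical_shape_params(1, D = 0.024, d = 0.008, lambda_pos = 0.51)
#' midlength_error(p)
#' @export
midlength_error <- function(params, lambda = params$lambda_pos) {
  stopifnot(inherits(params, "classical_shape_params"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 || lambda >= 1)
    stop("'lambda' must lie strictly in (0, 1)")
  D <- params$D; d <- params$d
  if (d == 0 && D == 0) stop("'d' and 'D' cannot both be zero")
  if (d == 0) return(0)  # degenerate frustum: volume independent of lambda
  0.5 * (1 - 2 * lambda) / (lambda + D^2 / (d^2 + d * D))
}
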