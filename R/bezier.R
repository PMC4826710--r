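#' Bernstein polynomial
#'
#' `B_{i,n}(t) = C(n, i) t^i (1 - t)^(n - i)`, the weight that the `i`-th
#' control point of a degree-`n` Bezier curve receives at parameter `t`.
#'
#' @param i basis index, integer in `0..n`.
#' @param n degree.
#' @param t parameter value(s) in `[0, 1]`.
#' @return numeric vector of weights, one per element of `t`.
#' @examples
#' bernstein(0, 6, 1/6)  # 15625/46656
#' @export
bernstein <- function(i, n, t) {
  if (length(i) != 1L || length(n) != 1L || i != round(i) || n != round(n))
    stop("'i' and 'n' must be single integers")
  if (i < 0 || i > n)
    stop(sprintf("basis index i = %d out of range 0..%d", i, n))
  choose(n, i) * t^i * (1 - t)^(n - i)
}

#' Bernstein basis matrix
#'
#' Matrix `B` with entry `(j, i) = B_{i,n}(t_j)` for the given parameter
#' nodes; the design matrix of the least-squares control-point fit.  Rows sum
#' to one (partition of unity).
#'
#' @param nodes parameter values in `[0, 1]`.
#' @param degree polynomial degree `n`.
#' @return `length(nodes) x (degree + 1)` matrix.
#' @export
bernstein_basis <- function(nodes, degree) {
  if (any(nodes < 0 | nodes > 1)) stop("nodes must lie in [0, 1]")
  outer(nodes, 0:degree, function(t, i) choose(degree, i) * t^i * (1 - t)^(degree - i))
}

#' Bezier curve from control points
#'
#' @param control_points numeric matrix (or data frame) with two columns
#'   `(x, y)` and at least two rows; the degree is the row count minus one.
#' @return an object of class `bezier_curve`.
#' @export
bezier_curve <- function(control_points) {
  P <- as.matrix(control_points)
  if (ncol(P) != 2L || nrow(P) < 2L)
    stop("control points must be an m x 2 matrix with m >= 2")
  if (any(!is.finite(P))) stop("control points must be finite")
  colnames(P) <- c("x", "y")
  structure(list(control_points = P, degree = nrow(P) - 1L),
            class = "bezier_curve")
}

#' @export
print.bezier_curve <- function(x, ...) {
  cat(sprintf("Bezier curve of degree %d (%d control points)\n",
              x$degree, nrow(x$control_points)))
  print(x$control_points)
  invisible(x)
}

#' Evaluate a Bezier curve
#'
#' @param curve a [bezier_curve()].
#' @param t parameter values in `[0, 1]`.
#' @return `length(t) x 2` matrix of `(x, y)` points.
#' @export
bezier_points <- function(curve, t) {
  stopifnot(inherits(curve, "bezier_curve"))
  bernstein_basis(t, curve$degree) %*% curve$control_points
}

#' Derivative of a Bezier curve
#'
#' `C'(t) = n * sum_i (P_{i+1} - P_i) B_{i,n-1}(t)`, the standard hodograph
#' form of the Bernstein derivative (out-of-range basis terms are zero).  At
#' the endpoints this reduces to `n (P_1 - P_0)` and `n (P_n - P_{n-1})`.
#'
#' @param curve a [bezier_curve()].
#' @param t parameter values in `[0, 1]`.
#' @return `length(t) x 2` matrix of `(dx/dt, dy/dt)`.
#' @export
bezier_derivative <- function(curve, t) {
  stopifnot(inherits(curve, "bezier_curve"))
  P <- curve$control_points
  n <- curve$degree
  dP <- P[-1L, , drop = FALSE] - P[-nrow(P), , drop = FALSE]
  n * (bernstein_basis(t, n - 1L) %*% dP)
}

#' Least-squares Bezier control points
#'
#' Solves the (optionally weighted) normal equations
#' `P = (B'WB)^{-1} B'WC` for the control points of a degree-`degree` Bezier
#' curve approximating the data `C` at the given parameter nodes.  When the
#' number of data points equals `degree + 1` the basis matrix is square and
#' the fitted curve interpolates the data exactly.
#'
#' @param data numeric matrix (or data frame) of `(x, y)` coordinates, one
#'   row per data point.
#' @param nodes parameter node for each data point; defaults to uniform
#'   spacing on `[0, 1]`.
#' @param degree curve degree; defaults to `nrow(data) - 1` (interpolation).
#' @param weights optional non-negative weight per data point (the diagonal
#'   of `W`); identity weights reproduce the unweighted fit.
#' @return a [bezier_curve()].
#' @examples
#' prof <- cobb_to_profile(aplectus_antarcticus())
#' fit_control_points(as.data.frame(prof))  # 7-point interpolation
#' @export
fit_control_points <- function(data, nodes = NULL, degree = NULL,
                               weights = NULL) {
  C <- as.matrix(data)
  if (ncol(C) != 2L) stop("'data' must have two columns (x, y)")
  m <- nrow(C)
  if (is.null(degree)) degree <- m - 1L
  if (m < degree + 1L)
    stop("need at least degree + 1 data points")
  if (is.null(nodes)) nodes <- seq(0, 1, length.out = m)
  if (length(nodes) != m) stop("one parameter node per data point required")
  B <- bernstein_basis(nodes, degree)
  if (m == degree + 1L) {
    # square system: interpolate directly rather than through the normal
    # equations, whose conditioning is the square of that of B
    if (rcond(B) < .Machine$double.eps * 1e2)
      stop("basis matrix is numerically singular; choose different nodes or a lower degree")
    P <- solve(B, C)
    return(bezier_curve(P))
  }
  if (is.null(weights)) {
    BtB <- crossprod(B)
    rhs <- crossprod(B, C)
  } else {
    if (length(weights) != m || any(weights < 0))
      stop("'weights' must be one non-negative value per data point")
    BtB <- crossprod(B, weights * B)
    rhs <- crossprod(B, weights * C)
  }
  if (rcond(BtB) < .Machine$double.eps * 1e2)
    stop("normal matrix is numerically singular; choose different nodes or a lower degree")
  bezier_curve(solve(BtB, rhs))
}
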