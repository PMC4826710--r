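#' Size estimates from a Bezier outline
#'
#' Evaluates the solid-of-revolution line integrals along the parametric
#' boundary `C(t) = (x(t), y(t))`,
#' \deqn{P = 2\int \sqrt{x'^2 + y'^2}\,dt,\quad A = 2\int y\,x'\,dt,}
#' \deqn{S = 2\pi\int |y| \sqrt{x'^2 + y'^2}\,dt,\quad
#'   V = \pi\int y^2 x'\,dt,}
#' over the retained parameter range of the outline, by fixed high-order
#' Gauss-Legendre quadrature (64 nodes, doubled until two successive
#' estimates agree to `quadrature_tol` relative).  The integrals are signed
#' by the traversal direction; orientation is checked and absolute values
#' are taken so that all outputs are positive.  For constructions whose
#' curve covers both flanks (`"extended13"`) the flank factors are halved
#' accordingly.  For the `"edited"` construction the straight anterior cap
#' contributes its exact segment length, triangle area, cone lateral surface
#' and cone volume.  Outputs are scaled by `L`, `L^2`, `L^2`, `L^3`.
#'
#' @param outline a [build_outline()] result, or a bare [bezier_curve()]
#'   interpreted as a single upper-boundary flank on `t` in `[0, 1]` with
#'   terminal end caps (so a constant-offset degree-1 curve reproduces the
#'   cylinder formulas).
#' @param quadrature_tol relative convergence tolerance for the doubling
#'   Gauss-Legendre scheme.
#' @return a [size_estimates()] object (`method = "bezier"`).
#' @examples
#' prof <- cobb_to_profile(aplectus_antarcticus())
#' bezier_estimates(build_outline(prof, "edited"))
#' @export
bezier_estimates <- function(outline, quadrature_tol = 1e-10) {
  if (inherits(outline, "bezier_curve")) {
    return(flank_estimates(outline, c(0, 1), length_L = 1,
                           end_caps = TRUE, tol = quadrature_tol))
  }
  stopifnot(inherits(outline, "nematode_outline"))
  L <- outline$profile$length_L
  tr <- outline$t_range
  curve <- outline$curve
  raw <- arc_integrals(curve, tr[1L], tr[2L], quadrature_tol)

  if (outline$construction == "extended13") {
    # closed curve covers both flanks: halve the flank-doubling factors
    p <- raw$arc
    a <- abs(raw$A)
    a_s <- pi * raw$Sy
    v <- pi * abs(raw$V) / 2
  } else {
    p <- 2 * raw$arc
    a <- 2 * abs(raw$A)
    a_s <- 2 * pi * raw$Sy
    v <- pi * abs(raw$V)
  }

  if (outline$construction == "edited" && !is.null(outline$cap)) {
    cx <- outline$cap[["x"]]; cy <- outline$cap[["y"]]
    slant <- sqrt(cx^2 + cy^2)
    p <- p + 2 * slant           # both cap segments
    a <- a + cx * cy             # two mirrored triangles
    a_s <- a_s + pi * cy * slant # anterior cone, apex at the tip
    v <- v + pi / 3 * cy^2 * cx
  }
  size_estimates(p * L, a * L^2, a_s * L^2, v * L^3, method = "bezier")
}

# Gauss-Legendre with node doubling; returns the four raw signed integrals.
arc_integrals <- function(curve, t0, t1, tol) {
  prev <- NULL
  for (nn in c(64L, 128L, 256L, 512L, 1024L, 2048L)) {
    gl <- pracma::gaussLegendre(nn, t0, t1)
    pt <- bezier_points(curve, gl$x)
    dpt <- bezier_derivative(curve, gl$x)
    y <- pt[, 2L]; xp <- dpt[, 1L]
    ds <- sqrt(dpt[, 1L]^2 + dpt[, 2L]^2)
    cur <- c(arc = sum(gl$w * ds),
             A = sum(gl$w * y * xp),
             Sy = sum(gl$w * abs(y) * ds),
             V = sum(gl$w * y^2 * xp))
    if (!is.null(prev)) {
      denom <- pmax(abs(cur), .Machine$double.eps)
      if (max(abs(cur - prev) / denom) < tol) {
        check_orientation(xp, gl$w)
        return(as.list(cur))
      }
    }
    prev <- cur
  }
  stop(sprintf("quadrature did not converge to %g on t in [%g, %g] (last change %.3g); the curve may be degenerate",
               tol, t0, t1, max(abs(cur - prev))))
}

check_orientation <- function(xp, w, frac = 0.05) {
  # a healthy retained arc traverses x monotonically; a large opposing
  # component signals that loops remain inside the integration range
  pos <- sum(w * pmax(xp, 0)); neg <- -sum(w * pmin(xp, 0))
  if (min(pos, neg) > frac * max(pos, neg))
    warning("boundary traversal reverses direction substantially; signed integrals may partially cancel")
  invisible(NULL)
}

# One explicit flank with terminal end caps (cylinder-style closure).
flank_estimates <- function(curve, tr, length_L, end_caps, tol) {
  raw <- arc_integrals(curve, tr[1L], tr[2L], tol)
  y0 <- abs(unname(bezier_points(curve, tr[1L])[, 2L]))
  y1 <- abs(unname(bezier_points(curve, tr[2L])[, 2L]))
  p <- 2 * raw$arc
  a <- 2 * abs(raw$A)
  a_s <- 2 * pi * raw$Sy
  v <- pi * abs(raw$V)
  if (end_caps) {
    p <- p + 2 * (y0 + y1)
    a_s <- a_s + pi * (y0^2 + y1^2)
  }
  L <- length_L
  size_estimates(p * L, a * L^2, a_s * L^2, v * L^3, method = "bezier")
}
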