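#' Bezier outline models of the nematode silhouette
#'
#' Builds one of three Bezier representations of the body outline from a
#' supplemented coordinate profile:
#'
#' * `"simple7"` - a single curve interpolating the `(l, r)` coordinates of
#'   the upper boundary at uniform nodes, mirrored about the body axis.  With
#'   seven coordinates this is the classic degree-6 construction; it develops
#'   a pair of anterior loops (the Runge phenomenon of high-degree polynomial
#'   interpolation), which is reported as a warning.
#' * `"extended13"` - a closed curve through the coordinates of *both*
#'   flanks, ordered clockwise: anterior tip, upper coordinates front to
#'   back, posterior tip, mirrored lower coordinates back to front, and the
#'   anterior tip again (13 points for a 7-coordinate profile, degree 12,
#'   uniform nodes).  Reasonable at the posterior; Runge oscillation is
#'   amplified at the anterior where the parameter interval begins and ends.
#' * `"edited"` - the extended curve with the ill-behaved anterior portion
#'   edited out: only the lower-boundary arc from the posterior tip towards
#'   the first morphometric coordinate is retained, reflected about the axis
#'   to give the upper boundary, and the anterior is closed by straight
#'   segments from the tip.  Because the anterior Runge loop of the extended
#'   curve starts *before* the parameter node of the first coordinate, the
#'   retained arc is clipped at the first parameter where the curve crosses
#'   the vertical line through that coordinate; without the clip the outline
#'   would cross its own anterior cap and fail to be a simple closed curve.
#'
#' @param profile a supplemented [morphometric_profile()] with at least 3
#'   coordinates (terminal radii zero).
#' @param construction one of `"edited"`, `"simple7"`, `"extended13"`.
#' @return an object of class `nematode_outline`: list with the underlying
#'   [bezier_curve()], the retained parameter range `t_range`, the anterior
#'   cap vertex (for `"edited"`), flags, and the source profile.
#' @seealso [bezier_estimates()], [outline_coords()], [outline_svg()]
#' @export
build_outline <- function(profile,
                          construction = c("edited", "simple7", "extended13")) {
  stopifnot(inherits(profile, "morphometric_profile"))
  construction <- match.arg(construction)
  if (!is_supplemented(profile))
    stop("outline construction requires a supplemented profile (terminal coordinates (0,0) and (1,0))")
  co <- profile$coords
  k <- nrow(co)
  if (k < 3L) stop("need at least 3 coordinates (one interior)")

  if (construction == "simple7") {
    curve <- fit_control_points(cbind(co$l, co$r))
    out <- new_outline(construction, curve, c(0, 1), cap = NULL,
                       clipped = FALSE, profile = profile)
    if (outline_self_intersects(out))
      warning("simple construction outline self-intersects (anterior Runge loops)")
    return(out)
  }

  # clockwise closed traversal: tip, upper front-to-back, tail, lower
  # back-to-front, tip again -> 2k - 1 points, degree 2k - 2, uniform nodes
  iu <- 2:(k - 1L)
  X <- c(0, co$l[iu], 1, rev(co$l[iu]), 0)
  Y <- c(0, co$r[iu], 0, -rev(co$r[iu]), 0)
  curve <- fit_control_points(cbind(X, Y))
  m <- length(X) - 1L  # degree

  if (construction == "extended13")
    return(new_outline(construction, curve, c(0, 1), cap = NULL,
                       clipped = FALSE, profile = profile))

  # edited: retain the lower arc from the posterior tip (node (k-1)/m) to the
  # first morphometric coordinate (node (m-1)/m), clipping at the first
  # crossing of x = l_1 if the anterior loop begins earlier
  t_post <- (k - 1L) / m
  t_ant <- (m - 1L) / m
  x_first <- co$l[2L]
  tt <- seq(t_post, t_ant, length.out = 2049L)
  xx <- bezier_points(curve, tt)[, 1L]
  below <- which(xx < x_first)
  clipped <- FALSE
  t_end <- t_ant
  if (length(below) > 0L && below[1L] > 1L) {
    j <- below[1L]
    t_end <- stats::uniroot(function(t) bezier_points(curve, t)[, 1L] - x_first,
                            c(tt[j - 1L], tt[j]), tol = 1e-14)$root
    clipped <- t_end < t_ant - 1e-12
  }
  end_pt <- drop(bezier_points(curve, t_end))
  cap <- c(x = unname(end_pt[1L]), y = abs(unname(end_pt[2L])))
  new_outline("edited", curve, c(t_post, t_end), cap = cap,
              clipped = clipped, profile = profile)
}

new_outline <- function(construction, curve, t_range, cap, clipped, profile) {
  structure(list(construction = construction, curve = curve,
                 t_range = t_range, cap = cap, clipped = clipped,
                 profile = profile),
            class = "nematode_outline")
}

#' @export
print.nematode_outline <- function(x, ...) {
  cat(sprintf("Nematode outline (%s construction), degree-%d curve, t in [%.4g, %.4g]%s\n",
              x$construction, x$curve$degree, x$t_range[1L], x$t_range[2L],
              if (isTRUE(x$clipped)) ", anterior loop clipped" else ""))
  invisible(x)
}

#' Sample the closed outline polygon
#'
#' Returns the outline as an ordered closed polygon in relative units
#' (clockwise; first and last vertex coincide), suitable for plotting, SVG
#' export or polygon-based verification.
#'
#' @param outline a [build_outline()] result.
#' @param n number of samples per boundary arc.
#' @return data frame with columns `x` and `y`.
#' @export
outline_coords <- function(outline, n = 256L) {
  stopifnot(inherits(outline, "nematode_outline"))
  tr <- outline$t_range
  tt <- seq(tr[1L], tr[2L], length.out = n)
  pts <- bezier_points(outline$curve, tt)
  switch(outline$construction,
    simple7 = {
      upper <- pts
      lower <- cbind(rev(pts[, 1L]), -rev(pts[, 2L]))
      data.frame(x = c(upper[, 1L], lower[, 1L]),
                 y = c(upper[, 2L], lower[, 2L]))
    },
    extended13 = data.frame(x = pts[, 1L], y = pts[, 2L]),
    edited = {
      # arc runs posterior -> anterior along the lower flank; mirror for the
      # upper flank and close the anterior through the tip
      lower <- pts  # posterior -> anterior, y <= 0
      upper <- cbind(rev(pts[, 1L]), -rev(pts[, 2L]))  # anterior -> posterior
      data.frame(
        x = c(0, upper[, 1L], lower[-1L, 1L], 0),
        y = c(0, upper[, 2L], lower[-1L, 2L], 0))
    })
}

# Segment-pair self-intersection test on the sampled outline polygon.
outline_self_intersects <- function(outline, n = 200L) {
  poly <- outline_coords(outline, n)
  segments_self_intersect(poly$x, poly$y)
}

#' Does the sampled outline self-intersect?
#'
#' Pairwise segment intersection test on the sampled outline polygon
#' (adjacent segments excluded).  Used to flag the anterior loops of the
#' simple construction.
#'
#' @param outline a [build_outline()] result.
#' @param n samples per arc.
#' @return logical.
#' @export
has_self_intersection <- function(outline, n = 200L) {
  outline_self_intersects(outline, n)
}

segments_self_intersect <- function(x, y) {
  n <- length(x) - 1L
  if (n < 3L) return(FALSE)
  x1 <- x[-length(x)]; y1 <- y[-length(y)]
  x2 <- x[-1L]; y2 <- y[-1L]
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    # skip the closing segment's adjacency with the first
    if (i == 1L) j <- j[j != n]
    if (length(j) == 0L) next
    d1 <- cross2(x2[i] - x1[i], y2[i] - y1[i], x1[j] - x1[i], y1[j] - y1[i])
    d2 <- cross2(x2[i] - x1[i], y2[i] - y1[i], x2[j] - x1[i], y2[j] - y1[i])
    d3 <- cross2(x2[j] - x1[j], y2[j] - y1[j], x1[i] - x1[j], y1[i] - y1[j])
    d4 <- cross2(x2[j] - x1[j], y2[j] - y1[j], x2[i] - x1[j], y2[i] - y1[j])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

cross2 <- function(ax, ay, bx, by) ax * by - ay * bx

#' Export an outline as SVG
#'
#' Writes a minimal SVG 1.1 document containing the sampled outline as a
#' closed path.  The vertical axis can be exaggerated (slender nematodes are
#' conventionally drawn with a 10x radial exaggeration).
#'
#' @param outline a [build_outline()] result.
#' @param path output file path.
#' @param y_exaggeration vertical scale factor applied to the radii.
#' @param n samples per arc.
#' @param width SVG pixel width of the body length.
#' @return the path, invisibly.
#' @export
outline_svg <- function(outline, path, y_exaggeration = 1, n = 256L,
                        width = 800) {
  poly <- outline_coords(outline, n)
  xs <- poly$x * width
  ys <- -poly$y * y_exaggeration * width  # SVG y grows downwards
  pad <- 0.05 * width
  ymin <- min(ys); ymax <- max(ys)
  d <- paste0("M ", paste(sprintf("%.3f %.3f", xs, ys - ymin + pad),
                          collapse = " L "), " Z")
  svg <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%.0f" height="%.0f" viewBox="0 0 %.0f %.0f">',
            width + 2 * pad, ymax - ymin + 2 * pad,
            width + 2 * pad, ymax - ymin + 2 * pad),
    sprintf('<path d="%s" fill="none" stroke="black" stroke-width="1" transform="translate(%.3f,0)"/>',
            d, pad),
    '</svg>')
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(svg, con)
  invisible(path)
}

#' Export sampled outline coordinates as CSV
#'
#' @param outline a [build_outline()] result.
#' @param path output file path.
#' @param n samples per arc.
#' @return the path, invisibly.
#' @export
write_outline_csv <- function(outline, path, n = 256L) {
  utils::write.csv(outline_coords(outline, n), path, row.names = FALSE)
  invisible(path)
}
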