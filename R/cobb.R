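#' Cobb's morphometric ratios
#'
#' Cobb's "formula" records, for five standard anatomical landmarks (base of
#' the pharynx or buccal cavity, nerve ring, end of the oesophagus, vulva or
#' mid-body, anus), the axial position `l_i` and the body diameter `d_i`
#' at that position, both expressed as percentages of the total body length
#' `L`.  Note that the `d_i` are *diameters*, not radii.
#'
#' @param length_L total body length in metres.
#' @param l numeric vector of 5 landmark positions, percent of `L`,
#'   strictly increasing, all in `(0, 100)`.
#' @param d numeric vector of 5 diameters at those landmarks, percent of
#'   `L`, all `> 0`.
#' @param label optional specimen name.
#' @return an object of class `cobb_ratios`.
#' @seealso [cobb_to_profile()], [deman_indices()], [aplectus_antarcticus()]
#' @export
cobb_ratios <- function(length_L, l, d, label = NULL) {
  if (length(l) != 5L || length(d) != 5L)
    stop("Cobb's ratios consist of exactly 5 positions and 5 diameters")
  if (anyNA(l) || anyNA(d)) stop("missing values in Cobb's ratios")
  if (any(l <= 0) || any(l >= 100))
    stop("landmark positions must lie strictly between 0 and 100 percent")
  dd <- diff(l)
  if (any(dd <= 0)) {
    i <- which(dd <= 0)[1L]
    stop(sprintf("landmark positions must be strictly increasing; l%d (= %g) is out of order",
                 i + 1L, l[i + 1L]))
  }
  if (any(d <= 0)) stop("all diameters must be positive")
  if (!is.numeric(length_L) || length(length_L) != 1L || length_L <= 0)
    stop("'length_L' must be a single positive number (metres)")
  structure(list(length_L = length_L, l = as.numeric(l), d = as.numeric(d),
                 label = label),
            class = "cobb_ratios")
}

#' @export
print.cobb_ratios <- function(x, ...) {
  cat("Cobb's ratios")
  if (!is.null(x$label)) cat(" for ", x$label, sep = "")
  cat(sprintf(" (L = %g m)\n", x$length_L))
  m <- rbind(`l (%)` = x$l, `d (%)` = x$d)
  colnames(m) <- paste0("#", 1:5)
  print(m)
  invisible(x)
}

#' Build a coordinate profile from Cobb's ratios
#'
#' Converts the five (position, diameter) percentage pairs of Cobb's notation
#' into the canonical relative profile: positions `l_i / 100`, radii
#' `d_i / 200` (half the relative diameter), supplemented with the terminal
#' coordinates `(0, 0)` and `(1, 0)`.  The result is the 7-coordinate profile
#' used by every estimator in the package.
#'
#' @param ratios a [cobb_ratios()] object.
#' @return a supplemented [morphometric_profile()] with 7 coordinates.
#' @examples
#' cobb_to_profile(aplectus_antarcticus())
#' @export
cobb_to_profile <- function(ratios) {
  stopifnot(inherits(ratios, "cobb_ratios"))
  morphometric_profile(ratios$l / 100, ratios$d / 200, ratios$length_L,
                       ratios$label, supplement = TRUE)
}

#' Recover Cobb's ratios from a 7-coordinate profile
#'
#' Inverse of [cobb_to_profile()] on its range: strips the supplementary
#' terminal coordinates and re-expresses the interior coordinates as
#' percentage positions and percentage diameters.
#'
#' @param profile a supplemented 7-coordinate [morphometric_profile()].
#' @return a [cobb_ratios()] object.
#' @export
profile_to_cobb <- function(profile) {
  stopifnot(inherits(profile, "morphometric_profile"))
  if (n_coords(profile) != 7L || !is_supplemented(profile))
    stop("expected a supplemented 7-coordinate profile (terminal coordinates (0,0) and (1,0))")
  co <- profile$coords[2:6, ]
  cobb_ratios(profile$length_L, co$l * 100, co$r * 200, profile$label)
}

#' de Man indices
#'
#' The classical nematode shape indices: `a` = length / greatest diameter,
#' `b` = length / oesophagus length, `c` = length / tail length and
#' `c_prime` = tail length / body radius at the anus.
#'
#' @param length_L total body length in metres.
#' @param a,b,c ratios, all `> 1`.
#' @param c_prime tail length over anal radius, `> 0`.
#' @param label optional specimen name.
#' @return an object of class `deman_indices`.
#' @export
deman_indices <- function(length_L, a, b, c, c_prime, label = NULL) {
  vals <- c(a = a, b = b, c = c, c_prime = c_prime)
  if (anyNA(vals) || any(vals <= 0))
    stop("all de Man indices must be positive")
  if (a <= 1 || b <= 1 || c <= 1)
    stop("'a', 'b' and 'c' are length ratios and must exceed 1")
  if (!is.numeric(length_L) || length(length_L) != 1L || length_L <= 0)
    stop("'length_L' must be a single positive number (metres)")
  structure(list(length_L = length_L, a = a, b = b, c = c, c_prime = c_prime,
                 label = label),
            class = "deman_indices")
}

#' Express de Man indices as (partial) Cobb's ratios
#'
#' Only four of Cobb's ten numbers are recoverable from the de Man indices:
#' the oesophagus end `l3 = 100 / b`, the mid-body diameter `d4 = 200 / a`
#' (taking the greatest diameter to sit at the vulva / mid-body landmark),
#' the anus position `l5 = 100 (1 - 1 / c)` and the anal diameter
#' `d5 = 200 / (c c')`, all in percent of `L`.  The remaining fields are
#' returned as `NA` and flagged in `missing`.
#'
#' @param idx a [deman_indices()] object.
#' @return an object of class `partial_cobb`: list with `length_L`, `l`,
#'   `d` (length-5 vectors with `NA` for unknown entries) and `missing`
#'   (names of the absent fields).
#' @export
deman_to_partial_cobb <- function(idx) {
  stopifnot(inherits(idx, "deman_indices"))
  l <- c(NA, NA, 100 / idx$b, NA, 100 * (1 - 1 / idx$c))
  d <- c(NA, NA, NA, 200 / idx$a, 200 / (idx$c * idx$c_prime))
  miss <- c("l1", "l2", "l4", "d1", "d2", "d3")
  structure(list(length_L = idx$length_L, l = l, d = d, missing = miss,
                 label = idx$label),
            class = "partial_cobb")
}

#' @export
print.partial_cobb <- function(x, ...) {
  cat("Partial Cobb's ratios (percent of L); missing:",
      paste(x$missing, collapse = ", "), "\n")
  m <- rbind(`l (%)` = x$l, `d (%)` = x$d)
  colnames(m) <- paste0("#", 1:5)
  print(m)
  invisible(x)
}

#' Compute de Man indices from Cobb's ratios
#'
#' Uses the same approximate correspondences as [deman_to_partial_cobb()],
#' so the two functions are mutually inverse on the shared fields: the
#' greatest diameter is the largest of the `d_i` (inverted through
#' `d4 = 200 / a`), the oesophagus ends at `l3`, the tail runs from `l5` to
#' the posterior tip and the anal radius is `d5 / 2`.
#'
#' @param ratios a [cobb_ratios()] object.
#' @return a [deman_indices()] object.
#' @export
deman_from_cobb <- function(ratios) {
  stopifnot(inherits(ratios, "cobb_ratios"))
  tail_frac <- 1 - ratios$l[5L] / 100
  deman_indices(ratios$length_L,
                a = 200 / max(ratios$d),
                b = 100 / ratios$l[3L],
                c = 1 / tail_frac,
                c_prime = tail_frac / (ratios$d[5L] / 200),
                label = ratios$label)
}

#' Convert a partial Cobb record to a coordinate profile
#'
#' Drops the unknown landmarks and builds a (necessarily coarser) supplemented
#' profile from whatever coordinates carry both a position and a diameter.
#' With de Man-derived data only the anus coordinate has both, so the
#' estimators degrade towards the coarse classical shapes.
#'
#' @param partial a `partial_cobb` object from [deman_to_partial_cobb()].
#' @return a supplemented [morphometric_profile()].
#' @export
partial_cobb_to_profile <- function(partial) {
  stopifnot(inherits(partial, "partial_cobb"))
  keep <- !is.na(partial$l) & !is.na(partial$d)
  if (!any(keep))
    stop("no landmark has both a position and a diameter")
  morphometric_profile(partial$l[keep] / 100, partial$d[keep] / 200,
                       partial$length_L, partial$label, supplement = TRUE)
}

#' The worked example: Aplectus antarcticus
#'
#' Cobb's published morphometric record for *Aplectus antarcticus*
#' (body length 0.6 mm): landmark positions 0.1, 12.6, 21, 51 and 87 percent
#' of `L`, with diameters 0.8, 2.2, 2.3, 2.4 and 1.9 percent of `L`.  This is
#' the specimen used throughout the package documentation and tests.
#'
#' @return a [cobb_ratios()] object.
#' @examples
#' piecewise_estimates(cobb_to_profile(aplectus_antarcticus()))
#' @export
aplectus_antarcticus <- function() {
  cobb_ratios(length_L = 0.6e-3,
              l = c(0.1, 12.6, 21, 51, 87),
              d = c(0.8, 2.2, 2.3, 2.4, 1.9),
              label = "Aplectus antarcticus")
}
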