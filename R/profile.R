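#' Morphometric profile of a nematode
#'
#' The universal input of all estimators in this package: an ordered set of
#' axial coordinates along the body, each giving the axial position as a
#' fraction of the total body length `L` and the local body radius, also as a
#' fraction of `L`, together with the absolute body length in metres.
#' Positions must be strictly increasing; radii are non-negative and must be
#' positive strictly inside the body (a zero interior radius would pinch the
#' body into two).
#'
#' All computation in the package is carried out in these relative
#' (dimensionless) units and only scaled to metres on output, so that inputs
#' given as percentages, fractions or absolute measurements all reduce to the
#' same canonical form.
#'
#' @param positions numeric vector of axial positions, fractions of `L` in
#'   `[0, 1]`, strictly increasing.
#' @param radii numeric vector of body radii at `positions`, fractions of
#'   `L`, all `>= 0`; radii at strictly interior positions must be `> 0`.
#' @param length_L total body length in metres (`> 0`).
#' @param label optional free-text specimen name.
#' @param supplement if `TRUE`, prepend `(0, 0)` and append `(1, 0)` when the
#'   profile does not already start at 0 and end at 1 (the standard closure
#'   of a morphometric profile: the body tapers to points at both tips).
#' @return an object of class `morphometric_profile` with fields `length_L`,
#'   `coords` (data frame with columns `l`, `r`) and `label`.
#' @seealso [cobb_to_profile()], [supplement_profile()],
#'   [profile_to_absolute()], [piecewise_estimates()]
#' @examples
#' prof <- morphometric_profile(c(0.1, 51, 87) / 100,
#'                              c(0.4, 1.2, 0.95) / 100,
#'                              length_L = 6e-4, supplement = TRUE)
#' prof
#' @export
morphometric_profile <- function(positions, radii, length_L, label = NULL,
                                 supplement = FALSE) {
  if (!is.numeric(positions) || !is.numeric(radii))
    stop("'positions' and 'radii' must be numeric")
  if (length(positions) != length(radii))
    stop("'positions' and 'radii' must have the same length")
  if (anyNA(positions) || anyNA(radii))
    stop("missing values in profile coordinates")
  if (!is.numeric(length_L) || length(length_L) != 1L || !is.finite(length_L) ||
      length_L <= 0)
    stop("'length_L' must be a single positive number (metres)")

  if (supplement) {
    if (length(positions) == 0L || positions[1L] > 0) {
      positions <- c(0, positions)
      radii <- c(0, radii)
    }
    n <- length(positions)
    if (positions[n] < 1) {
      positions <- c(positions, 1)
      radii <- c(radii, 0)
    }
  }

  if (length(positions) < 1L)
    stop("profile needs at least one coordinate")
  if (any(positions < 0) || any(positions > 1))
    stop("axial positions must lie in [0, 1] (fractions of L)")
  d <- diff(positions)
  if (any(d == 0)) {
    i <- which(d == 0)[1L]
    stop(sprintf("duplicate axial position at index %d (l = %g); ties have no meaning for a radius function r(l)",
                 i + 1L, positions[i + 1L]))
  }
  if (any(d < 0)) {
    i <- which(d < 0)[1L]
    stop(sprintf("axial positions must be strictly increasing; index %d (l = %g) is out of order",
                 i + 1L, positions[i + 1L]))
  }
  if (any(radii < 0))
    stop("radii must be non-negative")
  interior <- positions > 0 & positions < 1
  if (any(radii[interior] == 0))
    stop("interior radii must be strictly positive")

  structure(
    list(length_L = length_L,
         coords = data.frame(l = as.numeric(positions), r = as.numeric(radii)),
         label = label),
    class = "morphometric_profile")
}

#' Complete a profile with the standard terminal coordinates
#'
#' Adds the supplementary coordinates `(0, 0)` and `(1, 0)` to a profile that
#' does not already span the full body, so that the body closes to a point at
#' the anterior and posterior tips.
#'
#' @param profile a [morphometric_profile()].
#' @return a supplemented `morphometric_profile`.
#' @export
supplement_profile <- function(profile) {
  stopifnot(inherits(profile, "morphometric_profile"))
  morphometric_profile(profile$coords$l, profile$coords$r,
                       profile$length_L, profile$label, supplement = TRUE)
}

#' Convert a relative profile to absolute coordinates
#'
#' Scales the relative coordinates of a profile by the body length, yielding
#' axial positions and radii in metres.
#'
#' @param profile a [morphometric_profile()].
#' @return data frame with columns `position` and `radius`, in metres, in the
#'   original order.
#' @examples
#' p <- cobb_to_profile(aplectus_antarcticus())
#' head(profile_to_absolute(p))
#' @export
profile_to_absolute <- function(profile) {
  stopifnot(inherits(profile, "morphometric_profile"))
  data.frame(position = profile$coords$l * profile$length_L,
             radius = profile$coords$r * profile$length_L)
}

#' @export
print.morphometric_profile <- function(x, ...) {
  cat("Morphometric profile")
  if (!is.null(x$label)) cat(" of ", x$label, sep = "")
  cat(sprintf(": L = %g m, %d coordinates\n", x$length_L, nrow(x$coords)))
  print(x$coords, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.morphometric_profile <- function(x, ...) x$coords

n_coords <- function(profile) nrow(profile$coords)

is_supplemented <- function(profile) {
  co <- profile$coords
  n <- nrow(co)
  n >= 2L && co$l[1L] == 0 && co$r[1L] == 0 && co$l[n] == 1 && co$r[n] == 0
}
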