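#' Size estimates container
#'
#' Bundles the four size measures produced by every estimator in the package:
#' perimeter `p` of the projected (silhouette) outline in metres, projected
#' area `a` in square metres, surface area `a_s` in square metres and volume
#' `v` in cubic metres, together with the method that produced them.
#'
#' @param p perimeter (m).
#' @param a projected area (m^2).
#' @param a_s surface area (m^2).
#' @param v volume (m^3).
#' @param method one of `"cylinder"`, `"andrassy"`, `"tsalolikhin"`,
#'   `"geometric"`, `"bezier"`.
#' @return an object of class `size_estimates`.
#' @export
size_estimates <- function(p, a, a_s, v,
                           method = c("cylinder", "andrassy", "tsalolikhin",
                                      "geometric", "bezier")) {
  method <- match.arg(method)
  vals <- c(p = p, a = a, a_s = a_s, v = v)
  if (any(!is.na(vals) & vals < 0))
    stop("size estimates must be non-negative")
  structure(list(p = p, a = a, a_s = a_s, v = v, method = method),
            class = "size_estimates")
}

#' @export
print.size_estimates <- function(x, digits = 4, ...) {
  cat(sprintf("Size estimates (%s model)\n", x$method))
  cat(sprintf("  perimeter      p   = %s m\n", format(signif(x$p, digits))))
  cat(sprintf("  projected area a   = %s m^2\n", format(signif(x$a, digits))))
  cat(sprintf("  surface area   a_s = %s m^2\n", format(signif(x$a_s, digits))))
  cat(sprintf("  volume         v   = %s m^3\n", format(signif(x$v, digits))))
  invisible(x)
}

#' @export
as.data.frame.size_estimates <- function(x, ...) {
  data.frame(method = x$method, p = x$p, a = x$a, a_s = x$a_s, v = x$v,
             stringsAsFactors = FALSE)
}
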