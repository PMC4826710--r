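#' Compare size estimators on one profile
#'
#' Runs the requested estimators on a profile and tabulates perimeter,
#' projected area, surface area and volume, together with percent
#' differences relative to a reference method (by default the piecewise
#' geometric model, which represents the minimum - convex-hull - size of the
#' body).  The classical methods derive their `L`, `D`, `d` and widest-point
#' position from the profile via [shape_params_from_profile()].  The
#' Andrassy estimator defines a volume only; its other measures are `NA`.
#'
#' @param profile a [morphometric_profile()].
#' @param methods character vector drawn from `"cylinder"`, `"andrassy"`,
#'   `"tsalolikhin"`, `"geometric"`, `"bezier"`.
#' @param reference method against which percent differences are computed;
#'   it is added to the computation if absent from `methods`.
#' @param bezier_construction construction passed to [build_outline()].
#' @return data frame with one row per method: columns `method`, `p`, `a`,
#'   `a_s`, `v` and `pct_p`, `pct_a`, `pct_a_s`, `pct_v` (percent difference
#'   from the reference).
#' @examples
#' estimate_report(cobb_to_profile(aplectus_antarcticus()))
#' @export
estimate_report <- function(profile,
                            methods = c("cylinder", "andrassy", "tsalolikhin",
                                        "geometric", "bezier"),
                            reference = "geometric",
                            bezier_construction = "edited") {
  stopifnot(inherits(profile, "morphometric_profile"))
  all_methods <- c("cylinder", "andrassy", "tsalolikhin", "geometric", "bezier")
  bad <- setdiff(methods, all_methods)
  if (length(bad) > 0L)
    stop(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")))
  if (!reference %in% all_methods)
    stop(sprintf("unknown reference method '%s'", reference))

  need <- union(methods, reference)
  params <- if (any(need != "geometric"))
    shape_params_from_profile(profile) else NULL
  one <- function(m) {
    est <- switch(m,
      cylinder = cylinder_estimates(params),
      andrassy = size_estimates(NA_real_, NA_real_, NA_real_,
                                andrassy_volume(params), method = "andrassy"),
      tsalolikhin = tsalolikhin_shape_estimates(params),
      geometric = piecewise_estimates(profile),
      bezier = bezier_estimates(build_outline(profile, bezier_construction)))
    as.data.frame(est)
  }
  rows <- lapply(need, one)
  tab <- do.call(rbind, rows)
  ref <- tab[tab$method == reference, ]
  for (col in c("p", "a", "a_s", "v")) {
    tab[[paste0("pct_", col)]] <- 100 * (tab[[col]] / ref[[col]] - 1)
  }
  tab <- tab[tab$method %in% methods, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write an estimate report as CSV
#'
#' @param report data frame from [estimate_report()].
#' @param path output file path (`""` prints to stdout).
#' @param full_precision if `FALSE` (default), numbers are rounded to 4
#'   significant figures; if `TRUE`, written with 17 significant digits so
#'   that re-reading reproduces them bit for bit.
#' @return the path, invisibly.
#' @export
write_report_csv <- function(report, path, full_precision = FALSE) {
  out <- report
  num <- vapply(out, is.numeric, logical(1L))
  if (full_precision) {
    for (j in which(num)) out[[j]] <- sprintf("%.17g", out[[j]])
  } else {
    for (j in which(num)) out[[j]] <- signif(out[[j]], 4)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
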