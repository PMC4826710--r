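#' Read a morphometric profile from CSV or JSON
#'
#' The CSV dialect has two columns, `position` and `value`, preceded by
#' metadata comment lines of the form `#key=value`.  Three metadata keys are
#' mandatory, because guessing measurement conventions silently is exactly
#' the trap these data are known for (diameters read as radii, percentages
#' read as fractions):
#'
#' * `units` - one of `percent`, `fraction`, `absolute`; how both columns
#'   are expressed (`absolute` means metres).
#' * `value_kind` - `radius` or `diameter`; what the `value` column holds.
#' * `length_m` - total body length in metres.
#'
#' Optional keys: `label` (specimen name) and `supplement`
#' (`true`/`false`, default `true`: add the terminal `(0,0)` and `(1,0)`
#' coordinates when absent).
#'
#' The JSON form carries the same keys plus `position` and `value` arrays.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return a [morphometric_profile()].
#' @seealso [write_profile_csv()]
#' @export
read_profile <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  meta_and_data <- if (format == "json") read_profile_json(path)
                   else read_profile_csv_raw(path)
  build_profile_from_raw(meta_and_data, path)
}

read_profile_csv_raw <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[trimws(substr(kv, 1, eq - 1))]] <- trimws(substr(kv, eq + 1, nchar(kv)))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("position", "value") %in% names(df)))
    stop(sprintf("'%s': expected columns 'position' and 'value'", path))
  c(meta, list(position = df$position, value = df$value))
}

read_profile_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$position) || is.null(obj$value))
    stop(sprintf("'%s': expected 'position' and 'value' arrays", path))
  obj
}

build_profile_from_raw <- function(raw, path) {
  for (key in c("units", "value_kind", "length_m")) {
    if (is.null(raw[[key]]))
      stop(sprintf("'%s': missing required metadata key '%s' (measurement conventions are never guessed)",
                   path, key))
  }
  units <- match.arg(as.character(raw$units), c("percent", "fraction", "absolute"))
  kind <- match.arg(as.character(raw$value_kind), c("radius", "diameter"))
  L <- as.numeric(raw$length_m)
  if (!is.finite(L) || L <= 0) stop(sprintf("'%s': invalid length_m", path))
  pos <- as.numeric(raw$position)
  val <- as.numeric(raw$value)
  scale <- switch(units, percent = 1 / 100, fraction = 1, absolute = 1 / L)
  pos <- pos * scale
  val <- val * scale
  if (kind == "diameter") val <- val / 2
  supp <- if (is.null(raw$supplement)) TRUE
          else tolower(as.character(raw$supplement)) %in% c("true", "1", "yes")
  label <- if (is.null(raw$label)) NULL else as.character(raw$label)
  morphometric_profile(pos, val, L, label = label, supplement = supp)
}

#' Write a profile in the package CSV dialect
#'
#' Emits the canonical form (fractions of `L`, radii), which
#' [read_profile()] consumes unchanged; the fixture generator uses the same
#' writer.
#'
#' @param profile a [morphometric_profile()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "morphometric_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#units=fraction",
               "#value_kind=radius",
               sprintf("#length_m=%.17g", profile$length_L),
               if (!is.null(profile$label)) sprintf("#label=%s", profile$label),
               "#supplement=false",
               "position,value",
               sprintf("%.17g,%.17g", profile$coords$l, profile$coords$r)),
             con)
  invisible(path)
}
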