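# Spectrum container and plain-text file I/O shared by all modules.
#
# File dialect: optional `# key: value` metadata header lines followed by a
# two-column numeric body, whitespace- or comma-separated.  The same dialect
# is used for input and output so round trips are exact.

#' Spectrum container
#'
#' @param x Abscissa values (field in mT, velocity in mm/s, or temperature
#'   in K, according to `kind`).
#' @param y Ordinate values.
#' @param kind One of `"field"`, `"velocity"`, `"temperature"`.
#' @param meta Named list of acquisition metadata (e.g. `frequency_GHz`,
#'   `temperature_K`, `field_T`).
#' @return Object of class `spectrum_data`.
#' @export
spectrum_data <- function(x, y, kind = c("field", "velocity", "temperature"),
                          meta = list()) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(y), is.numeric(x), is.numeric(y))
  structure(list(x = as.numeric(x), y = as.numeric(y), kind = kind,
                 meta = meta), class = "spectrum_data")
}

#' @export
print.spectrum_data <- function(x, ...) {
  unit <- switch(x$kind, field = "mT", velocity = "mm/s", temperature = "K")
  cat(sprintf("<spectrum_data> %s, %d points, %s = [%g, %g]\n",
              x$kind, length(x$x), unit, min(x$x), max(x$x)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = " = ",
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.spectrum_data <- function(x, ...) {
  xlab <- switch(x$kind, field = "Field (mT)", velocity = "Velocity (mm/s)",
                 temperature = "Temperature (K)")
  plot(x$x, x$y, type = "l", xlab = xlab, ylab = "Intensity", ...)
  invisible(x)
}

.parse_meta_value <- function(v) {
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) num else v
}

#' Read / write two-column spectrum files
#'
#' @param path File path.
#' @param kind Abscissa kind recorded in the returned object; if the file
#'   header carries a `kind` key it takes precedence.
#' @return `read_spectrum` returns a [spectrum_data()]; `write_spectrum`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path, kind = "field") {
  lines <- readLines(path)
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+?)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- .parse_meta_value(m[3])
  }
  body <- lines[!is_meta & nzchar(trimws(lines))]
  body_lineno <- which(!is_meta & nzchar(trimws(lines)))
  rows <- lapply(body, function(ln)
    suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:],]+")[[1]])))
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) < 2L || anyNA(rows[[i]][1:2]))
      stop("non-numeric or malformed data row at line ", body_lineno[i],
           " of ", path)
  }
  xy <- do.call(rbind, rows)
  if (!is.null(meta$kind)) kind <- meta$kind
  spectrum_data(xy[, 1], xy[, 2], kind = kind,
                meta = meta[setdiff(names(meta), "kind")])
}

#' @rdname read_spectrum
#' @param spec A [spectrum_data()] object.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_data"))
  hdr <- c(sprintf("# kind: %s", spec$kind),
           vapply(names(spec$meta), function(k)
             sprintf("# %s: %s", k, format(spec$meta[[k]], digits = 15)), ""))
  body <- sprintf("%.10g %.10g", spec$x, spec$y)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write temperature-series files
#'
#' Two- or three-column text: temperature (K), value, optional per-point
#' uncertainty.  Same `# key: value` header dialect as spectra.
#'
#' @param path File path.
#' @return `read_series` returns a data.frame with columns `T`, `value`
#'   (and `sigma` if present) plus a `meta` attribute.
#' @export
read_series <- function(path) {
  sp <- read_spectrum(path, kind = "temperature")
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- lapply(body, function(ln)
    suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:],]+")[[1]])))
  ncol3 <- all(vapply(cols, length, 0L) >= 3L)
  out <- data.frame(T = sp$x, value = sp$y)
  if (ncol3) out$sigma <- vapply(cols, `[`, 0, 3L)
  attr(out, "meta") <- sp$meta
  out
}

#' @rdname read_series
#' @param series Data frame with columns `T`, `value` and optional `sigma`.
#' @param meta Named list written as header lines.
#' @export
write_series <- function(series, path, meta = list()) {
  hdr <- vapply(names(meta), function(k)
    sprintf("# %s: %s", k, format(meta[[k]], digits = 15)), "")
  cols <- c("T", "value", if ("sigma" %in% names(series)) "sigma")
  body <- apply(series[cols], 1L, function(r)
    paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read a flat key = value truth or configuration file
#'
#' Sections are introduced by `[name]` lines; keys inside a section are
#' returned as a nested list.  Numeric scalars and comma-separated numeric
#' vectors are coerced automatically.
#'
#' @param path File path.
#' @return Nested named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list(); section <- NULL
  for (ln in lines) {
    sec <- regmatches(ln, regexec("^\\s*\\[(.+)\\]\\s*$", ln))[[1]]
    if (length(sec) == 2L) { section <- sec[2]; out[[section]] <- list(); next }
    kv <- regmatches(ln, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(kv) != 3L) stop("cannot parse config line: ", ln)
    val <- kv[3]
    parts <- strsplit(val, "\\s*,\\s*")[[1]]
    nums <- suppressWarnings(as.numeric(parts))
    if (!anyNA(nums)) val <- nums
    if (is.null(section)) out[[kv[2]]] <- val else out[[section]][[kv[2]]] <- val
  }
  out
}

#' @rdname read_config
#' @param config Nested named list (one level of sections).
#' @export
write_config <- function(config, path) {
  scalar <- function(k, v)
    sprintf("%s = %s", k, paste(format(v, digits = 15), collapse = ", "))
  is_sec <- vapply(config, is.list, TRUE)
  lines <- unlist(lapply(names(config)[!is_sec], function(k)
    scalar(k, config[[k]])))        # top-level keys before any section
  for (k in names(config)[is_sec]) {
    v <- config[[k]]
    lines <- c(lines, sprintf("[%s]", k),
               unlist(lapply(names(v), function(kk) scalar(kk, v[[kk]]))))
  }
  writeLines(lines, path)
  invisible(path)
}
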