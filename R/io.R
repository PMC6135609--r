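#' Write a trace series to disk
#'
#' Serialises a [trace_series()] as plain text: one CSV file per trace
#' (columns `time_s`, `anisotropy`, values printed at full double
#' precision so the round-trip is lossless) plus a JSON manifest
#' (`manifest.json`) recording the scheme, kind, calibration, instrument
#' spec, units and per-trace metadata.  Unknown metadata entries are
#' carried through unchanged.
#'
#' @param series a [trace_series()].
#' @param path directory to write into (created if missing).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "trace_series"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("trace_%02d.csv", seq_along(series$traces))
  for (i in seq_along(series$traces)) {
    tr <- series$traces[[i]]
    con <- file.path(path, files[i])
    writeLines(c("time_s,anisotropy",
                 sprintf("%.17g,%.17g", tr$times, tr$values)), con)
  }
  manifest <- list(
    format = "parpkin-series-1",
    units = list(time = "s", signal = "anisotropy", concentration = "nM"),
    scheme = series$scheme, kind = series$kind,
    calibration = unclass(series$calibration),
    instrument = unclass(series$instrument),
    extra = series$extra,
    traces = lapply(seq_along(series$traces), function(i) {
      list(file = files[i], meta = series$traces[[i]]$meta)
    }))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a trace series from disk
#'
#' Inverse of [write_series()].  Fails with an informative message when
#' the manifest is absent, a trace file named by the manifest is missing,
#' or a trace file is malformed.
#'
#' @param path directory written by [write_series()].
#' @return A [trace_series()].
#' @export
read_series <- function(path) {
  mfile <- file.path(path, "manifest.json")
  if (!file.exists(mfile)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mfile)
  if (!identical(manifest$format, "parpkin-series-1")) {
    stop("unrecognised series format: ", manifest$format %||% "<missing>")
  }
  traces <- lapply(manifest$traces, function(entry) {
    f <- file.path(path, entry$file)
    if (!file.exists(f)) {
      stop("manifest names trace file '", entry$file,
           "' but it does not exist under ", path)
    }
    tab <- tryCatch(read.csv(f, colClasses = "numeric"),
                    error = function(e) {
                      stop("malformed trace file '", entry$file, "': ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (!all(c("time_s", "anisotropy") %in% names(tab))) {
      stop("trace file '", entry$file,
           "' lacks the time_s/anisotropy columns")
    }
    if (anyNA(tab$time_s) || anyNA(tab$anisotropy)) {
      bad <- which(is.na(tab$time_s) | is.na(tab$anisotropy))[1]
      stop("trace file '", entry$file, "': non-numeric value at data line ",
           bad)
    }
    new_trace(tab$time_s, tab$anisotropy, meta = simplify_meta(entry$meta))
  })
  cal <- do.call(anisotropy_calibration,
                 manifest$calibration[c("r_free", "r_bound")])
  inst <- do.call(instrument_spec, manifest$instrument)
  trace_series(traces, manifest$scheme, manifest$kind, cal, inst,
               extra = simplify_meta(manifest$extra))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# JSON scalars come back as length-1 lists; flatten one level
simplify_meta <- function(meta) {
  if (is.null(meta)) return(list())
  lapply(meta, function(x) if (is.list(x) && length(x) == 1L &&
                               is.null(names(x))) x[[1]] else x)
}
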