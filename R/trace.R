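#' Stopped-flow scattering trace
#'
#' One normalized 90-degree light-scattering time series recorded after an
#' osmotic jump, together with the absolute temperature of the measurement
#' and the vesicle/buffer geometry needed to model it.
#'
#' @param t time points (s), strictly increasing, starting at >= 0
#' @param I_norm normalized intensities (dimensionless, nominally 0-1)
#' @param temperature absolute temperature of the measurement (K)
#' @param spec a [vesicle_spec()]
#' @param meta optional named list of free-form metadata (kept on round
#'   trips through the CSV reader/writer)
#' @return an object of class `sf_trace`
#' @export
sf_trace <- function(t, I_norm, temperature, spec = vesicle_spec(),
                     meta = list()) {
  stopifnot(is.numeric(t), is.numeric(I_norm))
  if (length(t) != length(I_norm))
    stop("t and I_norm must have equal length", call. = FALSE)
  if (length(t) < 20)
    stop("a trace needs at least 20 samples", call. = FALSE)
  if (t[1] < 0 || any(diff(t) <= 0))
    stop("t must be strictly increasing from >= 0", call. = FALSE)
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop("temperature must be a single positive value (K)", call. = FALSE)
  .check_vesicle_spec(spec)
  structure(list(t = as.numeric(t), I_norm = as.numeric(I_norm),
                 temperature = temperature, spec = spec, meta = meta),
            class = "sf_trace")
}

#' @export
print.sf_trace <- function(x, ...) {
  cat(sprintf("Stopped-flow trace: %d points, t = [%g, %g] s, T = %g K\n",
              length(x$t), x$t[1], x$t[length(x$t)], x$temperature))
  invisible(x)
}

#' @export
plot.sf_trace <- function(x, ...) {
  graphics::plot(x$t, x$I_norm, type = "l",
                 xlab = "time (s)", ylab = "normalized intensity",
                 main = sprintf("T = %g K", x$temperature), ...)
  invisible(x)
}

## fit window after the instrument dead time (default 1 ms)
.trace_window <- function(trace, dead_time = 1e-3) {
  keep <- trace$t >= dead_time
  if (sum(keep) < 10)
    stop("fewer than 10 samples after the dead time", call. = FALSE)
  list(t = trace$t[keep], I = trace$I_norm[keep])
}

#' Read / write stopped-flow trace CSV files
#'
#' The trace dialect is a plain CSV with `#`-prefixed header lines carrying
#' the measurement metadata, followed by `time_s,intensity_norm` rows:
#' ```
#' # temperature_K=278
#' # c_in0_osm=210
#' # c_out_osm=360
#' # r0_nm=50
#' time_s,intensity_norm
#' 0,0
#' ...
#' ```
#'
#' @param path file path
#' @return `read_trace_csv()` returns an [sf_trace()];
#'   `write_trace_csv()` returns `path` invisibly.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  if (is.null(kv$temperature_K))
    stop("missing `# temperature_K=` header in ", path,
         " (a trace without its temperature cannot be fitted)", call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2 || !grepl("^time_s\\s*,\\s*intensity_norm", body[1]))
    stop("expected a `time_s,intensity_norm` column header in ", path,
         call. = FALSE)
  rows <- strsplit(body[-1], ",")
  bad <- which(vapply(rows, length, 0L) != 2)
  if (length(bad))
    stop("malformed row(s) in ", path, " at data line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  tt <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 1)))
  ii <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 2)))
  if (anyNA(tt) || anyNA(ii))
    stop("non-numeric value(s) in ", path, " at data line(s): ",
         paste(which(is.na(tt) | is.na(ii)), collapse = ", "), call. = FALSE)
  nonmono <- which(diff(tt) <= 0)
  if (length(nonmono))
    stop("non-monotone time in ", path, " at data line ", nonmono[1] + 1,
         call. = FALSE)
  spec <- vesicle_spec(
    r0_nm = as.numeric(kv$r0_nm %||% 50),
    c_in0 = as.numeric(kv$c_in0_osm %||% 210),
    c_out = as.numeric(kv$c_out_osm %||% 360))
  known <- c("temperature_K", "c_in0_osm", "c_out_osm", "r0_nm")
  sf_trace(tt, ii, temperature = as.numeric(kv$temperature_K), spec = spec,
           meta = kv[setdiff(names(kv), known)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_trace_csv
#' @param trace an [sf_trace()]
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sf_trace"))
  hdr <- c(
    sprintf("# temperature_K=%.10g", trace$temperature),
    sprintf("# c_in0_osm=%.10g", trace$spec$c_in0),
    sprintf("# c_out_osm=%.10g", trace$spec$c_out),
    sprintf("# r0_nm=%.10g", trace$spec$r0 * 1e9))
  if (length(trace$meta))
    hdr <- c(hdr, sprintf("# %s=%s", names(trace$meta),
                          vapply(trace$meta, as.character, "")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s,intensity_norm", con)
  ## 17 significant digits: doubles survive the round trip exactly
  writeLines(sprintf("%.17g,%.17g", trace$t, trace$I_norm), con)
  invisible(path)
}

#' Read / write a temperature ensemble with its manifest
#'
#' An ensemble is one proteoliposome trace plus one protein-free control
#' trace per temperature. On disk it is a directory containing the trace
#' CSVs and a `manifest.csv` with columns
#' `temperature_K,trace_file,control_file` (paths relative to the manifest).
#'
#' @param dir directory to write to / read from
#' @param ensemble an `sf_ensemble` as produced by [simulate_ensemble()]:
#'   a list with elements `traces` and `controls` (lists of [sf_trace()])
#' @return `read_ensemble()` returns an `sf_ensemble` list with `traces`,
#'   `controls` and `temperatures`; `write_ensemble()` returns `dir`
#'   invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(is.list(ensemble$traces), is.list(ensemble$controls),
            length(ensemble$traces) == length(ensemble$controls))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(ensemble$traces)
  rows <- character(n)
  for (k in seq_len(n)) {
    Tk <- ensemble$traces[[k]]$temperature
    tf <- sprintf("trace_%03.0fK.csv", Tk)
    cf <- sprintf("control_%03.0fK.csv", Tk)
    write_trace_csv(ensemble$traces[[k]], file.path(dir, tf))
    write_trace_csv(ensemble$controls[[k]], file.path(dir, cf))
    rows[k] <- sprintf("%.10g,%s,%s", Tk, tf, cf)
  }
  writeLines(c("temperature_K,trace_file,control_file", rows),
             file.path(dir, "manifest.csv"))
  if (!is.null(ensemble$truth)) {
    tl <- vapply(names(ensemble$truth), function(nm)
      sprintf("%s = %.12g", nm, ensemble$truth[[nm]]), "")
    writeLines(tl, file.path(dir, "ground_truth.txt"))
  }
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir, call. = FALSE)
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  need <- c("temperature_K", "trace_file", "control_file")
  if (!all(need %in% names(man)))
    stop("manifest.csv must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  traces <- lapply(file.path(dir, man$trace_file), read_trace_csv)
  controls <- lapply(file.path(dir, man$control_file), read_trace_csv)
  structure(list(traces = traces, controls = controls,
                 temperatures = man$temperature_K),
            class = "sf_ensemble")
}
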