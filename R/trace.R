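#' Fluorescence trace objects
#'
#' A `fluor_trace` holds one region's fluorescence time series together with
#' its sampling metadata. `kind` records the processing stage: `"raw"`
#' (camera units), `"dff"` (fractional change (F - F0)/F0) or `"normalized"`
#' (affinely mapped to the unit interval, as in normalized trace figures).
#' `NA` samples mark dropped frames; they are excluded from baselines,
#' extrema and detection, and runs of dropped frames longer than one second
#' are rejected.
#'
#' @param values numeric vector of samples (NA = dropped frame).
#' @param frame_rate sampling rate in Hz.
#' @param t0 time of the first sample, seconds.
#' @param kind one of `"raw"`, `"dff"`, `"normalized"`.
#' @param region region-of-interest label (e.g. `"DGH"`, `"CA3"`).
#' @param condition genotype/condition label.
#' @param drug_onset time of drug application in seconds, or `NA`.
#' @return A `fluor_trace` object.
#' @export
fluor_trace <- function(values, frame_rate, t0 = 0, kind = c("raw", "dff", "normalized"),
                        region = NA_character_, condition = NA_character_,
                        drug_onset = NA_real_) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  check_scalar(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  if (length(values) < 1L) stop("trace must contain at least one sample")
  if (any(!is.finite(values) & !is.na(values)))
    stop("trace values must be finite or NA (dropped frame)")
  na_runs <- rle(is.na(values))
  if (any(na_runs$values & na_runs$lengths > frame_rate))
    stop("run of dropped frames longer than 1 s")
  structure(
    list(values = values, frame_rate = frame_rate, t0 = t0, kind = kind,
         region = region, condition = condition, drug_onset = drug_onset),
    class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %s | %d samples @ %g Hz (%.1f s)%s%s\n",
              x$kind, length(x$values), x$frame_rate,
              length(x$values) / x$frame_rate,
              if (!is.na(x$region)) paste0(" | region ", x$region) else "",
              if (!is.na(x$condition)) paste0(" | ", x$condition) else ""))
  invisible(x)
}

#' @export
length.fluor_trace <- function(x) length(x$values)

#' Sample times of a trace
#' @param trace a [fluor_trace()].
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1L) / trace$frame_rate
}

#' Trace duration in seconds
#' @inheritParams trace_times
#' @export
trace_duration <- function(trace) length(trace$values) / trace$frame_rate

#' Compute the fractional fluorescence change (delta F/F)
#'
#' F0 is the mean raw fluorescence over a baseline window, by default the
#' pre-drug period (the first 600 s when no drug onset is recorded). Values
#' become `(F - F0)/F0`; ratio to a baseline makes the readout invariant to
#' multiplicative gain of the optical path.
#'
#' @param trace a raw [fluor_trace()].
#' @param baseline_window `(start_s, end_s)` window used for F0; default the
#'   recording start up to the drug onset (or 600 s).
#' @return A `fluor_trace` with `kind = "dff"`.
#' @export
compute_dff <- function(trace, baseline_window = NULL) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (trace$kind != "raw") stop("compute_dff() expects a raw trace")
  if (is.null(baseline_window)) {
    end <- if (!is.na(trace$drug_onset)) trace$drug_onset else 600
    baseline_window <- c(trace$t0, min(trace$t0 + trace_duration(trace), end))
  }
  tt <- trace_times(trace)
  in_win <- tt >= baseline_window[1L] & tt < baseline_window[2L]
  f0 <- mean(trace$values[in_win], na.rm = TRUE)
  if (!is.finite(f0) || !any(in_win)) stop("baseline window contains no samples")
  if (f0 <= 0) stop("baseline fluorescence F0 <= 0; cannot normalize")
  out <- trace
  out$values <- (trace$values - f0) / f0
  out$kind <- "dff"
  out
}

#' Normalize a trace to the unit interval
#'
#' Affinely maps the valid samples so the minimum becomes 0 and the maximum 1
#' (the convention used when plotting normalized delta F/F traces). Dropped
#' frames are ignored when locating the extrema. Idempotent.
#'
#' @inheritParams trace_times
#' @return A `fluor_trace` with `kind = "normalized"`.
#' @export
normalize_unit <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  v <- trace$values
  lo <- min(v, na.rm = TRUE)
  hi <- max(v, na.rm = TRUE)
  if (!is.finite(lo) || !is.finite(hi) || hi == lo)
    stop("cannot normalize a constant trace (degenerate range)")
  out <- trace
  out$values <- (v - lo) / (hi - lo)
  out$kind <- "normalized"
  out
}

#' Read and write trace tables
#'
#' Traces are exchanged as delimited text with a `time` column (seconds) and
#' one column per region. Metadata (frame rate, drug onset, kind) travels in
#' `#`-prefixed header comments.
#'
#' @param traces list of [fluor_trace()] sharing frame rate and length.
#' @param path file path.
#' @param sep field separator.
#' @return `write_trace_table()` returns `path` invisibly;
#'   `read_trace_table()` returns a list of `fluor_trace`.
#' @export
write_trace_table <- function(traces, path, sep = "\t") {
  if (inherits(traces, "fluor_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  fr <- unique(vapply(traces, function(x) x$frame_rate, 0))
  ns <- unique(vapply(traces, function(x) length(x$values), 0L))
  if (length(fr) != 1L || length(ns) != 1L)
    stop("traces must share frame rate and length")
  labels <- vapply(seq_along(traces), function(i) {
    r <- traces[[i]]$region
    if (is.na(r)) paste0("trace", i) else r
  }, "")
  df <- data.frame(time = trace_times(traces[[1L]]))
  for (i in seq_along(traces)) df[[labels[i]]] <- traces[[i]]$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# frame_rate: %g", fr),
    sprintf("# kind: %s", traces[[1L]]$kind),
    sprintf("# drug_onset: %g", traces[[1L]]$drug_onset),
    sprintf("# condition: %s", traces[[1L]]$condition)), con)
  write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_table
#' @export
read_trace_table <- function(path, sep = "\t") {
  hdr <- readLines(path, n = 20L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- list(frame_rate = NA_real_, kind = "dff", drug_onset = NA_real_,
               condition = NA_character_)
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1L]]
    if (length(kv) == 2L && kv[1L] %in% names(meta)) meta[[kv[1L]]] <- kv[2L]
  }
  df <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                   check.names = FALSE)
  if (!"time" %in% names(df))
    stop("trace table is missing required column `time`")
  fr <- suppressWarnings(as.numeric(meta$frame_rate))
  if (!is.finite(fr)) {
    dt <- diff(df$time)
    fr <- 1 / median(dt)
  }
  kind <- if (meta$kind %in% c("raw", "dff", "normalized")) meta$kind else "dff"
  onset <- suppressWarnings(as.numeric(meta$drug_onset))
  cond <- if (identical(meta$condition, "NA")) NA_character_ else meta$condition
  regions <- setdiff(names(df), "time")
  lapply(regions, function(r) {
    fluor_trace(df[[r]], frame_rate = fr, t0 = df$time[1L], kind = kind,
                region = r, condition = cond, drug_onset = onset)
  })
}
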