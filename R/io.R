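#' Write detected event intervals as BED-like text
#'
#' Three tab-separated columns — trace id, start and end in seconds
#' (half-open) — one row per event.
#'
#' @param trains an `sle_train` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(trains, path) {
  if (inherits(trains, "sle_train")) trains <- list(trains)
  rows <- lapply(trains, function(tr) {
    if (nrow(tr$intervals) == 0L) return(NULL)
    data.frame(id = if (is.na(tr$trace_id)) "trace" else tr$trace_id,
               start = tr$intervals[, 1L], end = tr$intervals[, 2L])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(id = character(0), start = numeric(0),
                                    end = numeric(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a JSON provenance record for a run
#'
#' Records the parameters, thresholds, seed and software version needed to
#' re-run a detection identically.
#'
#' @param path output path.
#' @param params parameter list (e.g. a [detection_params()]).
#' @param seed the seed used, or `NULL`.
#' @param extra named list of additional fields (noise SDs, thresholds...).
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, params = NULL, seed = NULL, extra = list()) {
  log <- c(list(package = "epislice",
                version = as.character(packageVersion("epislice")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                seed = seed,
                params = if (!is.null(params)) unclass(params) else NULL),
           extra)
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read detection/simulation parameters from a YAML file
#'
#' Unknown keys are rejected so a typo in a config cannot silently fall
#' back to a default.
#'
#' @param path YAML file path.
#' @param constructor the parameter constructor the keys belong to
#'   (default [detection_params()]).
#' @return the constructed parameter object.
#' @export
read_params_yaml <- function(path, constructor = detection_params) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(constructor))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop(sprintf("unknown parameter key(s): %s", paste(unknown, collapse = ", ")))
  do.call(constructor, vals)
}

#' Write a ramp or current-clamp recording as delimited text
#'
#' One block per sweep separated by `# sweep` comment lines, so recordings
#' round-trip through plain text.
#'
#' @param rec a `ramp_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ramp_table <- function(rec, path) {
  stopifnot(inherits(rec, "ramp_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate: %g", rec$sample_rate), con)
  for (i in seq_along(rec$sweeps)) {
    writeLines(sprintf("# sweep %d time_from_breakin %g", i,
                       rec$time_from_breakin[i]), con)
    write.table(rec$sweeps[[i]], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = i == 1L)
  }
  invisible(path)
}

#' @rdname write_ramp_table
#' @export
read_ramp_table <- function(path) {
  lines <- readLines(path)
  sr_line <- grep("^# sample_rate:", lines, value = TRUE)
  sample_rate <- as.numeric(sub("^# sample_rate:\\s*", "", sr_line[1L]))
  sweep_idx <- grep("^# sweep ", lines)
  header <- strsplit(lines[sweep_idx[1L] + 1L], "\t")[[1L]]
  times <- as.numeric(sub(".*time_from_breakin\\s+", "", lines[sweep_idx]))
  bounds <- c(sweep_idx, length(lines) + 1L)
  sweeps <- lapply(seq_along(sweep_idx), function(k) {
    from <- bounds[k] + 1L
    if (k == 1L) from <- from + 1L   # skip the single header line
    block <- lines[from:(bounds[k + 1L] - 1L)]
    df <- read.table(text = block, sep = "\t", col.names = header)
    df$segment <- as.character(df$segment)
    df
  })
  structure(list(sweeps = sweeps, time_from_breakin = times,
                 sample_rate = sample_rate, capacitance = NA_real_),
            class = "ramp_recording")
}
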