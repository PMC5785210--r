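#' Slope conductance from a voltage-ramp sweep
#'
#' Ordinary-least-squares slope of recorded current (pA) against commanded
#' voltage (mV) over the ramp samples whose command lies in `fit_range`
#' (default -120 to -90 mV, the standard running assessment of whole-cell
#' slope conductance). pA/mV is nS.
#'
#' @param sweep data.frame with columns `command` (mV), `current` (pA) and
#'   optionally `segment` (only `"ramp"` samples are fitted when present).
#' @param fit_range `(lo, hi)` command range in mV.
#' @return Slope conductance in nS.
#' @export
slope_conductance <- function(sweep, fit_range = c(-120, -90)) {
  stopifnot(is.data.frame(sweep), all(c("command", "current") %in% names(sweep)))
  sel <- sweep$command >= min(fit_range) & sweep$command <= max(fit_range)
  if ("segment" %in% names(sweep)) sel <- sel & sweep$segment == "ramp"
  if (sum(sel) < 10L)
    stop("fewer than 10 ramp samples inside the fit range")
  v <- sweep$command[sel]
  i <- sweep$current[sel]
  vm <- mean(v)
  sum((v - vm) * (i - mean(i))) / sum((v - vm)^2)
}

#' Input resistance from the prepulse steps
#'
#' `R = dV/dI` between the -100 and -120 mV prepulses, using the mean
#' current over the last 20 ms of each 100-ms step (a late window avoids
#' capacitive transients). Returned in megaohms.
#'
#' @param sweep data.frame with columns `t` (s), `command` (mV), `current`
#'   (pA) and `segment` containing `"step100"` and `"step120"`.
#' @param steady_window length of the steady-state averaging window at the
#'   end of each step, seconds.
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(sweep, steady_window = 0.02) {
  stopifnot(is.data.frame(sweep))
  if (!all(c("segment", "t", "current") %in% names(sweep)) ||
      !all(c("step100", "step120") %in% sweep$segment))
    stop("sweep is missing the -100/-120 mV prepulse steps")
  steady <- function(seg) {
    idx <- sweep$segment == seg
    tend <- max(sweep$t[idx])
    mean(sweep$current[idx & sweep$t > tend - steady_window])
  }
  i100 <- steady("step100")
  i120 <- steady("step120")
  dv <- -100 - (-120)                      # mV
  1000 * dv / (i100 - i120)                # mV/pA = GOhm -> MOhm
}

#' Washdown/run-up time course of slope conductance
#'
#' Fits the slope conductance of every sweep and normalizes the series to
#' the sweep nearest the anchor time (3 min after break-in by default; ties
#' resolved toward the earlier sweep; no interpolation, so the anchor value
#' is data-driven and the normalized series is exactly 1 there).
#'
#' @param rec a `ramp_recording`.
#' @param anchor_s anchor time in seconds from break-in.
#' @param anchor_tol maximal distance (s) from the anchor to the nearest
#'   sweep before erroring.
#' @param fit_range passed to [slope_conductance()].
#' @return A `conductance_timecourse` data.frame with columns `time`,
#'   `conductance` (nS), `normalized`, `input_resistance` (MOhm);
#'   attributes `anchor_time` and `anchor_conductance`.
#' @export
washdown_timecourse <- function(rec, anchor_s = 180, anchor_tol = 30,
                                fit_range = c(-120, -90)) {
  stopifnot(inherits(rec, "ramp_recording"))
  g <- vapply(rec$sweeps, slope_conductance, 0, fit_range = fit_range)
  rin <- vapply(rec$sweeps, function(s) {
    tryCatch(input_resistance(s), error = function(e) NA_real_)
  }, 0)
  times <- rec$time_from_breakin
  d <- abs(times - anchor_s)
  if (min(d) > anchor_tol)
    stop(sprintf("no sweep within %g s of the %g s anchor", anchor_tol, anchor_s))
  anchor_idx <- which(d == min(d))[1L]   # ties -> earlier sweep
  out <- data.frame(time = times, conductance = g,
                    normalized = g / g[anchor_idx], input_resistance = rin)
  attr(out, "anchor_time") <- times[anchor_idx]
  attr(out, "anchor_conductance") <- g[anchor_idx]
  class(out) <- c("conductance_timecourse", "data.frame")
  out
}

#' Count action potentials in a current-clamp sweep
#'
#' `zero_crossing` (default): upward crossings of 0 mV, the reference level
#' marked on excitability figures; `dvdt`: upward crossings of
#' `dV/dt >= dvdt_threshold` (mV/ms). Both apply an absolute refractory so
#' one spike is counted once. A spike straddling the window end counts iff
#' its crossing time falls inside the half-open window.
#'
#' @param voltage numeric voltage trace, mV.
#' @param sample_rate Hz.
#' @param pulse_window `(start_s, end_s)` counting window (half-open).
#' @param rule `"zero_crossing"` or `"dvdt"`.
#' @param refractory seconds; crossings closer than this to the previous
#'   accepted spike are ignored.
#' @param dvdt_threshold mV/ms, for the `dvdt` rule.
#' @return Integer spike count with attribute `spike_times` (seconds) and
#'   `detection_rule`.
#' @export
count_aps <- function(voltage, sample_rate, pulse_window,
                      rule = c("zero_crossing", "dvdt"), refractory = 0.002,
                      dvdt_threshold = 20) {
  rule <- match.arg(rule)
  v <- as.numeric(voltage)
  if (any(!is.finite(v))) stop("voltage trace contains non-finite samples")
  n <- length(v)
  tt <- (seq_len(n) - 1L) / sample_rate
  if (pulse_window[1L] < 0 || pulse_window[2L] > n / sample_rate + 1e-9)
    stop("pulse window lies outside the sweep")
  if (rule == "zero_crossing") {
    i <- which(v[-n] < 0 & v[-1L] >= 0) # crossing between i and i+1
    times <- tt[i] + (0 - v[i]) / (v[i + 1L] - v[i]) / sample_rate
  } else {
    d <- diff(v) * sample_rate / 1000   # mV/ms
    i <- which(d[-length(d)] < dvdt_threshold & d[-1L] >= dvdt_threshold)
    times <- tt[i + 1L]
  }
  times <- times[times >= pulse_window[1L] & times < pulse_window[2L]]
  kept <- numeric(0)
  last <- -Inf
  for (s in times) {
    if (s - last >= refractory) {
      kept <- c(kept, s)
      last <- s
    }
  }
  structure(length(kept), spike_times = kept,
            detection_rule = list(rule = rule, refractory = refractory,
                                  dvdt_threshold = dvdt_threshold))
}

#' F-I curve: action-potential count versus injected current
#'
#' Counts spikes in every sweep of a current-clamp recording and returns
#' the curve sorted by amplitude. Across-cell aggregation (mean +/- SEM) is
#' the job of the group-statistics layer.
#'
#' @param rec a `cclamp_recording`.
#' @param rule,refractory,dvdt_threshold passed to [count_aps()].
#' @return An `fi_curve` data.frame with columns `amplitude` (pA) and
#'   `ap_count`; attribute `detection_rule`.
#' @export
fi_curve <- function(rec, rule = c("zero_crossing", "dvdt"),
                     refractory = 0.002, dvdt_threshold = 20) {
  stopifnot(inherits(rec, "cclamp_recording"))
  rule <- match.arg(rule)
  if (anyDuplicated(rec$amplitudes)) stop("duplicate pulse amplitudes")
  counts <- vapply(rec$sweeps, function(v) {
    as.integer(count_aps(v, rec$sample_rate, rec$pulse_window, rule = rule,
                         refractory = refractory,
                         dvdt_threshold = dvdt_threshold))
  }, 0L)
  ord <- order(rec$amplitudes)
  out <- data.frame(amplitude = rec$amplitudes[ord], ap_count = counts[ord])
  attr(out, "detection_rule") <- list(rule = rule, refractory = refractory,
                                      dvdt_threshold = dvdt_threshold)
  class(out) <- c("fi_curve", "data.frame")
  out
}
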