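#' Configuration for the synthetic calcium-imaging generator
#'
#' Describes an 80-minute slice experiment as imaged at 10 frames/s: 10 min
#' of baseline, drug application at `drug_onset`, then seizure-like events
#' (SLEs) whose rate rises sigmoidally and plateaus by 2400 s. Each SLE is a
#' dense Poisson train of calcium transients (difference-of-exponentials
#' kernel) riding on a slow baseline made of a smoothed random-walk drift
#' and an exponential photobleaching decay, plus white Gaussian noise.
#'
#' Instead of a raw event rate, the plateau is parameterized by
#' `plateau_occupancy`, the expected fraction of plateau time spent inside
#' SLEs. Events are laid down sequentially with an enforced minimum gap, so
#' a candidate rate lambda with `1/lambda = d/p - d - gap` (d = mean event
#' duration, p = occupancy, gap = `min_event_gap`) yields expected occupancy
#' p. This makes programmed between-group occupancy contrasts exact in
#' expectation.
#'
#' @param duration recording length, seconds.
#' @param frame_rate acquisition rate, Hz.
#' @param drug_onset convulsant application time, seconds.
#' @param latency_to_first_sle minimum delay from onset to the first possible
#'   event, seconds.
#' @param plateau_occupancy expected fraction of time in SLEs at plateau,
#'   in `[0, 0.7]`.
#' @param rise_midpoint,rise_scale center and scale (seconds) of the sigmoid
#'   event-rate rise; with the defaults the rate is >99% of its plateau value
#'   by 2400 s.
#' @param event_duration_mean,event_duration_sd SLE duration distribution
#'   (normal, truncated at `min_event_duration`), seconds.
#' @param min_event_duration shortest allowed event, seconds.
#' @param min_event_gap enforced gap between consecutive events, seconds.
#' @param transient_rate within-event calcium-transient rate, Hz.
#' @param transient_rise_tau,transient_decay_tau kernel time constants,
#'   seconds.
#' @param peak_dff maximal transient amplitude, delta F/F units.
#' @param amp_range transient amplitudes are uniform on
#'   `amp_range * peak_dff`.
#' @param drift_amplitude stationary SD of the slow drift, delta F/F units.
#' @param drift_tau correlation time of the drift, seconds.
#' @param bleach_amplitude,bleach_tau photobleaching baseline decays from 0
#'   to `-bleach_amplitude` with time constant `bleach_tau` (seconds).
#' @param noise_sd white-noise SD, delta F/F units.
#' @param forced_events optional two-column matrix of `[start, end)` event
#'   intervals that replaces the stochastic event process (for calibration).
#' @param seed integer seed; identical configs and seeds give bit-identical
#'   output.
#' @return A `calcium_sim_config` list.
#' @export
calcium_sim_config <- function(duration = 4800, frame_rate = 10,
                               drug_onset = 600, latency_to_first_sle = 120,
                               plateau_occupancy = 0.4, rise_midpoint = 1200,
                               rise_scale = 240, event_duration_mean = 20,
                               event_duration_sd = 5, min_event_duration = 2,
                               min_event_gap = 5, transient_rate = 8,
                               transient_rise_tau = 0.05,
                               transient_decay_tau = 0.4, peak_dff = 0.5,
                               amp_range = c(0.5, 1), drift_amplitude = 0.05,
                               drift_tau = 300, bleach_amplitude = 0.1,
                               bleach_tau = 2000, noise_sd = 0.02,
                               forced_events = NULL, seed = NULL) {
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  check_scalar(drug_onset, "drug_onset", lower = 0)
  if (duration <= drug_onset)
    stop_param("drug_onset", "duration must exceed drug_onset")
  check_scalar(latency_to_first_sle, "latency_to_first_sle", lower = 0)
  check_scalar(plateau_occupancy, "plateau_occupancy", lower = 0, upper = 0.7)
  check_scalar(transient_rise_tau, "transient_rise_tau", lower = 0, strict_lower = TRUE)
  check_scalar(transient_decay_tau, "transient_decay_tau", lower = 0, strict_lower = TRUE)
  if (transient_decay_tau <= transient_rise_tau)
    stop_param("transient_decay_tau", "must exceed transient_rise_tau")
  check_scalar(event_duration_mean, "event_duration_mean", lower = 0, strict_lower = TRUE)
  check_scalar(event_duration_sd, "event_duration_sd", lower = 0)
  check_scalar(min_event_duration, "min_event_duration", lower = 0, strict_lower = TRUE)
  check_scalar(min_event_gap, "min_event_gap", lower = 0)
  check_scalar(transient_rate, "transient_rate", lower = 0, strict_lower = TRUE)
  check_scalar(peak_dff, "peak_dff", lower = 0, strict_lower = TRUE)
  check_scalar(drift_amplitude, "drift_amplitude", lower = 0)
  check_scalar(drift_tau, "drift_tau", lower = 0, strict_lower = TRUE)
  check_scalar(bleach_amplitude, "bleach_amplitude", lower = 0)
  check_scalar(bleach_tau, "bleach_tau", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (!is.null(forced_events)) forced_events <- as_intervals(forced_events)
  structure(as.list(environment()), class = "calcium_sim_config")
}

# Difference-of-exponentials transient kernel, peak-normalized to 1 at
# t* = tr*td/(td - tr) * log(td/tr).
transient_kernel <- function(u, rise_tau, decay_tau) {
  tpk <- rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
  norm <- exp(-tpk / decay_tau) - exp(-tpk / rise_tau)
  ifelse(u >= 0, (exp(-u / decay_tau) - exp(-u / rise_tau)) / norm, 0)
}

# Sequential SLE interval sampling: thinned inhomogeneous Poisson candidates
# with sigmoid rate rise, truncated-normal durations, enforced gap.
sample_sle_intervals <- function(cfg) {
  if (!is.null(cfg$forced_events)) return(cfg$forced_events)
  p <- cfg$plateau_occupancy
  d <- cfg$event_duration_mean
  if (p <= 0) return(as_intervals(NULL))
  inv_lambda <- d / p - d - cfg$min_event_gap
  if (inv_lambda <= 0)
    stop_param("plateau_occupancy",
               "too high for the event duration and minimum gap")
  lambda_max <- 1 / inv_lambda
  t_min <- cfg$drug_onset + cfg$latency_to_first_sle
  rate_frac <- function(t) 1 / (1 + exp(-(t - cfg$rise_midpoint) / cfg$rise_scale))
  starts <- numeric(0)
  ends <- numeric(0)
  t <- t_min
  repeat {
    # next accepted candidate (thinning against lambda_max)
    repeat {
      t <- t + rexp(1L, lambda_max)
      if (t >= cfg$duration) break
      if (runif(1L) < rate_frac(t)) break
    }
    if (t >= cfg$duration) break
    dur <- rnorm(1L, cfg$event_duration_mean, cfg$event_duration_sd)
    dur <- max(dur, cfg$min_event_duration)
    e <- min(t + dur, cfg$duration)
    starts <- c(starts, t)
    ends <- c(ends, e)
    t <- e + cfg$min_event_gap
  }
  cbind(start = starts, end = ends)
}

#' Generate a synthetic delta F/F trace with ground truth
#'
#' Builds the trace as (transient train) + (drift + bleach baseline) +
#' (white noise) at the configured frame rate. Transient onsets are aligned
#' to the frame grid (the 0.1 s frame interval exceeds the kernel rise time,
#' so sub-frame timing is not resolvable anyway), which lets the train be
#' assembled by linear convolution.
#'
#' @param config a [calcium_sim_config()].
#' @param region,condition metadata labels attached to the trace.
#' @return list with elements `trace` (a [fluor_trace()], `kind = "dff"`)
#'   and `truth` (a `synthetic_truth` with exact `event_intervals` and the
#'   generating config).
#' @export
simulate_dff_trace <- function(config, region = NA_character_,
                               condition = NA_character_) {
  stopifnot(inherits(config, "calcium_sim_config"))
  with_seed(config$seed, {
    fs <- config$frame_rate
    n <- round(config$duration * fs)
    events <- sample_sle_intervals(config)

    # impulse train: transient amplitudes at frame indices
    impulses <- numeric(n)
    if (nrow(events) > 0L) {
      all_times <- vector("list", nrow(events))
      for (k in seq_len(nrow(events))) {
        s <- events[k, 1L]
        e <- events[k, 2L]
        # one transient at event start, then a Poisson train until the end
        dur <- e - s
        mu <- config$transient_rate * dur
        times <- s
        tk <- s
        repeat {
          gaps <- rexp(ceiling(mu + 4 * sqrt(mu) + 10), config$transient_rate)
          cand <- tk + cumsum(gaps)
          times <- c(times, cand[cand < e])
          tk <- tk + sum(gaps)
          if (tk >= e) break
        }
        all_times[[k]] <- times
      }
      times <- unlist(all_times)
      amps <- runif(length(times), config$amp_range[1L], config$amp_range[2L]) *
        config$peak_dff
      idx <- pmin(n, floor(times * fs) + 1L)
      agg <- rowsum(amps, idx)
      impulses[as.integer(rownames(agg))] <- agg[, 1L]
    }
    klen <- ceiling((6 * config$transient_decay_tau) * fs) + 1L
    kern <- transient_kernel((seq_len(klen) - 1L) / fs,
                             config$transient_rise_tau,
                             config$transient_decay_tau)
    signal <- as.numeric(stats::filter(impulses, kern, method = "convolution",
                                       sides = 1L))
    # sides=1 convolution leaves leading NAs shorter than the kernel
    signal[is.na(signal)] <- 0
    # re-add the partial-kernel contribution the filter() call drops at the
    # start: explicit convolution for the first klen-1 samples
    if (klen > 1L && n >= 2L) {
      for (i in seq_len(min(klen - 1L, n))) {
        j <- seq_len(i)
        signal[i] <- sum(impulses[j] * kern[i - j + 1L])
      }
    }

    tt <- (seq_len(n) - 1L) / fs
    bleach <- config$bleach_amplitude * (exp(-tt / config$bleach_tau) - 1)
    drift <- numeric(n)
    if (config$drift_amplitude > 0) {
      phi <- exp(-1 / (config$drift_tau * fs))
      w <- rnorm(n)
      drift <- as.numeric(stats::filter(w, phi, method = "recursive"))
      drift <- drift * config$drift_amplitude * sqrt(1 - phi^2)
    }
    noise <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else numeric(n)

    trace <- fluor_trace(signal + bleach + drift + noise, frame_rate = fs,
                         kind = "dff", region = region, condition = condition,
                         drug_onset = config$drug_onset)
    truth <- synthetic_truth(event_intervals = events, params = config)
    list(trace = trace, truth = truth)
  })
}

#' Ground truth attached to synthetic recordings
#'
#' @param event_intervals two-column matrix of true `[start, end)` event
#'   intervals, seconds.
#' @param spike_times true spike times, seconds (current-clamp case).
#' @param conductance_fn function of time returning the true total slope
#'   conductance in nS (ramp case).
#' @param params the generating configuration.
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(event_intervals = NULL, spike_times = NULL,
                            conductance_fn = NULL, params = NULL) {
  ev <- as_intervals(event_intervals)
  if (nrow(ev) > 1L && any(ev[-1L, 1L] < ev[-nrow(ev), 2L]))
    stop("truth event intervals overlap")
  st <- if (is.list(spike_times)) spike_times else list(spike_times)
  for (s in st) {
    if (!is.null(s) && length(s) > 1L && is.unsorted(s, strictly = TRUE))
      stop("truth spike times must be strictly increasing")
  }
  structure(list(event_intervals = ev, spike_times = spike_times,
                 conductance_fn = conductance_fn, params = params),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d event intervals, %d spikes%s\n",
              nrow(x$event_intervals), length(x$spike_times),
              if (!is.null(x$conductance_fn)) ", conductance_fn" else ""))
  invisible(x)
}
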