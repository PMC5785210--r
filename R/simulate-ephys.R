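#' Configuration for the synthetic passive-membrane ramp generator
#'
#' Models a voltage-clamped cell with an ohmic leak plus a K-ATP-like
#' conductance that varies slowly with time from break-in as a single
#' exponential: `g_katp(t) = g_inf + (g0 - g_inf) * exp(-t / tau)`. With
#' `g0 > g_inf` this is the "washdown" of an initially high conductance as
#' ATP-rich pipette solution dialyzes the cell; with `g0 < g_inf` it is
#' "run-up" under low-ATP solution; `mode = "constant"` freezes it at `g0`.
#' The conductance is frozen within each sweep at the sweep's break-in time.
#' Currents are purely resistive (the capacitive transient of an ideally
#' compensated cell is omitted; `capacitance` is kept as metadata).
#'
#' @param capacitance membrane capacitance, pF (metadata; cells of 30-40 pF).
#' @param leak_conductance ohmic leak, nS.
#' @param leak_reversal leak reversal potential, mV.
#' @param katp_conductance_t0 K-ATP conductance at break-in, nS.
#' @param katp_conductance_inf asymptotic K-ATP conductance, nS.
#' @param katp_tau washdown/run-up time constant, seconds.
#' @param katp_mode `"washdown"`, `"runup"` or `"constant"`.
#' @param katp_reversal potassium reversal potential, mV.
#' @param noise_sd additive current noise SD, pA.
#' @param sample_rate acquisition rate, Hz.
#' @param seed integer seed.
#' @return A `membrane_sim_config` list.
#' @export
membrane_sim_config <- function(capacitance = 35, leak_conductance = 1,
                                leak_reversal = -70, katp_conductance_t0 = 3,
                                katp_conductance_inf = 0, katp_tau = 60,
                                katp_mode = c("washdown", "runup", "constant"),
                                katp_reversal = -90, noise_sd = 2,
                                sample_rate = 5000, seed = NULL) {
  katp_mode <- match.arg(katp_mode)
  check_scalar(capacitance, "capacitance", lower = 0, upper = 1000,
               strict_lower = TRUE)
  check_scalar(leak_conductance, "leak_conductance", lower = 0)
  check_scalar(katp_conductance_t0, "katp_conductance_t0", lower = 0)
  check_scalar(katp_conductance_inf, "katp_conductance_inf", lower = 0)
  check_scalar(katp_tau, "katp_tau", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  if (katp_mode == "washdown" && katp_conductance_t0 < katp_conductance_inf)
    stop_param("katp_mode", "washdown requires katp_conductance_t0 >= katp_conductance_inf")
  if (katp_mode == "runup" && katp_conductance_t0 > katp_conductance_inf)
    stop_param("katp_mode", "runup requires katp_conductance_t0 <= katp_conductance_inf")
  structure(as.list(environment()), class = "membrane_sim_config")
}

katp_conductance_at <- function(cfg, t) {
  if (cfg$katp_mode == "constant") {
    rep(cfg$katp_conductance_t0, length(t))
  } else {
    cfg$katp_conductance_inf +
      (cfg$katp_conductance_t0 - cfg$katp_conductance_inf) * exp(-t / cfg$katp_tau)
  }
}

# The standard ramp command: hold -70 mV (100 ms), step -100 mV (100 ms),
# step -120 mV (100 ms), 1 s ramp -120 -> -60 mV, return to hold (100 ms).
ramp_command <- function(sample_rate) {
  dt <- 1 / sample_rate
  seg_lens <- c(hold = 0.1, step100 = 0.1, step120 = 0.1, ramp = 1.0, tail = 0.1)
  edges <- cumsum(c(0, seg_lens))
  t <- seq(0, edges[length(edges)] - dt / 2, by = dt)
  segment <- cut(t, breaks = edges, labels = names(seg_lens), right = FALSE)
  command <- numeric(length(t))
  command[segment == "hold"] <- -70
  command[segment == "step100"] <- -100
  command[segment == "step120"] <- -120
  ramp_idx <- segment == "ramp"
  command[ramp_idx] <- -120 + 60 * (t[ramp_idx] - edges[4L]) / 1.0
  command[segment == "tail"] <- -70
  data.frame(t = t, command = command, segment = as.character(segment))
}

#' Generate a synthetic voltage-clamp ramp recording with ground truth
#'
#' One sweep per `sweep_interval` (ramps applied every 10 s in the standard
#' protocol), each realizing the hold/step/step/ramp command, with current
#' `I = g_leak (V - E_leak) + g_katp(t_sweep) (V - E_K) + noise`.
#'
#' @param config a [membrane_sim_config()].
#' @param n_sweeps number of sweeps (>= 1).
#' @param sweep_interval seconds between sweeps (> 0).
#' @param t_first break-in time of the first sweep, seconds.
#' @return list with `recording` (a `ramp_recording`) and `truth` (a
#'   [synthetic_truth()] whose `conductance_fn(t)` is the exact total slope
#'   conductance, nS, at break-in time `t`).
#' @export
simulate_ramp_recording <- function(config, n_sweeps = 60, sweep_interval = 10,
                                    t_first = 0) {
  stopifnot(inherits(config, "membrane_sim_config"))
  if (!is.numeric(n_sweeps) || n_sweeps < 1) stop_param("n_sweeps", "must be >= 1")
  check_scalar(sweep_interval, "sweep_interval", lower = 0, strict_lower = TRUE)
  with_seed(config$seed, {
    cmd <- ramp_command(config$sample_rate)
    times <- t_first + (seq_len(n_sweeps) - 1L) * sweep_interval
    sweeps <- lapply(times, function(tb) {
      g_katp <- katp_conductance_at(config, tb)
      current <- config$leak_conductance * (cmd$command - config$leak_reversal) +
        g_katp * (cmd$command - config$katp_reversal)
      if (config$noise_sd > 0)
        current <- current + rnorm(length(current), 0, config$noise_sd)
      data.frame(t = cmd$t, command = cmd$command, current = current,
                 segment = cmd$segment)
    })
    rec <- structure(list(sweeps = sweeps, time_from_breakin = times,
                          sample_rate = config$sample_rate,
                          capacitance = config$capacitance),
                     class = "ramp_recording")
    truth <- synthetic_truth(
      conductance_fn = function(t) config$leak_conductance +
        katp_conductance_at(config, t),
      params = config)
    list(recording = rec, truth = truth)
  })
}

#' @export
print.ramp_recording <- function(x, ...) {
  cat(sprintf("<ramp_recording> %d sweeps @ %g Hz, break-in %g-%g s\n",
              length(x$sweeps), x$sample_rate, min(x$time_from_breakin),
              max(x$time_from_breakin)))
  invisible(x)
}

#' Configuration for the synthetic current-clamp (spiking) generator
#'
#' A leaky integrate-and-fire neuron under the standard excitability
#' protocol: holding current keeps the cell at `holding_target` (-70 mV),
#' then 1 s depolarizing pulses of 50-200 pA in 50 pA steps. An optional
#' K-ATP leak (`katp_leak` toward `katp_reversal`) lowers excitability.
#' Spikes are rendered as stereotyped waveforms peaking at `spike_peak`
#' (above 0 mV) so 0-mV-crossing detection sees them; with `noise_sd = 0`
#' spike times follow the closed-form LIF inter-spike interval.
#'
#' @param capacitance pF.
#' @param leak_conductance nS.
#' @param leak_reversal resting (leak reversal) potential, mV.
#' @param threshold spike threshold, mV (must exceed `reset`).
#' @param reset post-spike reset potential, mV.
#' @param refractory absolute refractory period, seconds (spike waveform
#'   occupies this window).
#' @param spike_peak rendered spike peak, mV.
#' @param katp_leak,katp_reversal optional K-ATP leak conductance (nS) and
#'   its reversal (mV).
#' @param holding_target holding potential, mV.
#' @param pulse_amplitudes injected pulse amplitudes, pA, strictly
#'   increasing.
#' @param pulse_duration pulse length, seconds.
#' @param pre_window,post_window held time before/after the pulse, seconds.
#' @param noise_sd current-noise SD, pA (0 = deterministic).
#' @param sample_rate Hz.
#' @param seed integer seed.
#' @return A `spiking_sim_config` list.
#' @export
spiking_sim_config <- function(capacitance = 40, leak_conductance = 4,
                               leak_reversal = -75, threshold = -40,
                               reset = -65, refractory = 0.002,
                               spike_peak = 30, katp_leak = 0,
                               katp_reversal = -90, holding_target = -70,
                               pulse_amplitudes = c(50, 100, 150, 200),
                               pulse_duration = 1, pre_window = 0.1,
                               post_window = 0.1, noise_sd = 0,
                               sample_rate = 20000, seed = NULL) {
  check_scalar(capacitance, "capacitance", lower = 0, upper = 1000,
               strict_lower = TRUE)
  check_scalar(leak_conductance, "leak_conductance", lower = 0, strict_lower = TRUE)
  check_scalar(katp_leak, "katp_leak", lower = 0)
  check_scalar(pulse_duration, "pulse_duration", lower = 0, strict_lower = TRUE)
  check_scalar(refractory, "refractory", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  if (length(pulse_amplitudes) < 1L)
    stop_param("pulse_amplitudes", "must contain at least one amplitude")
  if (length(pulse_amplitudes) > 1L &&
      is.unsorted(pulse_amplitudes, strictly = TRUE))
    stop_param("pulse_amplitudes", "must be strictly increasing")
  if (threshold <= reset)
    stop_param("threshold", "must exceed the reset potential")
  structure(as.list(environment()), class = "spiking_sim_config")
}

# Closed-form LIF spike times for a constant input current (noiseless).
# All potentials mV, conductances nS, capacitance pF, current pA; the
# membrane time constant C/g is then in ms.
lif_spike_times <- function(cfg, amplitude) {
  g_tot <- cfg$leak_conductance + cfg$katp_leak
  tau_s <- cfg$capacitance / g_tot / 1000
  i_hold <- cfg$leak_conductance * (cfg$holding_target - cfg$leak_reversal) +
    cfg$katp_leak * (cfg$holding_target - cfg$katp_reversal)
  v_inf <- (cfg$leak_conductance * cfg$leak_reversal +
              cfg$katp_leak * cfg$katp_reversal + i_hold + amplitude) / g_tot
  cross_time <- function(v0) {
    if (v_inf <= cfg$threshold) return(Inf)
    tau_s * log((v_inf - v0) / (v_inf - cfg$threshold))
  }
  spikes <- numeric(0)
  t <- cross_time(cfg$holding_target)
  while (t < cfg$pulse_duration) {
    spikes <- c(spikes, t)
    t <- t + cfg$refractory + cross_time(cfg$reset)
  }
  spikes
}

# Stereotyped spike waveform over the refractory window: linear rise from
# threshold to peak in 0.4 ms, linear fall back to reset.
render_spike <- function(u, cfg) {
  rise <- 4e-4
  ifelse(u < rise,
         cfg$threshold + (cfg$spike_peak - cfg$threshold) * u / rise,
         cfg$spike_peak + (cfg$reset - cfg$spike_peak) *
           (u - rise) / (cfg$refractory - rise))
}

#' Generate synthetic current-clamp sweeps with ground truth
#'
#' One voltage sweep per pulse amplitude. With `noise_sd = 0` the membrane
#' is integrated exactly (piecewise-exponential relaxation between spikes)
#' and `truth$spike_times` are the closed-form threshold crossings; with
#' noise the model is integrated by Euler-Maruyama steps at the sample rate.
#'
#' @param config a [spiking_sim_config()].
#' @return list with `recording` (a `cclamp_recording`) and `truth` (a
#'   [synthetic_truth()] whose `spike_times` is a per-amplitude list of
#'   spike times in seconds from pulse onset).
#' @export
simulate_current_clamp <- function(config) {
  stopifnot(inherits(config, "spiking_sim_config"))
  with_seed(config$seed, {
    fs <- config$sample_rate
    dt <- 1 / fs
    total <- config$pre_window + config$pulse_duration + config$post_window
    tt <- seq(0, total - dt / 2, by = dt)
    pulse_on <- config$pre_window
    pulse_off <- config$pre_window + config$pulse_duration
    g_tot <- config$leak_conductance + config$katp_leak
    tau_s <- config$capacitance / g_tot / 1000
    i_hold <- config$leak_conductance * (config$holding_target - config$leak_reversal) +
      config$katp_leak * (config$holding_target - config$katp_reversal)

    build_sweep <- function(amp) {
      if (config$noise_sd == 0) {
        spikes <- lif_spike_times(config, amp)
        v <- rep(config$holding_target, length(tt))
        v_inf <- (config$leak_conductance * config$leak_reversal +
                    config$katp_leak * config$katp_reversal + i_hold + amp) / g_tot
        # subthreshold relaxation segments between spikes
        seg_start <- pulse_on
        v0 <- config$holding_target
        for (b in spikes + pulse_on) {
          idx <- which(tt >= seg_start & tt < b)
          v[idx] <- v_inf + (v0 - v_inf) * exp(-(tt[idx] - seg_start) / tau_s)
          seg_start <- b + config$refractory
          v0 <- config$reset
        }
        idx <- which(tt >= seg_start & tt < pulse_off)
        v[idx] <- v_inf + (v0 - v_inf) * exp(-(tt[idx] - seg_start) / tau_s)
        # relaxation back to holding after the pulse
        v_end <- if (pulse_off > seg_start) {
          v_inf + (v0 - v_inf) * exp(-(pulse_off - seg_start) / tau_s)
        } else v0
        idx <- which(tt >= pulse_off)
        v[idx] <- config$holding_target +
          (v_end - config$holding_target) * exp(-(tt[idx] - pulse_off) / tau_s)
        # overlay stereotyped spike waveforms last so each spike keeps its
        # 0-mV crossing even when it straddles the pulse end
        for (b in spikes + pulse_on) {
          sp_idx <- which(tt >= b & tt < b + config$refractory)
          v[sp_idx] <- render_spike(tt[sp_idx] - b, config)
        }
        list(v = v, spikes = spikes)
      } else {
        v <- numeric(length(tt))
        v[1L] <- config$holding_target
        spikes <- numeric(0)
        refrac_until <- -Inf
        dt_ms <- dt * 1000
        noise <- rnorm(length(tt), 0, config$noise_sd)
        for (i in 2L:length(tt)) {
          t_now <- tt[i]
          if (t_now < refrac_until) {
            v[i] <- render_spike(t_now - (refrac_until - config$refractory), config)
            next
          }
          i_inj <- i_hold + if (t_now >= pulse_on && t_now < pulse_off) amp else 0
          vprev <- if (tt[i - 1L] < refrac_until) config$reset else v[i - 1L]
          dv <- (-config$leak_conductance * (vprev - config$leak_reversal) -
                   config$katp_leak * (vprev - config$katp_reversal) +
                   i_inj + noise[i]) / config$capacitance * dt_ms
          v[i] <- vprev + dv
          if (v[i] >= config$threshold && t_now >= pulse_on) {
            spikes <- c(spikes, t_now - pulse_on)
            refrac_until <- t_now + config$refractory
            v[i] <- render_spike(0, config)
          }
        }
        list(v = v, spikes = spikes[spikes < config$pulse_duration])
      }
    }

    out <- lapply(config$pulse_amplitudes, build_sweep)
    rec <- structure(
      list(sweeps = lapply(out, `[[`, "v"),
           amplitudes = config$pulse_amplitudes, sample_rate = fs,
           pulse_window = c(pulse_on, pulse_off), holding_current = i_hold,
           holding_target = config$holding_target, t = tt),
      class = "cclamp_recording")
    truth <- synthetic_truth(
      spike_times = setNames(lapply(out, `[[`, "spikes"),
                             paste0(config$pulse_amplitudes, "pA")),
      params = config)
    list(recording = rec, truth = truth)
  })
}

#' @export
print.cclamp_recording <- function(x, ...) {
  cat(sprintf("<cclamp_recording> %d sweeps (%s pA) @ %g Hz\n",
              length(x$sweeps), paste(x$amplitudes, collapse = ", "),
              x$sample_rate))
  invisible(x)
}
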