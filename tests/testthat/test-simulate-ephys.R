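test_that("noiseless ramp currents obey Ohm's law", {
  cfg <- membrane_sim_config(leak_conductance = 1, leak_reversal = 0,
                             katp_conductance_t0 = 0, katp_mode = "constant",
                             noise_sd = 0)
  sim <- simulate_ramp_recording(cfg, n_sweeps = 1)
  sw <- sim$recording$sweeps[[1L]]
  # with g = 1 nS and E = 0, I (pA) equals V (mV) at every ramp sample
  ramp <- sw$segment == "ramp"
  expect_equal(sw$current[ramp], sw$command[ramp], tolerance = 1e-12)
  k <- which(ramp)[which.min(abs(sw$command[ramp] + 100))]
  expect_equal(sw$current[k], -100, tolerance = 0.1)
  # holding at -70 mV with E = 0 draws -70 pA
  expect_equal(unique(sw$current[sw$segment == "hold"]), -70)
})

test_that("washdown truth decays exponentially and run-up/constant behave", {
  wd <- simulate_ramp_recording(
    membrane_sim_config(katp_conductance_t0 = 3, katp_tau = 60, noise_sd = 0),
    n_sweeps = 31, sweep_interval = 10)
  g0 <- wd$truth$conductance_fn(0)
  g300 <- wd$truth$conductance_fn(300)
  expect_gte(g0 - g300, 2.9)                       # 3 - 3 exp(-5) = 2.98
  expect_equal(g0 - g300, 3 - 3 * exp(-300 / 60), tolerance = 1e-12)

  cs <- simulate_ramp_recording(
    membrane_sim_config(katp_conductance_t0 = 2, katp_mode = "constant",
                        noise_sd = 0), n_sweeps = 5)
  g <- cs$truth$conductance_fn(cs$recording$time_from_breakin)
  expect_equal(g, rep(3, 5))                       # 1 leak + 2 constant katp

  ru <- membrane_sim_config(katp_conductance_t0 = 0,
                            katp_conductance_inf = 3, katp_tau = 120,
                            katp_mode = "runup", noise_sd = 0)
  gt <- simulate_ramp_recording(ru, n_sweeps = 20)$truth$conductance_fn
  expect_true(all(diff(gt(seq(0, 190, by = 10))) > 0))

  expect_error(simulate_ramp_recording(membrane_sim_config(), sweep_interval = 0),
               "sweep_interval")
  expect_error(membrane_sim_config(katp_tau = -1), "katp_tau")
  expect_error(membrane_sim_config(capacitance = 0), "capacitance")
})

test_that("line fits on noiseless sweeps recover the frozen truth conductance", {
  cfg <- membrane_sim_config(leak_conductance = 1.2, leak_reversal = -65,
                             katp_conductance_t0 = 2.5, katp_tau = 80,
                             noise_sd = 0)
  sim <- simulate_ramp_recording(cfg, n_sweeps = 12, sweep_interval = 10)
  fitted <- vapply(sim$recording$sweeps, slope_conductance, 0)
  truth <- sim$truth$conductance_fn(sim$recording$time_from_breakin)
  expect_equal(fitted, truth, tolerance = 1e-9)
  # and over a different voltage subrange (linear I-V, same slope)
  fitted2 <- vapply(sim$recording$sweeps, slope_conductance, 0,
                    fit_range = c(-110, -70))
  expect_equal(fitted2, truth, tolerance = 1e-9)
})

test_that("noiseless LIF sweeps match the closed-form inter-spike solution", {
  cfg <- spiking_sim_config(seed = 1)
  sim <- simulate_current_clamp(cfg)
  for (k in seq_along(cfg$pulse_amplitudes)) {
    oracle <- lif_oracle_times(cfg, cfg$pulse_amplitudes[k])
    expect_equal(sim$truth$spike_times[[k]], oracle, tolerance = 1e-9)
  }
  # zero / subthreshold input: no spikes, voltage pinned at holding
  quiet <- simulate_current_clamp(spiking_sim_config(pulse_amplitudes = 10))
  expect_length(quiet$truth$spike_times[[1L]], 0L)
  expect_lt(max(abs(quiet$recording$sweeps[[1L]] + 70)), 5)
  expect_lt(max(quiet$recording$sweeps[[1L]]), -40)
})

test_that("LIF spike count is monotone in drive and in added K-ATP leak", {
  counts <- vapply(seq_along(spiking_sim_config()$pulse_amplitudes),
                   function(k) length(simulate_current_clamp(
                     spiking_sim_config())$truth$spike_times[[k]]), 0L)
  expect_true(all(diff(counts) >= 0))
  set.seed(31)
  for (rep in 1:8) {
    g_leak <- runif(1, 2, 6)
    thr <- runif(1, -45, -38)
    base <- spiking_sim_config(leak_conductance = g_leak, threshold = thr)
    with_katp <- spiking_sim_config(leak_conductance = g_leak, threshold = thr,
                                    katp_leak = runif(1, 0.5, 3))
    n0 <- lengths(simulate_current_clamp(base)$truth$spike_times)
    n1 <- lengths(simulate_current_clamp(with_katp)$truth$spike_times)
    expect_true(all(n1 <= n0))
  }
})

test_that("spiking configuration is validated", {
  expect_error(spiking_sim_config(pulse_amplitudes = numeric(0)),
               "pulse_amplitudes")
  expect_error(spiking_sim_config(pulse_amplitudes = c(100, 50)),
               "pulse_amplitudes")
  expect_error(spiking_sim_config(threshold = -70, reset = -60), "threshold")
})

test_that("noisy LIF simulation remains seeded-deterministic and spikes render above 0 mV", {
  cfg <- spiking_sim_config(noise_sd = 20, seed = 77,
                            pulse_amplitudes = c(150))
  a <- simulate_current_clamp(cfg)
  b <- simulate_current_clamp(cfg)
  expect_identical(a$recording$sweeps[[1L]], b$recording$sweeps[[1L]])
  if (length(a$truth$spike_times[[1L]]) > 0)
    expect_gt(max(a$recording$sweeps[[1L]]), 0)
})
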