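test_that("detrending removes constants, slow ramps and preserves event peaks", {
  p <- quick_detection_params()
  flat <- fluor_trace(rep(0.3, 6000), 10, kind = "dff")
  expect_lt(max(abs(detrend_trace(flat, p)$values)), 1e-9)

  # linear drift 0 -> 0.2 over 30 min leaves residual well under 0.02
  ramp <- fluor_trace(seq(0, 0.2, length.out = 18000), 10, kind = "dff")
  expect_lt(max(abs(detrend_trace(ramp, p)$values)), 0.02)

  # a tall 10-s event on the same drift keeps its height within 10%
  n <- 18000
  tt <- (0:(n - 1)) / 10
  ev <- ifelse(tt >= 900 & tt < 910, 1.0, 0)
  drifty <- fluor_trace(seq(0, 0.2, length.out = n) + ev, 10, kind = "dff")
  clean <- fluor_trace(ev, 10, kind = "dff")
  h1 <- max(detrend_trace(drifty, p)$values)
  h0 <- max(detrend_trace(clean, p)$values)
  expect_lt(abs(h1 - h0) / h0, 0.1)

  expect_error(detrend_trace(fluor_trace(rnorm(100), 10, kind = "dff"), p),
               "window")
})

test_that("robust noise estimation is calibrated and event-insensitive", {
  set.seed(41)
  x <- rnorm(36000, 0, 0.01)
  est <- estimate_noise(fluor_trace(x, 10, kind = "dff"))
  expect_gt(est, 0.009)
  expect_lt(est, 0.011)

  expect_equal(estimate_noise(fluor_trace(rep(0, 100), 10, kind = "dff")), 0)

  # contaminate 10% of samples with large positive events
  y <- x
  idx <- seq_len(3600)
  y[idx] <- y[idx] + 0.5
  est2 <- estimate_noise(fluor_trace(y, 10, kind = "dff"))
  expect_lt(abs(est2 - est) / est, 0.15)

  expect_error(estimate_noise(fluor_trace(c(NA, NA), 10, kind = "dff")),
               "valid")
})

test_that("thresholding, gap merging and minimum duration follow the stated rules", {
  p <- quick_detection_params()
  fs <- 10
  quiet <- fluor_trace(rep(0, 3000), fs, kind = "dff")
  expect_equal(nrow(detect_events(quiet, p, threshold = 0.1)$intervals), 0L)

  # supra-threshold exactly on [100, 160) s
  tt <- (0:2999) / fs
  v <- ifelse(tt >= 100 & tt < 160, 1, 0)
  tr <- fluor_trace(v, fs, kind = "dff")
  iv <- detect_events(tr, p, threshold = 0.5)$intervals
  expect_equal(nrow(iv), 1L)
  expect_equal(unname(iv[1L, ]), c(100, 160))

  # two epochs separated by a 1-s gap merge under merge_gap_s = 2;
  # brute-force construction of the expected mask
  v2 <- ifelse((tt >= 50 & tt < 60) | (tt >= 61 & tt < 70), 1, 0)
  iv2 <- detect_events(fluor_trace(v2, fs, kind = "dff"), p,
                       threshold = 0.5)$intervals
  expect_equal(nrow(iv2), 1L)
  expect_equal(unname(iv2[1L, ]), c(50, 70))

  # a 3-s gap stays split
  v3 <- ifelse((tt >= 50 & tt < 60) | (tt >= 63 & tt < 70), 1, 0)
  expect_equal(nrow(detect_events(fluor_trace(v3, fs, kind = "dff"), p,
                                  threshold = 0.5)$intervals), 2L)

  # events shorter than min_event_s are discarded
  v4 <- ifelse(tt >= 50 & tt < 50.5, 1, 0)
  expect_equal(nrow(detect_events(fluor_trace(v4, fs, kind = "dff"), p,
                                  threshold = 0.5)$intervals), 0L)

  expect_error(detect_events(tr, p, threshold = NaN), "finite")
})

test_that("binned fractions and plateau percentages follow interval arithmetic", {
  p <- quick_detection_params()
  fs <- 10
  tt <- (0:11999) / fs
  quiet <- detect_events(fluor_trace(rep(0, 12000), fs, kind = "dff"), p,
                         threshold = 0.1)
  b0 <- time_in_sle(quiet, 1200, p)
  expect_true(all(b0$fraction == 0))
  expect_equal(b0$plateau_percent, 0)

  # one event covering exactly the second 300-s bin
  v <- ifelse(tt >= 300 & tt < 600, 1, 0)
  tr <- detect_events(fluor_trace(v, fs, kind = "dff"), p, threshold = 0.5)
  b1 <- time_in_sle(tr, 1200, p)
  expect_equal(b1$fraction, c(0, 1, 0, 0))

  # 600 s of events inside a 600-s plateau window -> plateau = 100 * 600/600;
  # interval-overlap oracle: here use events covering half the window
  v2 <- ifelse((tt >= 600 & tt < 750) | (tt >= 900 & tt < 1050), 1, 0)
  tr2 <- detect_events(fluor_trace(v2, fs, kind = "dff"), p, threshold = 0.5)
  b2 <- time_in_sle(tr2, 1200, p)
  expect_equal(b2$plateau_percent, 100 * 300 / 600)

  # duration shorter than the plateau end: computed over overlap + flagged
  p2 <- quick_detection_params(plateau_window = c(600, 2400))
  b3 <- time_in_sle(tr2, 1200, p2)
  expect_true(b3$plateau_truncated)
  expect_equal(b3$plateau_percent, 100 * 300 / 600)

  expect_error(time_in_sle(tr2, duration = 1000), "event end")
})

test_that("the slice pipeline emits a tidy per-region table and checks inputs", {
  p <- quick_detection_params()
  zeros <- lapply(c("DGH", "CA3", "CA1", "MEC", "LEC"), function(r)
    fluor_trace(rep(0, 12000), 10, kind = "dff", region = r))
  tab <- run_slice_pipeline(zeros, p)
  expect_equal(sort(unique(tab$region)), sort(c("DGH", "CA3", "CA1", "MEC", "LEC")))
  expect_true(all(tab$fraction == 0))
  expect_true(all(tab$plateau_percent == 0))

  # permuting trace order permutes rows only
  tab2 <- run_slice_pipeline(rev(zeros), p)
  o1 <- tab[order(tab$region, tab$bin_start), ]
  o2 <- tab2[order(tab2$region, tab2$bin_start), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)

  bad <- c(zeros[1:2], list(fluor_trace(rep(0, 600), 10, kind = "dff",
                                        region = "SHORT")))
  expect_error(run_slice_pipeline(bad, p), "SHORT")
})

test_that("synthetic slices are recovered with high interval overlap", {
  p <- quick_detection_params()
  for (seed in 1:5) {
    sim <- simulate_dff_trace(quick_calcium_cfg(seed))
    det <- detrend_trace(sim$trace, p)
    train <- detect_events(det, p)
    expect_gte(interval_jaccard(train$intervals, sim$truth$event_intervals),
               0.8)
  }
})

test_that("detection is scale-equivariant and conserves event time across bins", {
  p <- quick_detection_params()
  for (seed in 21:26) {
    sim <- simulate_dff_trace(quick_calcium_cfg(seed))
    det <- detrend_trace(sim$trace, p)
    train <- detect_events(det, p)
    for (c_scale in c(0.2, 5)) {
      scaled <- det
      scaled$values <- c_scale * det$values
      train_s <- detect_events(scaled, p)
      expect_equal(train_s$noise_sd, c_scale * train$noise_sd,
                   tolerance = 1e-12)
      expect_equal(train_s$threshold, c_scale * train$threshold,
                   tolerance = 1e-12)
      expect_equal(train_s$intervals, train$intervals)
    }
    binned <- time_in_sle(train, 1200, p)
    widths <- diff(binned$bin_edges)
    expect_equal(sum(binned$fraction * widths),
                 interval_total(train$intervals), tolerance = 1e-9)
  }
})

test_that("lowering the threshold multiplier never shrinks detections", {
  for (seed in 31:36) {
    sim <- simulate_dff_trace(quick_calcium_cfg(seed))
    det <- detrend_trace(sim$trace, quick_detection_params())
    hi <- detect_events(det, quick_detection_params(threshold_k = 5))
    lo <- detect_events(det, quick_detection_params(threshold_k = 3))
    n <- length(det$values)
    mask_hi <- epislice:::intervals_to_mask(hi$intervals, n, det$frame_rate)
    mask_lo <- epislice:::intervals_to_mask(lo$intervals, n, det$frame_rate)
    expect_true(all(mask_lo[mask_hi]))
  }
})
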