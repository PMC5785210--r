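#' Simulate a group of slices and quantify their seizure-like activity
#'
#' Generates one synthetic delta F/F trace per slice and region at the
#' given plateau occupancy, runs the full detection pipeline on each, and
#' returns per-slice/region plateau percentages alongside the ground-truth
#' values computed from the generating event intervals.
#'
#' @param n_slices number of slices in the group.
#' @param occupancy programmed plateau occupancy (fraction of plateau time
#'   in SLEs).
#' @param condition condition label attached to the traces.
#' @param regions character vector of region labels (one trace per region
#'   per slice).
#' @param params a [detection_params()].
#' @param seed integer seed for the whole group.
#' @param config_args extra arguments passed to [calcium_sim_config()].
#' @return data.frame with columns `condition`, `slice`, `region`,
#'   `plateau_percent` (pipeline estimate), `truth_plateau_percent`, plus a
#'   `bins` attribute (per-bin fractions, long format).
#' @export
simulate_slice_group <- function(n_slices, occupancy, condition = "WT",
                                 regions = "DGH",
                                 params = detection_params(), seed = NULL,
                                 config_args = list()) {
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                             n_slices * length(regions)),
                                  nrow = n_slices))
  pw <- params$plateau_window
  rows <- list()
  bins <- list()
  for (s in seq_len(n_slices)) {
    for (r in seq_along(regions)) {
      cfg <- do.call(calcium_sim_config,
                     c(list(plateau_occupancy = occupancy,
                            seed = seeds[s, r]), config_args))
      sim <- simulate_dff_trace(cfg, region = regions[r], condition = condition)
      det <- detrend_trace(sim$trace, params)
      train <- detect_events(det, params)
      binned <- time_in_sle(train, trace_duration(sim$trace), params)
      truth_pct <- 100 * interval_overlap(sim$truth$event_intervals,
                                          pw[1L], min(pw[2L], cfg$duration)) /
        (min(pw[2L], cfg$duration) - pw[1L])
      rows[[length(rows) + 1L]] <- data.frame(
        condition = condition, slice = s, region = regions[r],
        plateau_percent = binned$plateau_percent,
        truth_plateau_percent = truth_pct)
      nb <- length(binned$fraction)
      bins[[length(bins) + 1L]] <- data.frame(
        condition = condition, slice = s, region = regions[r],
        bin_start = binned$bin_edges[-(nb + 1L)], fraction = binned$fraction)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "bins") <- do.call(rbind, bins)
  out
}

#' Run the full synthetic two-genotype demonstration experiment
#'
#' End-to-end wild-type versus knockout comparison: the knockout group is
#' programmed with a `reduction` (default 50%) relative drop in plateau
#' occupancy. The imaging arm simulates slices, detects SLEs and compares
#' plateau percentages per region (Student's t test for two groups); the
#' electrophysiology arm produces a normalized washdown time course
#' (high-conductance washdown versus constant-conductance cell) and F-I
#' curves with and without an added K-ATP leak.
#'
#' @param seed integer seed controlling all randomness.
#' @param n_per_group slices per genotype.
#' @param reduction programmed relative reduction of plateau occupancy in
#'   the knockout group (0-1).
#' @param occupancy_wt wild-type plateau occupancy.
#' @param regions regions analyzed per slice.
#' @param params a [detection_params()].
#' @return list with `slices` (per-slice table), `tests` (per-region
#'   `test_result`), `estimated_reduction_percent` (per region, from group
#'   means), `washdown` (two `conductance_timecourse`s), `fi` (two
#'   [fi_curve()]s), `summary` (a [summarize_groups()] table per region)
#'   and `config` (the run parameters).
#' @export
run_demo_experiment <- function(seed = 1, n_per_group = 8, reduction = 0.5,
                                occupancy_wt = 0.4,
                                regions = c("DGH", "CA3", "CA1", "MEC", "LEC"),
                                params = detection_params()) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 6L))
  wt <- simulate_slice_group(n_per_group, occupancy_wt, "WT", regions,
                             params, seed = seeds[1L])
  ko <- simulate_slice_group(n_per_group, occupancy_wt * (1 - reduction),
                             "KO", regions, params, seed = seeds[2L])
  slices <- rbind(wt, ko)
  attr(slices, "bins") <- rbind(attr(wt, "bins"), attr(ko, "bins"))

  tests <- list()
  red <- numeric(0)
  summaries <- list()
  for (r in regions) {
    a <- slices$plateau_percent[slices$condition == "WT" & slices$region == r]
    b <- slices$plateau_percent[slices$condition == "KO" & slices$region == r]
    tests[[r]] <- two_tailed_t(a, b)
    red[r] <- 100 * (1 - mean(b) / mean(a))
    summaries[[r]] <- summarize_groups(list(WT = a, KO = b))
  }

  wash_high <- simulate_ramp_recording(
    membrane_sim_config(katp_conductance_t0 = 3, katp_tau = 60,
                        katp_mode = "washdown", noise_sd = 2,
                        seed = seeds[3L]), n_sweeps = 60)
  wash_none <- simulate_ramp_recording(
    membrane_sim_config(katp_conductance_t0 = 0, katp_mode = "constant",
                        noise_sd = 2, seed = seeds[4L]), n_sweeps = 60)
  washdown <- list(washdown = washdown_timecourse(wash_high$recording),
                   constant = washdown_timecourse(wash_none$recording))

  fi_ctrl <- simulate_current_clamp(spiking_sim_config(seed = seeds[5L]))
  fi_katp <- simulate_current_clamp(spiking_sim_config(katp_leak = 1.5,
                                                       seed = seeds[6L]))
  fi <- list(control = fi_curve(fi_ctrl$recording),
             katp_leak = fi_curve(fi_katp$recording))

  list(slices = slices, tests = tests,
       estimated_reduction_percent = red,
       summary = summaries, washdown = washdown, fi = fi,
       config = list(seed = seed, n_per_group = n_per_group,
                     reduction = reduction, occupancy_wt = occupancy_wt,
                     regions = regions, params = unclass(params)))
}

#' Power of the two-genotype comparison by repeated simulation
#'
#' Replicates the imaging arm of the demonstration experiment and reports
#' the rejection rate of the two-group comparison at `alpha` together with
#' the mean estimated relative reduction.
#'
#' @param n_reps number of replicate experiments.
#' @param n_per_group slices per genotype.
#' @param reduction programmed relative occupancy reduction.
#' @param occupancy_wt wild-type plateau occupancy.
#' @param alpha significance level.
#' @param seed integer seed.
#' @param region single region label used for the per-slice readout.
#' @param params a [detection_params()].
#' @return list with `power`, `mean_reduction_percent`, and `replicates`
#'   (data.frame `p_value`, `reduction_percent`).
#' @export
demo_power <- function(n_reps = 120, n_per_group = 8, reduction = 0.5,
                       occupancy_wt = 0.4, alpha = 0.05, seed = 1,
                       region = "DGH", params = detection_params()) {
  rep_seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                                 2L * n_reps), ncol = 2L))
  res <- lapply(seq_len(n_reps), function(k) {
    wt <- simulate_slice_group(n_per_group, occupancy_wt, "WT", region,
                               params, seed = rep_seeds[k, 1L])
    ko <- simulate_slice_group(n_per_group, occupancy_wt * (1 - reduction),
                               "KO", region, params, seed = rep_seeds[k, 2L])
    p <- two_tailed_t(wt$plateau_percent, ko$plateau_percent)$p_value
    data.frame(p_value = p,
               reduction_percent = 100 * (1 - mean(ko$plateau_percent) /
                                            mean(wt$plateau_percent)))
  })
  res <- do.call(rbind, res)
  list(power = mean(res$p_value < alpha),
       mean_reduction_percent = mean(res$reduction_percent),
       replicates = res)
}

#' Write the demonstration figures
#'
#' Base-graphics PNG figures: normalized washdown time courses, F-I curves
#' with and without K-ATP leak, and mean fraction of time in SLEs per 5-min
#' bin by genotype.
#'
#' @param demo result of [run_demo_experiment()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_demo_figures <- function(demo, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  p <- file.path(outdir, "washdown_timecourse.png")
  png(p, width = 800, height = 500)
  wd <- demo$washdown
  plot(wd$washdown$time / 60, wd$washdown$normalized, type = "b", pch = 16,
       col = "forestgreen", xlab = "Time after break-in (min)",
       ylab = "Normalized slope conductance",
       ylim = range(c(wd$washdown$normalized, wd$constant$normalized)))
  lines(wd$constant$time / 60, wd$constant$normalized, type = "b", pch = 1,
        col = "grey30")
  abline(v = 3, lty = 3)
  legend("topright", c("washdown", "constant"), col = c("forestgreen", "grey30"),
         pch = c(16, 1))
  dev.off()
  paths <- c(paths, p)

  p <- file.path(outdir, "fi_curves.png")
  png(p, width = 600, height = 500)
  fi <- demo$fi
  plot(fi$control$amplitude, fi$control$ap_count, type = "b", pch = 16,
       xlab = "Injected current (pA)", ylab = "Action potentials / pulse",
       ylim = range(c(fi$control$ap_count, fi$katp_leak$ap_count)))
  lines(fi$katp_leak$amplitude, fi$katp_leak$ap_count, type = "b", pch = 1,
        col = "firebrick")
  legend("topleft", c("control", "+K-ATP leak"), col = c("black", "firebrick"),
         pch = c(16, 1))
  dev.off()
  paths <- c(paths, p)

  p <- file.path(outdir, "fraction_in_sle.png")
  png(p, width = 800, height = 500)
  bins <- attr(demo$slices, "bins")
  agg <- aggregate(fraction ~ condition + bin_start, data = bins, FUN = mean)
  wt <- agg[agg$condition == "WT", ]
  ko <- agg[agg$condition == "KO", ]
  plot(wt$bin_start / 60, wt$fraction, type = "b", pch = 16,
       xlab = "Time (min, 5-min bins)", ylab = "Fraction of time in SLEs",
       ylim = c(0, max(agg$fraction)))
  lines(ko$bin_start / 60, ko$fraction, type = "b", pch = 1, col = "forestgreen")
  legend("topleft", c("WT", "KO"), col = c("black", "forestgreen"), pch = c(16, 1))
  dev.off()
  paths <- c(paths, p)

  invisible(paths)
}
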