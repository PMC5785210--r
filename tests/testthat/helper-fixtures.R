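# Shared fixture builders: all synthetic, constructed in code at test time.

# A short calcium config for property-style tests: 20-min recording with an
# early drug onset and a compressed rise so events appear quickly.
quick_calcium_cfg <- function(seed, ...) {
  defaults <- list(duration = 1200, drug_onset = 100,
                   latency_to_first_sle = 20, rise_midpoint = 250,
                   rise_scale = 60, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(calcium_sim_config, args)
}

quick_detection_params <- function(...) {
  defaults <- list(plateau_window = c(600, 1200))
  do.call(detection_params, utils::modifyList(defaults, list(...)))
}

# Independent closed-form LIF oracle: spike (threshold-crossing) times for a
# constant current step, from the exponential membrane relaxation solution.
lif_oracle_times <- function(cfg, amplitude) {
  g <- cfg$leak_conductance + cfg$katp_leak
  tau <- cfg$capacitance / g / 1000                       # seconds
  i_hold <- cfg$leak_conductance * (cfg$holding_target - cfg$leak_reversal) +
    cfg$katp_leak * (cfg$holding_target - cfg$katp_reversal)
  v_inf <- (cfg$leak_conductance * cfg$leak_reversal +
              cfg$katp_leak * cfg$katp_reversal + i_hold + amplitude) / g
  if (v_inf <= cfg$threshold) return(numeric(0))
  first <- tau * log((v_inf - cfg$holding_target) / (v_inf - cfg$threshold))
  isi <- cfg$refractory + tau * log((v_inf - cfg$reset) / (v_inf - cfg$threshold))
  times <- first + (0:5000) * isi
  times[times < cfg$pulse_duration]
}

# Number of rendered spikes whose 0-mV upward crossing falls inside the
# half-open pulse window: the crossing happens on the stereotyped rise,
# 0.4 ms * (0 - threshold)/(peak - threshold) after the threshold crossing.
lif_oracle_count_zero_crossing <- function(cfg, amplitude) {
  times <- lif_oracle_times(cfg, amplitude)
  delta0 <- 4e-4 * (0 - cfg$threshold) / (cfg$spike_peak - cfg$threshold)
  sum(times + delta0 < cfg$pulse_duration)
}

# ImageJ .roi binary fixture, built directly from the published byte layout
# (big-endian: "Iout" magic, version, type at offset 6, bounds at 8..15,
# n at 16, coordinates relative to (left, top) from offset 64).
make_imagej_roi_bytes <- function(type, top, left, bottom, right,
                                  xs = integer(0), ys = integer(0)) {
  be_short <- function(v) {
    v <- as.integer(v)
    as.raw(c(bitwAnd(bitwShiftR(v, 8L), 255L), bitwAnd(v, 255L)))
  }
  head <- c(charToRaw("Iout"), be_short(227), as.raw(c(type, 0)),
            be_short(top), be_short(left), be_short(bottom), be_short(right),
            be_short(length(xs)))
  pad <- as.raw(rep(0L, 64 - length(head)))
  coords <- as.raw(unlist(lapply(c(xs - left, ys - top), be_short)))
  c(head, pad, coords)
}

# CRC-32 (polynomial 0xEDB88320), computed on doubles to dodge R's signed
# 32-bit integers; only used to build tiny stored-method zip fixtures.
crc32 <- function(bytes) {
  crc <- 4294967295
  for (b in as.integer(bytes)) {
    crc <- bitwXor_dbl(crc, b, low = TRUE)
    for (k in 1:8) {
      odd <- crc %% 2
      crc <- floor(crc / 2)
      if (odd == 1) crc <- bitwXor_dbl(crc, 3988292384)
    }
  }
  bitwXor_dbl(crc, 4294967295)
}

# xor of two non-negative doubles < 2^32 (low = TRUE xors only the low byte)
bitwXor_dbl <- function(a, b, low = FALSE) {
  if (low) {
    lowa <- a %% 256
    return(a - lowa + bitwXor(as.integer(lowa), as.integer(b)))
  }
  out <- 0
  bit <- 1
  for (k in 1:32) {
    abit <- a %% 2
    bbit <- b %% 2
    if (abit != bbit) out <- out + bit
    a <- floor(a / 2)
    b <- floor(b / 2)
    bit <- bit * 2
  }
  out
}

# Minimal ZIP archive (store method, no compression) holding named raw
# entries; enough structure for unzip() to extract the members.
make_store_zip <- function(path, entries) {
  le <- function(v, n) {
    out <- raw(n)
    for (i in seq_len(n)) {
      out[i] <- as.raw(v %% 256)
      v <- floor(v / 256)
    }
    out
  }
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  central <- raw(0)
  pos <- 0
  for (nm in names(entries)) {
    data <- entries[[nm]]
    crc <- crc32(data)
    name <- charToRaw(nm)
    local_hdr <- c(le(67324752, 4), le(20, 2), le(0, 2), le(0, 2),
                   le(0, 2), le(0, 2), le(crc, 4), le(length(data), 4),
                   le(length(data), 4), le(length(name), 2), le(0, 2),
                   name)
    writeBin(c(local_hdr, data), con)
    central <- c(central,
                 le(33639248, 4), le(20, 2), le(20, 2), le(0, 2), le(0, 2),
                 le(0, 2), le(0, 2), le(crc, 4), le(length(data), 4),
                 le(length(data), 4), le(length(name), 2), le(0, 2),
                 le(0, 2), le(0, 2), le(0, 2), le(0, 4), le(pos, 4), name)
    pos <- pos + length(local_hdr) + length(data)
  }
  writeBin(central, con)
  writeBin(c(le(101010256, 4), le(0, 2), le(0, 2),
             le(length(entries), 2), le(length(entries), 2),
             le(length(central), 4), le(pos, 4), le(0, 2)), con)
  invisible(path)
}
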