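# Shared fixtures: everything is generated in code at test time.

default_instr <- instrument_spec()

# A photon stream with prescribed total counts per consecutive bin
# (channels/microtimes cycled deterministically), for burst-search checks.
stream_from_bin_counts <- function(bin_counts, bin_width = 5e-4,
                                   instrument = default_instr) {
  ticks_per_bin <- bin_width * instrument$clock_rate_hz
  ticks <- unlist(lapply(seq_along(bin_counts), function(k) {
    n <- bin_counts[k]
    if (n == 0) return(numeric(0))
    (k - 1) * ticks_per_bin + round(seq(0, ticks_per_bin - 1,
                                        length.out = n))
  }), use.names = FALSE)
  n <- length(ticks)
  channel <- rep_len(c("D", "A"), n)
  micro <- rep_len(c(30, 40, 10), n) # both PIE windows represented
  photon_stream(ticks, channel, micro,
                clock_rate_hz = instrument$clock_rate_hz, sort = TRUE)
}

# Counts-level single-species burst table plus its fret points.
sim_species_points <- function(E, n = 5000, seed = 1,
                               instrument = default_instr,
                               labeled_state = "double",
                               brightness = 80) {
  corr <- correction_set_from_instrument(instrument)
  sp <- species_spec("x", E, brightness_D_ex = brightness,
                     brightness_A_ex = brightness,
                     labeled_state = labeled_state)
  cnt <- withr::with_seed(seed,
    fretburst:::simulate_burst_counts(list(sp), rep(1L, n), instrument))
  fret_points(cnt, corr)
}

# Exhaustive reference burst search: loops over every bin and photon.
brute_force_bursts <- function(stream, params, instrument) {
  t <- stream$ticks / attr(stream, "clock_rate_hz")
  if (!length(t)) return(NULL)
  w <- params$bin_width
  nbins <- floor(max(t) / w) + 1
  counts <- integer(nbins)
  for (i in seq_along(t)) {
    b <- floor(t[i] / w) + 1
    counts[b] <- counts[b] + 1L
  }
  hot <- counts >= params$threshold
  bursts <- list()
  k <- 1
  while (k <= nbins) {
    if (hot[k]) {
      j <- k
      while (j < nbins && hot[j + 1]) j <- j + 1
      cls <- c(DD = 0L, DA = 0L, AA = 0L, AD = 0L)
      for (i in seq_along(t)) {
        b <- floor(t[i] / w) + 1
        if (b >= k && b <= j) {
          win <- if (stream$microtime_ns[i] >= instrument$microtime_split)
            "D_ex" else "A_ex"
          key <- if (stream$channel[i] == "D" && win == "D_ex") "DD"
          else if (stream$channel[i] == "A" && win == "D_ex") "DA"
          else if (stream$channel[i] == "A") "AA" else "AD"
          cls[key] <- cls[key] + 1L
        }
      }
      bursts[[length(bursts) + 1]] <- data.frame(
        start = (k - 1) * w, stop = j * w, duration = (j - k + 1) * w,
        n_DD = cls[["DD"]], n_DA = cls[["DA"]], n_AA = cls[["AA"]],
        n_AD = cls[["AD"]], n_total = sum(cls))
      k <- j + 1
    } else k <- k + 1
  }
  if (!length(bursts)) return(NULL)
  do.call(rbind, bursts)
}
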