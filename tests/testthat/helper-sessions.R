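# Shared fixtures: all built in code at test time.

clean_session <- function(seed = 1, offset = 1, noise = TRUE, ...) {
  simulate_session(sim_config(
    seed = seed, true_offset_s = offset,
    noise_sd_mm = if (noise) 1 else 0,
    noise_sd_px = if (noise) 0.5 else 0, ...))
}

estimate_offset <- function(ses, params = nod_params()) {
  sync_nod(ses$mocap, ses$gaze, params = params)$offset_s
}

# analytic raised-cosine dip in a position channel (no noise)
dip_series <- function(rate_hz = 200, dur_s = 8, apex_s = 4, depth = 80,
                       width_s = 0.4, baseline = 1000) {
  t <- seq(0, dur_s - 1 / rate_hz, by = 1 / rate_hz)
  u <- t - apex_s
  w <- ifelse(abs(u) <= width_s / 2, 0.5 * (1 + cos(2 * pi * u / width_s)), 0)
  sampled_series(baseline - depth * w, rate_hz, units = "mm")
}

# independent oracle for the sync-point rule: exhaustive scan implementing
# "first (or last) strict local minimum below the threshold, then the first
# frame n at or after it with v[n] < 0 and v[n+1] >= 0" with explicit loops.
oracle_sync_frame <- function(v, threshold, reverse = FALSE) {
  n <- length(v)
  mins <- integer(0)
  for (i in 2:(n - 1)) {
    # plateau rule: first frame of a minimal plateau
    j <- i
    while (j < n && v[j + 1] == v[i]) j <- j + 1
    prev_ok <- v[i - 1] > v[i]
    next_ok <- j < n && v[j + 1] > v[i]
    if (prev_ok && next_ok && v[i] < threshold) {
      mins <- c(mins, i)
    }
  }
  if (!length(mins)) return(NA_integer_)
  m <- if (reverse) mins[length(mins)] else mins[1]
  for (k in m:(n - 1)) {
    if (v[k] < 0 && v[k + 1] >= 0) return(k - 1L)  # 0-based frame
  }
  NA_integer_
}

# writes a small mocap TSV fixture, returns the path
write_mocap_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
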