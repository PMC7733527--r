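#' Simulation configuration for a two-stream session
#'
#' Describes a recording session as the supported protocol produces it: the
#' mocap system starts first at `t = 0` on the world clock; the eye tracker
#' starts `true_offset_s` later (about a second in practice). The participant
#' performs one sharp nod shortly after both devices are running, and
#' optionally a second nod near the end of the session. The nod appears as a
#' smooth raised-cosine dip in the vertical head-marker coordinate (mm) and in
#' the vertical pupil image coordinate (px), synchronous on the world clock.
#'
#' @param mocap_rate_hz Mocap sampling rate (default 200).
#' @param eye_rate_hz Nominal eye-tracker rate (default 50).
#' @param session_s Total mocap recording duration in seconds (default 10).
#' @param true_offset_s Eye-tracker start delay (default 1.0).
#' @param nod_time_s World-clock time of the start-nod apex (default 3.5,
#'   leaving room for the prefix-zeroing windows at any offset up to 2 s).
#' @param end_nod_time_s Optional world-clock time of an end-nod apex.
#' @param nod_depth_mm Head-marker dip amplitude (default 80 mm — a chin-to-
#'   chest-halfway nod moves a front head marker by several centimetres).
#' @param nod_duration_s Dip width (default 0.4 s, a brisk single nod).
#' @param pupil_dip_px Pupil-coordinate dip amplitude (default 60 px).
#' @param noise_sd_mm,noise_sd_px Additive white-noise sd per channel
#'   (defaults 1 mm, 0.5 px).
#' @param blinks Optional list of `c(time_s, duration_s)` pairs (eye-stream
#'   clock) marked as invalid frames.
#' @param clock_skew_ppm Eye-clock rate error in parts per million. Positive
#'   skew means the eye tracker's clock runs fast: it counts one nominal
#'   frame period while slightly more world time passes, i.e. it actually
#'   samples at `eye_rate_hz / (1 + ppm * 1e-6)` while timestamps assume the
#'   nominal rate, so eye recordings of a fixed world interval appear
#'   shorter — the drift signature seen in long sessions.
#' @param baseline_mm,baseline_px Resting levels of the two channels.
#' @param seed Random seed; identical configurations give identical sessions.
#' @return A `nodsync_sim_config`.
#' @export
sim_config <- function(mocap_rate_hz = 200, eye_rate_hz = 50, session_s = 10,
                       true_offset_s = 1.0, nod_time_s = 3.5,
                       end_nod_time_s = NULL, nod_depth_mm = 80,
                       nod_duration_s = 0.4, pupil_dip_px = 60,
                       noise_sd_mm = 1, noise_sd_px = 0.5, blinks = NULL,
                       clock_skew_ppm = 0, baseline_mm = 1500,
                       baseline_px = 300, seed = 1) {
  if (mocap_rate_hz <= 0 || eye_rate_hz <= 0) {
    abort_nodsync("sampling rates must be positive", "nodsync_config_error")
  }
  if (session_s <= 0 || true_offset_s < 0 ||
      true_offset_s >= session_s) {
    abort_nodsync("offset must be >= 0 and inside the session",
                  "nodsync_config_error")
  }
  if (nod_duration_s <= 4 / eye_rate_hz) {
    abort_nodsync("nod must span more than 4 eye-tracker frames",
                  "nodsync_config_error")
  }
  half <- nod_duration_s / 2
  if (nod_time_s - half <= true_offset_s || nod_time_s + half >= session_s) {
    abort_nodsync("start nod must lie inside both streams",
                  "nodsync_config_error")
  }
  if (!is.null(end_nod_time_s) &&
      (end_nod_time_s - half <= nod_time_s + half ||
       end_nod_time_s + half >= session_s)) {
    abort_nodsync("end nod must follow the start nod and end before the session does",
                  "nodsync_config_error")
  }
  structure(list(mocap_rate_hz = mocap_rate_hz, eye_rate_hz = eye_rate_hz,
                 session_s = session_s, true_offset_s = true_offset_s,
                 nod_time_s = nod_time_s, end_nod_time_s = end_nod_time_s,
                 nod_depth_mm = nod_depth_mm, nod_duration_s = nod_duration_s,
                 pupil_dip_px = pupil_dip_px, noise_sd_mm = noise_sd_mm,
                 noise_sd_px = noise_sd_px, blinks = blinks,
                 clock_skew_ppm = clock_skew_ppm, baseline_mm = baseline_mm,
                 baseline_px = baseline_px, seed = seed),
            class = "nodsync_sim_config")
}

# smooth unimodal dip: 1 at u = 0, 0 outside |u| > dur/2
raised_cosine <- function(u, dur) {
  w <- ifelse(abs(u) <= dur / 2, 0.5 * (1 + cos(2 * pi * u / dur)), 0)
  w
}

#' Simulate a two-stream recording session with known ground truth
#'
#' Generates the vertical head-marker trajectory (plus flat x/y channels and a
#' second head marker, so multi-marker IO is exercised) on the mocap clock,
#' and the pupil trace on the eye-tracker clock, which starts
#' `true_offset_s` later and may run at a skewed rate. Blinks configured in
#' `cfg` are injected as invalid gaze frames. The returned truth object holds
#' the apex frames each device would ideally report.
#'
#' @param cfg A [sim_config()].
#' @return A list `mocap` ([mocap_recording()]), `gaze`
#'   ([gaze_recording()]), `truth` (`nodsync_sim_truth`: `true_offset_s`,
#'   `apex_frame_mocap`, `apex_frame_eye`, `end_apex_frame_mocap`,
#'   `end_apex_frame_eye`, `eye_rate_actual_hz`).
#' @export
simulate_session <- function(cfg) {
  if (!inherits(cfg, "nodsync_sim_config")) {
    abort_nodsync("cfg must be a sim_config()", "nodsync_config_error")
  }
  set.seed(cfg$seed)
  dip <- function(t) {
    w <- raised_cosine(t - cfg$nod_time_s, cfg$nod_duration_s)
    if (!is.null(cfg$end_nod_time_s)) {
      w <- w + raised_cosine(t - cfg$end_nod_time_s, cfg$nod_duration_s)
    }
    w
  }

  n_m <- as.integer(round(cfg$session_s * cfg$mocap_rate_hz))
  t_m <- (seq_len(n_m) - 1L) / cfg$mocap_rate_hz
  z <- cfg$baseline_mm - cfg$nod_depth_mm * dip(t_m) +
    stats::rnorm(n_m, 0, cfg$noise_sd_mm)
  mk <- function(zvals) list(
    x = sampled_series(stats::rnorm(n_m, 100, cfg$noise_sd_mm), cfg$mocap_rate_hz,
                       units = "mm"),
    y = sampled_series(stats::rnorm(n_m, 250, cfg$noise_sd_mm), cfg$mocap_rate_hz,
                       units = "mm"),
    z = sampled_series(zvals, cfg$mocap_rate_hz, units = "mm"))
  z2 <- cfg$baseline_mm - cfg$nod_depth_mm * dip(t_m) +
    stats::rnorm(n_m, 0, cfg$noise_sd_mm)
  mocap <- mocap_recording(
    list(head_front_left = mk(z), head_front_right = mk(z2)),
    cfg$mocap_rate_hz)

  r_eye <- cfg$eye_rate_hz / (1 + cfg$clock_skew_ppm * 1e-6)
  n_e <- as.integer(floor((cfg$session_s - cfg$true_offset_s) * r_eye))
  t_world_e <- cfg$true_offset_s + (seq_len(n_e) - 1L) / r_eye
  py <- cfg$baseline_px - cfg$pupil_dip_px * dip(t_world_e) +
    stats::rnorm(n_e, 0, cfg$noise_sd_px)
  px <- stats::rnorm(n_e, 320, cfg$noise_sd_px)
  gaze <- gaze_recording(px, py, rep(TRUE, n_e), cfg$eye_rate_hz)
  if (!is.null(cfg$blinks)) {
    for (b in cfg$blinks) gaze <- inject_blink(gaze, b[1], b[2])
  }

  apex_e <- function(world_t) as.integer(round((world_t - cfg$true_offset_s) * r_eye))
  truth <- structure(list(
    true_offset_s = cfg$true_offset_s,
    apex_frame_mocap = as.integer(round(cfg$nod_time_s * cfg$mocap_rate_hz)),
    apex_frame_eye = apex_e(cfg$nod_time_s),
    end_apex_frame_mocap = if (is.null(cfg$end_nod_time_s)) NULL else
      as.integer(round(cfg$end_nod_time_s * cfg$mocap_rate_hz)),
    end_apex_frame_eye = if (is.null(cfg$end_nod_time_s)) NULL else
      apex_e(cfg$end_nod_time_s),
    eye_rate_actual_hz = r_eye
  ), class = "nodsync_sim_truth")

  list(mocap = mocap, gaze = gaze, truth = truth)
}

#' Mark a blink window as invalid gaze frames
#'
#' Emulates the main field failure mode: the participant blinking near (or
#' during) the nod, which removes pupil samples exactly where the detector
#' needs them.
#'
#' @param gaze A [gaze_recording()].
#' @param time_s Blink onset on the eye-stream clock.
#' @param duration_s Blink duration; frames in `[time_s, time_s + duration_s)`
#'   are invalidated. Zero duration is a no-op.
#' @return The modified recording.
#' @export
inject_blink <- function(gaze, time_s, duration_s) {
  stopifnot(inherits(gaze, "nodsync_gaze"))
  n <- n_frames(gaze$pupil_y)
  dur_total <- n / gaze$rate_hz
  if (duration_s < 0 || time_s < 0 || time_s + duration_s > dur_total) {
    abort_nodsync("blink window lies outside the gaze stream",
                  "nodsync_precondition_error")
  }
  if (duration_s == 0) return(gaze)
  t <- (seq_len(n) - 1L) / gaze$rate_hz
  hit <- t >= time_s & t < time_s + duration_s
  gaze_recording(gaze$pupil_x$values, gaze$pupil_y$values,
                 gaze$valid & !hit, gaze$rate_hz, gaze$meta)
}
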