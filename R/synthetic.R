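# Synthetic head-gesture generator. Emulates the statistical structure of
# IMU head-gesture acquisition: seven stylized trajectory shapes on the
# semi-hemispherical head motion range, per-subject style variation
# (amplitude, speed, tilt), smooth angular noise, and jittered sampling
# intervals. Directional pairs (clockwise/counterclockwise, left/right,
# m-left/m-right) trace identical point sets in opposite temporal order,
# so they are separable only by classifiers that use temporal information.

#' The seven built-in gesture classes
#' @export
gesture_classes <- function() {
  c("clockwise", "counterclockwise", "left", "right", "nod", "m_left", "m_right")
}

#' Synthetic dataset configuration
#'
#' @param subjects Number of subjects (default 12).
#' @param reps_per_class Recordings per subject and class (default 10).
#' @param classes Gesture classes to generate (default all seven).
#' @param noise_angle_deg Stationary sd of the smooth per-sample angular
#'   noise, in degrees (default 2).
#' @param amplitude_range Per-subject multiplicative range for gesture
#'   extent (default 0.75–1.25).
#' @param speed_range Per-subject duration multiplier range (default
#'   0.8–1.25).
#' @param tilt_sd_deg Sd of the per-subject in-plane tilt of the gesture
#'   shape, degrees (default 4).
#' @param dt_mean_ms,dt_sd_ms Sampling-interval model: normal with this
#'   mean and sd, floored at 1 ms (defaults 22.06 and 5.83).
#' @param length_bounds Min/max recording length in samples (default
#'   c(50, 530)); generated lengths are clamped into this range.
#' @param seed Integer seed; all randomness flows through it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(subjects = 12L, reps_per_class = 10L,
                             classes = gesture_classes(),
                             noise_angle_deg = 2,
                             amplitude_range = c(0.75, 1.25),
                             speed_range = c(0.8, 1.25),
                             tilt_sd_deg = 4,
                             dt_mean_ms = 22.06, dt_sd_ms = 5.83,
                             length_bounds = c(50L, 530L),
                             seed = 1L) {
  stopifnot(subjects >= 1, reps_per_class >= 1, length(classes) >= 1,
            noise_angle_deg >= 0, all(amplitude_range > 0),
            all(speed_range > 0), tilt_sd_deg >= 0,
            dt_mean_ms > 0, dt_sd_ms >= 0,
            length(length_bounds) == 2, length_bounds[1] >= 2,
            length_bounds[1] <= length_bounds[2])
  structure(list(subjects = as.integer(subjects),
                 reps_per_class = as.integer(reps_per_class),
                 classes = classes,
                 noise_angle_deg = noise_angle_deg,
                 amplitude_range = amplitude_range,
                 speed_range = speed_range,
                 tilt_sd_deg = tilt_sd_deg,
                 dt_mean_ms = dt_mean_ms, dt_sd_ms = dt_sd_ms,
                 length_bounds = as.integer(length_bounds),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# --- idealized shapes -------------------------------------------------------
# Each shape maps t in [0, 1] to (yaw, pitch) in degrees, starts and ends at
# (0, 0), and is parametrized at (piecewise-)constant angular speed so the
# inter-sample velocity of a generated gesture never dips to zero mid-motion.

.polyline_shape <- function(waypoints) {
  d <- sqrt(rowSums(diff(waypoints)^2))
  s <- c(0, cumsum(d)) / sum(d)
  function(t) cbind(yaw = approx(s, waypoints[, 1L], xout = t)$y,
                    pitch = approx(s, waypoints[, 2L], xout = t)$y)
}

.shape_bank <- local({
  circle <- function(t) cbind(yaw = 25 * sin(2 * pi * t),
                              pitch = -25 + 25 * cos(2 * pi * t))
  left <- .polyline_shape(cbind(c(0, -60, 0, 60, 0), c(0, 0, 0, 0, 0)))
  m_left <- .polyline_shape(cbind(c(0, -15, -30, -45, -60, 0),
                                  c(0, 25, 0, 25, 0, 0)))
  list(
    clockwise = circle,
    counterclockwise = function(t) circle(1 - t),
    left = left,
    right = function(t) left(1 - t),
    nod = .polyline_shape(cbind(c(0, 0, 0), c(0, -40, 0))),
    m_left = m_left,
    m_right = function(t) m_left(1 - t)
  )
})

# Nominal gesture durations in seconds (before style multipliers); quick for
# the nod, longer for the wide sweeps, chosen so angular velocity stays in
# the 1.5-2.5 degrees/sample band at ~45 Hz.
.shape_durations <- c(clockwise = 1.8, counterclockwise = 1.8,
                      left = 2.2, right = 2.2, nod = 1.2,
                      m_left = 2.2, m_right = 2.2)

#' Idealized gesture shape curve
#'
#' @param class One of [gesture_classes()].
#' @param t Vector of curve parameters in `[0, 1]`.
#' @return A matrix with columns `yaw` and `pitch` in degrees.
#' @export
gesture_shape <- function(class, t) {
  f <- .shape_bank[[match.arg(class, gesture_classes())]]
  f(t)
}

#' Zero-roll quaternion for a yaw/pitch head direction
#'
#' Returns the unit quaternion (yaw about the vertical axis composed with
#' pitch about the lateral axis, no roll) whose head-direction image
#' ([quat_to_direction()]) is
#' `[sin(yaw) cos(pitch), sin(pitch), cos(yaw) cos(pitch)]`.
#'
#' @param yaw,pitch Angles in degrees (vectors of equal length);
#'   `abs(pitch)` must stay below 90 (gimbal).
#' @return An n x 4 matrix of unit quaternions (a vector if n = 1).
#' @export
direction_to_quaternion <- function(yaw, pitch) {
  if (any(abs(pitch) >= 90))
    stop("|pitch| must be below 90 degrees (gimbal) for the zero-roll model")
  y2 <- yaw * pi / 360   # half-angles in radians
  p2 <- pitch * pi / 360
  Q <- cbind(x = -sin(p2) * cos(y2),
             y = sin(y2) * cos(p2),
             z = sin(p2) * sin(y2),
             w = cos(p2) * cos(y2))
  if (nrow(Q) == 1L) Q[1L, ] else Q
}

# Smooth AR(1) noise with stationary sd `sd` (possibly per-sample vector).
.smooth_noise <- function(n, sd, phi = 0.9) {
  sd <- rep_len(sd, n)
  e <- numeric(n)
  innov <- rnorm(n)
  e[1L] <- sd[1L] * innov[1L]
  for (i in seq_len(n)[-1L])
    e[i] <- phi * e[i - 1L] + sd[i] * sqrt(1 - phi^2) * innov[i]
  e
}

#' Draw jittered sampling intervals
#'
#' Normal intervals with the configured mean and sd, floored at 1 ms so no
#' interval is non-positive.
#'
#' @param n Number of intervals.
#' @param config A [synthetic_config()].
#' @return Numeric vector of intervals in ms.
#' @export
sample_intervals <- function(n, config = synthetic_config()) {
  pmax(rnorm(n, config$dt_mean_ms, config$dt_sd_ms), 1)
}

.neutral_style <- function() {
  list(amplitude = 1, speed = 1, tilt_deg = 0, yaw_scale = 1, pitch_scale = 1)
}

# Per-subject execution style: overall amplitude and speed, an in-plane tilt
# of the drawn shape, and a yaw/pitch anisotropy (people compress or stretch
# gestures differently along the two head axes).
.draw_style <- function(config) {
  list(amplitude = runif(1, config$amplitude_range[1], config$amplitude_range[2]),
       speed = runif(1, config$speed_range[1], config$speed_range[2]),
       tilt_deg = rnorm(1, 0, config$tilt_sd_deg),
       yaw_scale = runif(1, 0.8, 1.2),
       pitch_scale = runif(1, 0.8, 1.2))
}

# Repetition-to-repetition variation within a subject: amplitude and tilt
# jitter, a smooth monotone time warp t -> t + a sin(pi t) that varies the
# speed profile along the gesture (|a| < 1/pi keeps it monotone), and a
# low-frequency deformation of the drawn shape itself (two harmonics per
# axis) — repetitions of the "same" gesture flatten bumps, drift, and
# overshoot rather than just rescaling.
.draw_rep_variation <- function() {
  list(amp = runif(1, 0.9, 1.1),
       tilt_deg = rnorm(1, 0, 2),
       warp_a = runif(1, -0.25, 0.25),
       def_amp = rnorm(4, 0, 5),
       def_phase = runif(4, 0, 2 * pi))
}

.no_rep_variation <- function() {
  list(amp = 1, tilt_deg = 0, warp_a = 0, def_amp = rep(0, 4),
       def_phase = rep(0, 4))
}

.apply_tilt <- function(yp, tilt_deg) {
  th <- tilt_deg * pi / 180
  cbind(yaw = cos(th) * yp[, 1L] - sin(th) * yp[, 2L],
        pitch = sin(th) * yp[, 1L] + cos(th) * yp[, 2L])
}

# yaw/pitch curve for one gesture instance; returns n x 2 matrix.
.gesture_curve <- function(class, style, config, n, rep_var = .no_rep_variation()) {
  t_norm <- seq(0, 1, length.out = n)
  t_warp <- t_norm + rep_var$warp_a * sin(pi * t_norm)
  yp <- .shape_bank[[class]](t_warp)
  a <- rep_var$def_amp; ph <- rep_var$def_phase
  yp[, 1L] <- style$amplitude * rep_var$amp * style$yaw_scale * yp[, 1L] +
    a[1L] * sin(pi * t_norm + ph[1L]) + a[2L] * sin(2 * pi * t_norm + ph[2L])
  yp[, 2L] <- style$amplitude * rep_var$amp * style$pitch_scale * yp[, 2L] +
    a[3L] * sin(pi * t_norm + ph[3L]) + a[4L] * sin(2 * pi * t_norm + ph[4L])
  .apply_tilt(yp, style$tilt_deg + rep_var$tilt_deg)
}

.gesture_samples <- function(class, style, config) {
  # duration scales with amplitude as well as speed: smaller gestures are
  # performed proportionally faster, keeping angular velocity amplitude-free
  duration_ms <- 1000 * .shape_durations[[class]] * style$speed *
    style$amplitude * runif(1, 0.9, 1.1)
  dts <- sample_intervals(config$length_bounds[2L], config)
  n <- which(cumsum(dts) >= duration_ms)[1L]
  if (is.na(n)) n <- length(dts)
  n <- min(max(n, config$length_bounds[1L]), config$length_bounds[2L])
  list(n = n, dts = dts[seq_len(n - 1L)])
}

#' Generate one synthetic gesture recording
#'
#' Samples the idealized class shape at jittered acquisition times, applies
#' the subject's amplitude/speed/tilt style and smooth per-sample angular
#' noise, converts yaw/pitch to zero-roll quaternions, and re-references so
#' the first rotation is the identity.
#'
#' @param class One of [gesture_classes()].
#' @param style Subject style (list with `amplitude`, `speed`, `tilt_deg`);
#'   default neutral.
#' @param config A [synthetic_config()].
#' @param subject Optional subject id stored on the recording.
#' @param seed Optional seed for standalone reproducible draws; when `NULL`
#'   the current RNG stream is used (as inside [generate_dataset()]).
#' @return A labeled [orientation_sequence].
#' @export
generate_recording <- function(class, style = .neutral_style(),
                               config = synthetic_config(),
                               subject = NULL, seed = NULL) {
  class <- match.arg(class, gesture_classes())
  if (!is.null(seed)) return(.with_seed(seed, generate_recording(class, style, config, subject)))
  rep_var <- .draw_rep_variation()
  ns <- .gesture_samples(class, style, config)
  yp <- .gesture_curve(class, style, config, ns$n, rep_var)
  yp[, 1L] <- yp[, 1L] + .smooth_noise(ns$n, config$noise_angle_deg)
  # pitch capped at +/-88: the head cannot pitch to the pole of the motion
  # range, and the zero-roll quaternion model is singular there
  yp[, 2L] <- pmin(88, pmax(-88, yp[, 2L] + .smooth_noise(ns$n, config$noise_angle_deg)))
  q <- direction_to_quaternion(yp[, 1L], yp[, 2L])
  rereference(orientation_sequence(q, t = c(0, cumsum(ns$dts)),
                                   subject = subject, label = class,
                                   normalize = FALSE))
}

#' Generate a labeled synthetic dataset
#'
#' `subjects x classes x reps_per_class` recordings; per-subject style
#' parameters are drawn once per subject. Deterministic under the
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @return A list of labeled [orientation_sequence] objects.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  .with_seed(config$seed, {
    out <- list()
    for (s in seq_len(config$subjects)) {
      sid <- sprintf("s%02d", s)
      style <- .draw_style(config)
      for (cl in config$classes) {
        for (r in seq_len(config$reps_per_class)) {
          out[[length(out) + 1L]] <-
            generate_recording(cl, style, config, subject = sid)
        }
      }
    }
    out
  })
}

#' Generate a continuous multi-gesture stream with planted boundaries
#'
#' Concatenates still periods (small smooth noise, below the segmentation
#' threshold after median filtering) and gesture periods, and returns the
#' raw stream together with the ground-truth segment boundaries — the
#' fixture for testing gesture segmentation.
#'
#' @param config A [synthetic_config()].
#' @param gestures Character vector of gesture classes, in order.
#' @param rest_samples Still samples before, between, and after gestures.
#' @param seed Optional seed (defaults to `config$seed`).
#' @return List with `stream` (an [orientation_sequence]) and `segments`
#'   (data.frame `start`, `end`, `label`; 1-based inclusive sample ranges).
#' @export
generate_stream <- function(config = synthetic_config(),
                            gestures = c("clockwise", "left", "nod"),
                            rest_samples = 100L, seed = NULL) {
  rest_samples <- as.integer(rest_samples)
  if (rest_samples < 1L) stop("'rest_samples' must be >= 1")
  .with_seed(if (is.null(seed)) config$seed else seed, {
    style <- .neutral_style()
    yp <- matrix(numeric(0), ncol = 2)
    sd_per_sample <- numeric(0)
    starts <- ends <- integer(0)
    rest_sd <- min(0.3, config$noise_angle_deg)
    add_rest <- function() {
      yp <<- rbind(yp, matrix(0, rest_samples, 2))
      sd_per_sample <<- c(sd_per_sample, rep(rest_sd, rest_samples))
    }
    add_rest()
    for (g in gestures) {
      n <- .gesture_samples(g, style, config)$n
      starts <- c(starts, nrow(yp) + 1L)
      yp <- rbind(yp, .gesture_curve(g, style, config, n))
      ends <- c(ends, nrow(yp))
      sd_per_sample <- c(sd_per_sample, rep(config$noise_angle_deg, n))
      add_rest()
    }
    n_total <- nrow(yp)
    yaw <- yp[, 1L] + .smooth_noise(n_total, sd_per_sample)
    pitch <- yp[, 2L] + .smooth_noise(n_total, sd_per_sample)
    q <- direction_to_quaternion(yaw, pitch)
    stream <- orientation_sequence(
      q, t = c(0, cumsum(sample_intervals(n_total - 1L, config))),
      normalize = FALSE)
    list(stream = stream,
         segments = data.frame(start = starts, end = ends, label = gestures))
  })
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}
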