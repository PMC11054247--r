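deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

#' Sagittal hip angle series
#'
#' Signed angle between the thigh vector (hip to knee) and the downward
#' laboratory vertical, positive when the knee is forward of the hip
#' (flexion). The reference is the laboratory vertical rather than a pelvis
#' segment — the only hip landmarks available in a 2D keypoint set — which
#' is a documented systematic difference from marker-based pelvis-relative
#' conventions.
#'
#' @param series_world a metric sagittal [keypoint_series()].
#' @param side `"L"` or `"R"`.
#' @return numeric vector of angles in degrees, one per frame (NA where a
#'   node is missing).
#' @export
hip_angle <- function(series_world, side) {
  hip <- node_for(series_world, side, "hip")
  knee <- node_for(series_world, side, "knee")
  dx <- series_world$x[, knee] - series_world$x[, hip]
  dy <- series_world$y[, knee] - series_world$y[, hip]
  deg(atan2(dx, -dy))
}

#' Sagittal knee angle series
#'
#' 180 degrees minus the interior angle at the knee between the knee-to-hip
#' and knee-to-ankle vectors: 0 at full extension, positive flexion.
#'
#' @inheritParams hip_angle
#' @return numeric vector of angles in degrees (NA where missing or
#'   degenerate).
#' @export
knee_angle <- function(series_world, side) {
  hip <- node_for(series_world, side, "hip")
  knee <- node_for(series_world, side, "knee")
  ankle <- node_for(series_world, side, "ankle")
  ax <- series_world$x[, hip] - series_world$x[, knee]
  ay <- series_world$y[, hip] - series_world$y[, knee]
  bx <- series_world$x[, ankle] - series_world$x[, knee]
  by <- series_world$y[, ankle] - series_world$y[, knee]
  na <- sqrt(ax^2 + ay^2); nb <- sqrt(bx^2 + by^2)
  cosang <- (ax * bx + ay * by) / (na * nb)
  cosang[na == 0 | nb == 0] <- NA_real_
  180 - deg(acos(pmin(1, pmax(-1, cosang))))
}

#' Trailing limb angle series
#'
#' Angle between the downward vertical through the hip and the hip-to-toe
#' vector, positive when the toe trails behind the hip. Uses the big-toe
#' node, falling back to the ankle if absent.
#'
#' @inheritParams hip_angle
#' @return numeric vector of angles in degrees.
#' @export
tla_angle <- function(series_world, side) {
  hip <- node_for(series_world, side, "hip")
  toe <- node_for(series_world, side, "toe")
  dx <- series_world$x[, toe] - series_world$x[, hip]
  dy <- series_world$y[, toe] - series_world$y[, hip]
  deg(atan2(-dx, -dy))
}

#' Per-frame joint angle table
#'
#' Hip, knee and TLA series for one side with per-frame sanity gates
#' (|hip| < 90, -5 <= knee < 160, |TLA| < 60); violating frames are flagged
#' rather than dropped.
#'
#' @inheritParams hip_angle
#' @return data.frame with columns `time`, `hip`, `knee`, `tla`, `flagged`.
#' @export
joint_angles <- function(series_world, side) {
  h <- hip_angle(series_world, side)
  k <- knee_angle(series_world, side)
  tl <- tla_angle(series_world, side)
  flagged <- (abs(h) >= 90) | (k < -5 | k >= 160) | (abs(tl) >= 60)
  flagged[is.na(flagged)] <- FALSE
  data.frame(time = series_world$time, hip = h, knee = k, tla = tl,
             flagged = flagged)
}

#' Resample an angle series onto the normalised gait cycle
#'
#' Linear-interpolation resampling onto phases 0, 1, ..., 100% of the cycle
#' (101 points by default).
#'
#' @param time sample times (s).
#' @param values angle samples (degrees; NA allowed).
#' @param t_start,t_end cycle boundaries (s).
#' @param n_points number of phase points (default 101).
#' @return numeric vector of length `n_points`, or `NULL` if fewer than 4
#'   valid samples fall inside the cycle (the cycle should be invalidated).
#' @export
resample_cycle <- function(time, values, t_start, t_end, n_points = 101L) {
  ok <- is.finite(time) & is.finite(values)
  inside <- ok & time >= t_start & time <= t_end
  if (sum(inside) < 4L) return(NULL)
  phases <- seq(0, 100, length.out = n_points)
  target <- t_start + phases / 100 * (t_end - t_start)
  approx(time[ok], values[ok], xout = target, rule = 2)$y
}

#' Summarise one cycle's kinematics
#'
#' Peak flexion (max) and extension (min) with their phases (% of cycle,
#' ties resolved to the earliest sample; the duplicate endpoint 100% maps
#' to 0%), ROM = max - min for hip and knee, and the TLA peak (max) with
#' its phase. Extension peaks are signed (hip extension is negative).
#'
#' @param hip,knee,tla 101-point waveforms from [resample_cycle()] (any may
#'   be `NULL`, yielding NA fields).
#' @param side `"L"` or `"R"`.
#' @return one-row data.frame with `side` and, per joint, `*_flexion_peak`,
#'   `*_flexion_phase`, `*_extension_peak`, `*_extension_phase`, `*_rom`,
#'   plus `tla_peak`, `tla_phase`.
#' @export
summarize_cycle <- function(hip = NULL, knee = NULL, tla = NULL, side = NA) {
  peak <- function(w) {
    if (is.null(w)) return(c(NA, NA, NA, NA, NA))
    np <- length(w)
    phases <- seq(0, 100, length.out = np)
    imax <- which.max(w); imin <- which.min(w)
    pmax_ <- phases[imax] %% 100  # half-open cycle: 100% is 0%
    pmin_ <- phases[imin] %% 100
    c(w[imax], pmax_, w[imin], pmin_, w[imax] - w[imin])
  }
  h <- peak(hip); k <- peak(knee); tl <- peak(tla)
  data.frame(
    side = side,
    hip_flexion_peak = h[1], hip_flexion_phase = h[2],
    hip_extension_peak = h[3], hip_extension_phase = h[4], hip_rom = h[5],
    knee_flexion_peak = k[1], knee_flexion_phase = k[2],
    knee_extension_peak = k[3], knee_extension_phase = k[4], knee_rom = k[5],
    tla_peak = tl[1], tla_phase = tl[2],
    stringsAsFactors = FALSE
  )
}
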