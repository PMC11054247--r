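#' Configuration of the synthetic sagittal walker
#'
#' Parameterises a planar kinematic walker: segment lengths as fractions of
#' stature (standard anthropometry), stride timing and length, joint
#' waveform peak targets (value, phase-% pairs on the crossing-anchored
#' cycle scale), a trailing-limb-angle peak target, observation noise and a
#' seed. Defaults are the comfortable-walk condition of a published
#' two-system validation cohort (stride 1399.2 mm / 1.016 s, hip peaks
#' +31.7 deg at 12.5% and -13.7 deg at 70.9%, knee peaks 65.6 deg at 90.9%
#' and 6.2 deg at 57%, TLA peak 23.6 deg).
#'
#' @param subject_height stature in cm.
#' @param thigh_frac,shank_frac,foot_frac,hip_frac segment lengths and hip
#'   height as fractions of stature.
#' @param ankle_height_frac ankle-joint height above the sole as a fraction
#'   of stature.
#' @param stride_time stride (cycle) duration in s.
#' @param stride_length stride length in mm.
#' @param n_strides number of complete gait cycles per side to generate.
#' @param frame_rate camera frame rate in Hz.
#' @param hip_flexion,hip_extension,knee_flexion,knee_extension numeric
#'   `c(peak_deg, phase_pct)` targets; flexion peak must exceed extension
#'   peak.
#' @param tla_peak trailing limb angle peak target in degrees.
#' @param noise_px SD of Gaussian pixel jitter added to every projected
#'   keypoint (0 = noise-free).
#' @param dropout per-point probability of a missed detection.
#' @param rail_tracking if `TRUE` the side camera tracks the pelvis along
#'   the guide rail (per-frame rail offsets are part of the output);
#'   `FALSE` (default) is the static-camera convention.
#' @param lateral_offset mean lateral offset from the path centre line in m
#'   (frontal camera), plus a small sinusoidal sway around it.
#' @param sway_m amplitude of the lateral sway in m.
#' @param front_px_per_m frontal-camera scale in px per metre.
#' @param seed RNG seed for noise and dropout.
#' @return object of class `walker_config`.
#' @export
walker_config <- function(subject_height = 160.9,
                          thigh_frac = 0.245, shank_frac = 0.246,
                          foot_frac = 0.152, hip_frac = 0.530,
                          ankle_height_frac = 0.039,
                          stride_time = 1.016, stride_length = 1399.2,
                          n_strides = 4L, frame_rate = 60,
                          hip_flexion = c(31.7, 12.5),
                          hip_extension = c(-13.7, 70.9),
                          knee_flexion = c(65.6, 90.9),
                          knee_extension = c(6.2, 57.0),
                          tla_peak = 23.6,
                          noise_px = 0, dropout = 0,
                          rail_tracking = FALSE,
                          lateral_offset = 0, sway_m = 0.01,
                          front_px_per_m = 350,
                          seed = 1L) {
  cfg <- list(subject_height = subject_height, thigh_frac = thigh_frac,
              shank_frac = shank_frac, foot_frac = foot_frac,
              hip_frac = hip_frac, ankle_height_frac = ankle_height_frac,
              stride_time = stride_time, stride_length = stride_length,
              n_strides = as.integer(n_strides), frame_rate = frame_rate,
              hip_flexion = hip_flexion, hip_extension = hip_extension,
              knee_flexion = knee_flexion, knee_extension = knee_extension,
              tla_peak = tla_peak, noise_px = noise_px, dropout = dropout,
              rail_tracking = rail_tracking,
              lateral_offset = lateral_offset, sway_m = sway_m,
              front_px_per_m = front_px_per_m, seed = seed)
  with(cfg, {
    stopifnot(subject_height > 0, stride_time > 0, stride_length > 0,
              n_strides >= 1, frame_rate > 0, noise_px >= 0,
              dropout >= 0, dropout <= 1)
    if (hip_flexion[1] <= hip_extension[1] ||
        knee_flexion[1] <= knee_extension[1])
      stop("infeasible waveform targets: flexion peak must exceed extension peak")
    stopifnot(all(c(hip_flexion[2], hip_extension[2], knee_flexion[2],
                    knee_extension[2]) >= 0),
              all(c(hip_flexion[2], hip_extension[2], knee_flexion[2],
                    knee_extension[2]) < 100))
  })
  structure(cfg, class = "walker_config")
}

#' Condition presets for the synthetic cohort
#'
#' Walker parameter presets for the three walking conditions of the
#' emulated study design (comfortable, maximum-speed and tandem level
#' walking), set to the pooled left-right reference means of the emulated
#' cohort's marker-based system.
#'
#' @param condition `"com"`, `"max"` or `"tandem"`.
#' @return a [walker_config()].
#' @export
condition_preset <- function(condition = c("com", "max", "tandem")) {
  condition <- match.arg(condition)
  switch(condition,
    com = walker_config(),
    max = walker_config(stride_time = 0.866, stride_length = 1597.1,
                        hip_flexion = c(34.3, 14.5),
                        hip_extension = c(-16.3, 69.5),
                        knee_flexion = c(65.2, 90.3),
                        knee_extension = c(4.7, 57.5),
                        tla_peak = 27.0),
    tandem = walker_config(stride_time = 1.089, stride_length = 1320.9,
                           hip_flexion = c(32.4, 10.7),
                           hip_extension = c(-12.3, 71.7),
                           knee_flexion = c(65.3, 91.8),
                           knee_extension = c(6.0, 54.7),
                           tla_peak = 22.1)
  )
}

# Periodic C1 waveform through extremum/control knots: consecutive knots are
# joined by half-cosine segments (zero slope at both ends), so knot values
# that are local extrema are achieved exactly.
make_wave <- function(phases, values) {
  o <- order(phases)
  phases <- phases[o]; values <- values[o]
  ph <- c(phases, phases[1] + 100)
  va <- c(values, values[1])
  function(phase) {
    p <- phases[1] + ((phase - phases[1]) %% 100)
    i <- findInterval(p, ph, rightmost.closed = TRUE)
    i[i < 1] <- 1L; i[i > length(ph) - 1L] <- length(ph) - 1L
    u <- (p - ph[i]) / (ph[i + 1] - ph[i])
    va[i] + (va[i + 1] - va[i]) * (1 - cos(pi * u)) / 2
  }
}

# Leg pose at phase(s) phi (percent), relative to the hip joint at origin.
# Returns a list of 2-column matrices (x forward, y up), in metres.
pose_leg <- function(phi, hip_f, knee_f, cfg, foot_pitch) {
  H <- cfg$subject_height / 100
  Lt <- cfg$thigh_frac * H; Ls <- cfg$shank_frac * H
  Lf <- cfg$foot_frac * H; ah <- cfg$ankle_height_frac * H
  heel_back <- 0.25 * Lf
  h <- rad(hip_f(phi)); k <- rad(knee_f(phi))
  s <- h - k                         # shank angle from vertical
  knee <- cbind(Lt * sin(h), -Lt * cos(h))
  ankle <- knee + cbind(Ls * sin(s), -Ls * cos(s))
  beta <- s + rad(foot_pitch)        # foot long-axis attitude
  f <- cbind(cos(beta), sin(beta))   # heel -> toe unit vector
  n <- cbind(-sin(beta), cos(beta))  # foot up normal
  heel <- ankle - heel_back * f - ah * n
  toe <- heel + Lf * f
  list(knee = knee, ankle = ankle, heel = heel, toe = toe)
}

tla_of_pose <- function(pose) {
  deg(atan2(-pose$toe[, 1], -pose$toe[, 2]))
}

#' Joint waveforms of the synthetic walker
#'
#' Builds the hip and knee cycle waveforms from the peak targets as
#' periodic C1 cosine-segment curves that achieve every target peak and
#' phase exactly, then enforces the cycle-phase convention and the TLA
#' target:
#'
#' * the knee waveform receives one extra interior control point at phase 0
#'   whose value is solved so that the ankle sits exactly under the hip at
#'   phase 0 moving forward — making the crossing-anchored phase scale of
#'   the peak targets self-consistent with the event detector;
#' * the constant foot-pitch offset of the foot model is calibrated by root
#'   finding so the implied trailing-limb-angle waveform peaks at the
#'   target.
#'
#' @param config a [walker_config()].
#' @return list with waveform functions `hip`, `knee`, `tla` (degree values
#'   of phase in percent), `foot_pitch` (deg), `knee_at_zero` (deg),
#'   `ankle_dx` (function: forward ankle-hip offset in m), and
#'   `waveforms_101` (data.frame: phase 0..100 with hip, knee, tla).
#' @export
angle_waveforms <- function(config) {
  cfg <- config
  H <- cfg$subject_height / 100
  Lt <- cfg$thigh_frac * H; Ls <- cfg$shank_frac * H

  hip_f <- make_wave(c(cfg$hip_flexion[2], cfg$hip_extension[2]),
                     c(cfg$hip_flexion[1], cfg$hip_extension[1]))
  h0 <- hip_f(0)
  # ankle under hip at phase 0: Lt sin(h0) + Ls sin(h0 - k0) = 0
  arg <- (Lt / Ls) * sin(rad(h0))
  if (abs(arg) >= 1)
    stop("infeasible geometry: cannot place the ankle under the hip at phase 0")
  k0 <- h0 + deg(asin(arg))
  if (k0 >= cfg$knee_flexion[1] - 0.5 || k0 <= cfg$knee_extension[1] + 0.5)
    stop(sprintf(paste0("infeasible waveform targets: required knee angle at ",
                        "phase 0 (%.1f deg) is outside the peak range"), k0))
  knee_f <- make_wave(
    c(cfg$knee_extension[2], cfg$knee_flexion[2], 0),
    c(cfg$knee_extension[1], cfg$knee_flexion[1], k0)
  )

  ankle_dx <- function(phi) {
    h <- rad(hip_f(phi)); k <- rad(knee_f(phi))
    Lt * sin(h) + Ls * sin(h - k)
  }
  # the forward crossing must be unique within the cycle
  grid <- seq(0, 100, by = 0.25)
  dvals <- ankle_dx(grid + 1e-9)
  ups <- sum(dvals[-length(dvals)] < 0 & dvals[-1] > 0)
  if (ups != 1L)
    stop("waveform targets produce ", ups + 1L,
         " forward ankle-under-hip crossings per cycle; expected 1")

  peak_tla <- function(pitch) {
    ph <- seq(0, 100, by = 0.5)
    max(tla_of_pose(pose_leg(ph, hip_f, knee_f, cfg, pitch)))
  }
  lo <- -80; hi <- 80
  flo <- peak_tla(lo) - cfg$tla_peak
  fhi <- peak_tla(hi) - cfg$tla_peak
  if (flo * fhi > 0)
    stop("cannot reach the TLA peak target with foot pitch in [-80, 80] deg")
  foot_pitch <- uniroot(function(p) peak_tla(p) - cfg$tla_peak,
                        c(lo, hi), tol = 1e-10)$root

  ph <- 0:100
  pose <- pose_leg(ph, hip_f, knee_f, cfg, foot_pitch)
  tla_f <- function(phi)
    tla_of_pose(pose_leg(phi, hip_f, knee_f, cfg, foot_pitch))
  list(hip = hip_f, knee = knee_f, tla = tla_f,
       foot_pitch = foot_pitch, knee_at_zero = k0, ankle_dx = ankle_dx,
       waveforms_101 = data.frame(phase = ph, hip = hip_f(ph),
                                  knee = knee_f(ph),
                                  tla = tla_of_pose(pose)))
}

#' Default side-camera calibration for the synthetic scene
#'
#' A distortion-free pinhole at the emulated camera layout: 1.5 m from the
#' walking-path centre plane, centre of lens 80.5 cm above the floor.
#'
#' @return a [camera_calibration()].
#' @export
default_calibration <- function() camera_calibration()

#' Generate one synthetic walking trial
#'
#' Poses the walker frame by frame (pelvis advancing at
#' `stride_length / stride_time`, legs driven by the cycle waveforms with a
#' 50% phase offset between sides), projects every keypoint through the
#' side-camera model (inverse perspective correction, then lens
#' distortion), optionally adds Gaussian pixel jitter and dropout, and
#' emits side and frontal keypoint series plus an exact ground-truth
#' record. The walker is placed vertically so the heel's lowest point over
#' the cycle is the walking surface (y = 0). Deterministic given
#' `config$seed`.
#'
#' @param config a [walker_config()].
#' @param calibration a [camera_calibration()] (default
#'   [default_calibration()]).
#' @return list with `side` and `front` ([keypoint_series()], pixel units),
#'   `rail_offset` (per-frame m, all zero unless `rail_tracking`), and
#'   `truth`: stride/step/speed values, per-side crossing and heel-contact
#'   times, the 101-point joint waveforms and the walker geometry.
#' @export
generate_trial <- function(config, calibration = default_calibration()) {
  cfg <- config
  stopifnot(inherits(cfg, "walker_config"))
  waves <- angle_waveforms(cfg)
  H <- cfg$subject_height / 100
  T_ <- cfg$stride_time
  v <- (cfg$stride_length / 1000) / T_
  fr <- cfg$frame_rate

  # vertical placement: heel minimum over the cycle sits on the floor
  ph_fine <- seq(0, 100, by = 0.1)
  pose_fine <- pose_leg(ph_fine, waves$hip, waves$knee, cfg, waves$foot_pitch)
  y_hip <- -min(pose_fine$heel[, 2])
  i_hc <- which.min(pose_fine$heel[, 2])
  phi_hc <- optimize(function(p)
    pose_leg(p, waves$hip, waves$knee, cfg, waves$foot_pitch)$heel[, 2],
    interval = c(max(0, ph_fine[i_hc] - 1), min(100, ph_fine[i_hc] + 1)))$minimum

  t0 <- 0.25 * T_                     # lead-in before the first left crossing
  t_max <- t0 + (cfg$n_strides + 0.8) * T_
  nf <- floor(t_max * fr) + 1L
  t <- (0:(nf - 1L)) / fr
  phi_L <- 100 * (((t - t0) / T_) %% 1)
  phi_R <- 100 * (((t - t0 - T_ / 2) / T_) %% 1)

  nodes <- c("MidHip", "RHip", "LHip", "Neck",
             "RKnee", "RAnkle", "RHeel", "RBigToe",
             "LKnee", "LAnkle", "LHeel", "LBigToe")
  wx <- wy <- matrix(NA_real_, nf, length(nodes),
                     dimnames = list(NULL, nodes))
  hipx <- v * t
  wx[, "MidHip"] <- wx[, "RHip"] <- wx[, "LHip"] <- wx[, "Neck"] <- hipx
  wy[, "MidHip"] <- wy[, "RHip"] <- wy[, "LHip"] <- y_hip
  wy[, "Neck"] <- y_hip + 0.34 * H
  for (side in c("L", "R")) {
    phi <- if (side == "L") phi_L else phi_R
    pl <- pose_leg(phi, waves$hip, waves$knee, cfg, waves$foot_pitch)
    for (nd in c("Knee", "Ankle", "Heel", "BigToe")) {
      key <- switch(nd, Knee = "knee", Ankle = "ankle", Heel = "heel",
                    BigToe = "toe")
      wx[, paste0(side, nd)] <- hipx + pl[[key]][, 1]
      wy[, paste0(side, nd)] <- y_hip + pl[[key]][, 2]
    }
  }

  rail <- if (cfg$rail_tracking) v * t else rep(0, nf)
  Hinv <- solve(calibration$homography)
  px <- py <- matrix(NA_real_, nf, length(nodes),
                     dimnames = list(NULL, nodes))
  for (jn in seq_along(nodes)) {
    p <- world_to_side(cbind(wx[, jn], wy[, jn]), calibration, rail)
    p <- apply_homography(p, Hinv)
    p <- distort_point(p, calibration)
    px[, jn] <- p[, 1]; py[, jn] <- p[, 2]
  }
  conf <- matrix(1, nf, length(nodes), dimnames = list(NULL, nodes))
  if (cfg$noise_px > 0 || cfg$dropout > 0) {
    with_seed(cfg$seed, {
      if (cfg$noise_px > 0) {
        px <- px + matrix(rnorm(length(px), 0, cfg$noise_px), nf)
        py <- py + matrix(rnorm(length(py), 0, cfg$noise_px), nf)
      }
      if (cfg$dropout > 0) {
        drop <- matrix(runif(length(px)) < cfg$dropout, nf)
        px[drop] <- NA_real_; py[drop] <- NA_real_; conf[drop] <- 0
      }
    })
  }
  side_series <- keypoint_series(px, py, conf, fr, nodes = nodes,
                                 camera_id = "side",
                                 subject_height = cfg$subject_height)

  # frontal view: fixed scale, lateral offset plus sinusoidal sway
  k_px <- cfg$front_px_per_m
  lat <- cfg$lateral_offset + cfg$sway_m * sin(2 * pi * t / T_)
  fnodes <- c("Neck", "MidHip", "LHeel", "RHeel")
  fx <- fy <- matrix(NA_real_, nf, length(fnodes),
                     dimnames = list(NULL, fnodes))
  heights <- c(Neck = 0.87 * H, MidHip = cfg$hip_frac * H, LHeel = 0,
               RHeel = 0)
  lateral <- cbind(Neck = lat, MidHip = lat, LHeel = lat - 0.09,
                   RHeel = lat + 0.09)
  for (jn in seq_along(fnodes)) {
    fx[, jn] <- calibration$cx + lateral[, fnodes[jn]] * k_px
    fy[, jn] <- calibration$cy - heights[fnodes[jn]] * k_px
  }
  front_series <- keypoint_series(fx, fy, NULL, fr, nodes = fnodes,
                                  camera_id = "front",
                                  subject_height = cfg$subject_height)

  crossings <- list(
    L = t0 + (0:cfg$n_strides) * T_,
    R = t0 + T_ / 2 + (0:cfg$n_strides) * T_
  )
  crossings <- lapply(crossings, function(x) x[x <= t[nf]])
  contacts <- lapply(crossings, function(cr)
    (cr[-length(cr)] + phi_hc / 100 * T_))

  list(
    side = side_series, front = front_series, rail_offset = rail,
    truth = list(
      config = cfg, stride_time_s = T_,
      stride_length_mm = cfg$stride_length,
      step_length_mm = cfg$stride_length / 2,
      gait_speed_mps = v,
      crossings = crossings, contacts = contacts,
      contact_phase_pct = phi_hc,
      waveforms = waves$waveforms_101,
      foot_pitch = waves$foot_pitch, y_hip = y_hip,
      lateral_offset_m = cfg$lateral_offset
    )
  )
}

#' Generate a synthetic cohort of walkers
#'
#' Draws per-subject walker parameters around the condition presets
#' ([condition_preset()]) with between-subject SDs taken from the emulated
#' cohort's reference tables, truncated to +/- 2 SD and to feasible
#' waveform orderings. Stature is drawn around 160.9 +/- 6.8 cm. Returns
#' configurations and the true parameter table; keypoints for each trial
#' are materialised by [generate_trial()] (or [run_simulate()]).
#'
#' @param n_subjects number of subjects (default 20).
#' @param conditions subset of `c("com", "max", "tandem")`.
#' @param trials_per trials per subject and condition.
#' @param seed top-level seed; each trial gets a derived seed.
#' @param noise_px,dropout observation noise passed to every config.
#' @param sd_scale multiplier on every between-subject SD (0 makes all
#'   subjects identical to the preset).
#' @return list with `trials` (list of `subject`, `condition`, `trial`,
#'   `config`) and `truth` (data.frame of the drawn true parameters).
#' @export
generate_cohort <- function(n_subjects = 20, conditions = c("com", "max",
                                                            "tandem"),
                            trials_per = 1L, seed = 1L,
                            noise_px = 0, dropout = 0, sd_scale = 1) {
  stopifnot(n_subjects >= 1, sd_scale >= 0)
  sds <- list(
    com = c(stride_length = 94.4, stride_time = 0.046, hip_flex = 6.1,
            hip_ext = 6.2, knee_flex = 9.9, knee_ext = 7.1, tla = 2.5),
    max = c(stride_length = 102.3, stride_time = 0.065, hip_flex = 6.2,
            hip_ext = 6.8, knee_flex = 10.6, knee_ext = 7.5, tla = 2.6),
    tandem = c(stride_length = 146.8, stride_time = 0.131, hip_flex = 5.9,
               hip_ext = 7.3, knee_flex = 8.8, knee_ext = 8.0, tla = 3.2)
  )
  trunc_norm <- function(mu, sd, lo = -Inf, hi = Inf) {
    x <- mu + sd_scale * sd * max(-2, min(2, rnorm(1)))
    max(lo, min(hi, x))
  }
  trials <- list()
  rows <- list()
  with_seed(seed, {
    heights <- 160.9 + sd_scale * 6.8 * pmax(-2, pmin(2, rnorm(n_subjects)))
    for (si in seq_len(n_subjects)) {
      for (cond in conditions) {
        preset <- condition_preset(cond)
        s <- sds[[cond]]
        for (tr in seq_len(trials_per)) {
          repeat {
            hf <- trunc_norm(preset$hip_flexion[1], s["hip_flex"])
            he <- trunc_norm(preset$hip_extension[1], s["hip_ext"])
            kf <- trunc_norm(preset$knee_flexion[1], s["knee_flex"])
            ke <- trunc_norm(preset$knee_extension[1], s["knee_ext"],
                             lo = 0)
            tl <- trunc_norm(preset$tla_peak, s["tla"], lo = 10)
            sl <- trunc_norm(preset$stride_length, s["stride_length"],
                             lo = 600)
            st <- trunc_norm(preset$stride_time, s["stride_time"],
                             lo = 0.5)
            if (!(hf > he + 20 && kf > ke + 25)) next
            cfg <- tryCatch(
              walker_config(
                subject_height = heights[si],
                stride_time = st, stride_length = sl,
                n_strides = preset$n_strides,
                frame_rate = preset$frame_rate,
                hip_flexion = c(hf, preset$hip_flexion[2]),
                hip_extension = c(he, preset$hip_extension[2]),
                knee_flexion = c(kf, preset$knee_flexion[2]),
                knee_extension = c(ke, preset$knee_extension[2]),
                tla_peak = tl, noise_px = noise_px, dropout = dropout,
                seed = sample.int(2^30, 1)
              ),
              error = function(e) NULL)
            # the drawn targets must also give a feasible walker geometry
            if (!is.null(cfg) &&
                !is.null(tryCatch(angle_waveforms(cfg),
                                  error = function(e) NULL))) break
          }
          sid <- sprintf("S%02d", si)
          trials[[length(trials) + 1L]] <-
            list(subject = sid, condition = cond, trial = tr, config = cfg)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = sid, condition = cond, trial = tr,
            subject_height = heights[si], stride_length = sl,
            stride_time = st, gait_speed = (sl / 1000) / st,
            hip_flexion = hf, hip_extension = he,
            knee_flexion = kf, knee_extension = ke, tla_peak = tl,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  list(trials = trials, truth = do.call(rbind, rows))
}

#' Generate a two-system measurement matrix with known agreement
#'
#' Simulates `y_ij = t_i + b_j + e_ij` with subject effects
#' `t_i ~ N(mu, sigma_subject^2)` and errors `e_ij ~ N(0, sigma_error^2)`
#' for two systems with additive biases `b_1`, `b_2`. The theoretical
#' single-measures consistency ICC is
#' `sigma_subject^2 / (sigma_subject^2 + sigma_error^2)`.
#'
#' @param n_subjects number of rows.
#' @param mu grand mean of the true values.
#' @param sigma_subject between-subject SD (>= 0).
#' @param sigma_error within-system error SD (>= 0).
#' @param biases additive system biases `c(b1, b2)`.
#' @param seed RNG seed.
#' @return list with `matrix` (n x 2), `icc_theoretical` (single-measures
#'   consistency ICC) and `bias_diff` (`b1 - b2`).
#' @export
generate_two_system <- function(n_subjects, mu = 0, sigma_subject = 1,
                                sigma_error = 1, biases = c(0, 0),
                                seed = 1L) {
  stopifnot(sigma_subject >= 0, sigma_error >= 0, length(biases) == 2)
  m <- with_seed(seed, {
    t_i <- rnorm(n_subjects, mu, sigma_subject)
    e <- matrix(rnorm(2 * n_subjects, 0, sigma_error), n_subjects, 2)
    sweep(e, 2, biases, `+`) + t_i
  })
  colnames(m) <- c("system1", "system2")
  list(matrix = m,
       icc_theoretical = sigma_subject^2 / (sigma_subject^2 + sigma_error^2),
       bias_diff = biases[1] - biases[2])
}
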