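#' Extract gait parameters from one keypoint series
#'
#' Runs the full single-trial pipeline: confidence gating and gap filling,
#' optional smoothing, pixel-to-world conversion, ankle-under-hip cycle
#' detection, heel contacts, per-cycle spatiotemporal parameters and
#' 101-point joint kinematics. Every skipped cycle or frame span is logged
#' with a reason.
#'
#' @param series a pixel-unit side-camera [keypoint_series()].
#' @param calibration a [camera_calibration()].
#' @param rail_offset per-frame rail position in m (scalar or vector).
#' @param confidence_threshold,max_gap_frames passed to [clean_series()].
#' @param cutoff_hz smoothing cutoff for [smooth_series()]; `NULL` (default)
#'   disables smoothing.
#' @param duration_range valid cycle duration window in s.
#' @return list with `results` (one row per valid cycle per side:
#'   spatiotemporal and kinematic summary fields), `cycles` (all cycles
#'   with validity flags), `waveforms` (long data.frame: side, cycle,
#'   phase, hip, knee, tla) and `log` (data.frame: item, reason).
#' @export
extract_trial <- function(series, calibration = default_calibration(),
                          rail_offset = 0, confidence_threshold = 0.3,
                          max_gap_frames = 5L, cutoff_hz = NULL,
                          duration_range = c(0.4, 2.5)) {
  logs <- list()
  note <- function(item, reason)
    logs[[length(logs) + 1L]] <<- data.frame(item = item, reason = reason,
                                             stringsAsFactors = FALSE)
  cleaned <- clean_series(series, confidence_threshold, max_gap_frames)
  rep_ <- attr(cleaned, "fill_report")
  for (i in which(rep_$n_missing > 0))
    note(paste0("node:", rep_$node[i]),
         paste0(rep_$n_missing[i], " frames unrecoverable"))
  if (!is.null(cutoff_hz)) cleaned <- smooth_series(cleaned, cutoff_hz)
  ws <- series_to_world(cleaned, calibration, rail_offset)
  gaps <- find_gap_spans(ws, intersect(GAIT_NODES, ws$nodes))

  contacts <- list(L = detect_heel_contacts(ws, "L"),
                   R = detect_heel_contacts(ws, "R"))
  all_cycles <- list(); results <- list(); wave_rows <- list()
  for (side in c("L", "R")) {
    other <- if (side == "L") "R" else "L"
    cr <- tryCatch(ankle_hip_crossings(ws, side), error = function(e) {
      note(paste0("side:", side), conditionMessage(e)); numeric(0)
    })
    if (length(cr) < 2L) {
      note(paste0("side:", side), "fewer than 2 crossings; no cycles")
      next
    }
    cyc <- segment_cycles(side, cr, contacts[[side]], contacts[[other]],
                          duration_range, gaps)
    for (i in which(!cyc$valid))
      note(sprintf("cycle:%s%d", side, cyc$cycle[i]), cyc$reason[i])
    all_cycles[[side]] <- cyc
    valid <- cyc[cyc$valid, , drop = FALSE]
    if (nrow(valid) == 0L) next
    sm <- stride_metrics(ws, valid, contacts)
    ja <- joint_angles(ws, side)
    for (i in seq_len(nrow(valid))) {
      hw <- resample_cycle(ja$time, ja$hip, valid$t_start[i], valid$t_end[i])
      kw <- resample_cycle(ja$time, ja$knee, valid$t_start[i], valid$t_end[i])
      tw <- resample_cycle(ja$time, ja$tla, valid$t_start[i], valid$t_end[i])
      if (is.null(hw) || is.null(kw)) {
        note(sprintf("cycle:%s%d", side, valid$cycle[i]),
             "too few angle samples")
        next
      }
      ks <- summarize_cycle(hw, kw, tw, side)
      row <- cbind(data.frame(side = side, cycle = valid$cycle[i],
                              t_start = valid$t_start[i],
                              t_end = valid$t_end[i]),
                   sm[i, c("stride_time_s", "stride_length_mm",
                           "step_length_mm", "gait_speed_mps")],
                   ks[, setdiff(names(ks), "side")])
      results[[length(results) + 1L]] <- row
      wave_rows[[length(wave_rows) + 1L]] <- data.frame(
        side = side, cycle = valid$cycle[i], phase = 0:100,
        hip = hw, knee = kw, tla = if (is.null(tw)) NA_real_ else tw)
    }
  }
  list(
    results = if (length(results)) do.call(rbind, results) else
      data.frame(),
    cycles = if (length(all_cycles)) do.call(rbind, all_cycles) else
      data.frame(),
    waveforms = if (length(wave_rows)) do.call(rbind, wave_rows) else
      data.frame(),
    log = if (length(logs)) do.call(rbind, logs) else
      data.frame(item = character(0), reason = character(0))
  )
}

#' Simulate a synthetic walking dataset on disk
#'
#' Generates a cohort ([generate_cohort()]), materialises every trial's
#' side-camera keypoints as long-format CSVs, and writes `truth.csv` and a
#' `manifest.csv` listing subjects, conditions, files and derived seeds.
#' Deterministic for a fixed seed.
#'
#' @param out_dir output directory.
#' @param n_subjects,conditions,trials_per,seed,noise_px,dropout passed to
#'   [generate_cohort()].
#' @param force overwrite a non-empty existing directory.
#' @return the manifest data.frame, invisibly.
#' @export
run_simulate <- function(out_dir, n_subjects = 20,
                         conditions = c("com", "max", "tandem"),
                         trials_per = 1L, seed = 1L, noise_px = 0,
                         dropout = 0, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory is not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  coh <- generate_cohort(n_subjects, conditions, trials_per, seed,
                         noise_px, dropout)
  manifest <- list()
  for (tl in coh$trials) {
    id <- sprintf("%s_%s_t%02d", tl$subject, tl$condition, tl$trial)
    trial <- generate_trial(tl$config)
    f <- file.path(out_dir, paste0("keypoints_", id, ".csv"))
    write_keypoint_series(trial$side, f)
    manifest[[length(manifest) + 1L]] <- data.frame(
      subject = tl$subject, condition = tl$condition, trial = tl$trial,
      file = basename(f), frame_rate = tl$config$frame_rate,
      subject_height = tl$config$subject_height,
      seed = tl$config$seed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(coh$truth, file.path(out_dir, "truth.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(manifest)
}

#' Extract gait parameters for every trial of a simulated dataset
#'
#' Reads `manifest.csv` in `input_dir`, runs [extract_trial()] on every
#' listed keypoint file and writes `results.csv` (one row per valid cycle)
#' plus `extract_log.csv` (one row per excluded frame span or cycle, with
#' its reason).
#'
#' @param input_dir dataset directory from [run_simulate()] (or matching
#'   layout).
#' @param output_dir where to write results (default `input_dir`).
#' @param calibration a [camera_calibration()].
#' @param ... options passed to [extract_trial()].
#' @return the combined results data.frame, invisibly.
#' @export
run_extract <- function(input_dir, output_dir = input_dir,
                        calibration = default_calibration(), ...) {
  mf_path <- file.path(input_dir, "manifest.csv")
  if (!file.exists(mf_path)) stop("no manifest.csv in ", input_dir)
  manifest <- read.csv(mf_path, stringsAsFactors = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  all_res <- list(); all_log <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- sprintf("%s_%s_t%02d", manifest$subject[i], manifest$condition[i],
                  manifest$trial[i])
    series <- tryCatch(
      read_keypoint_files(file.path(input_dir, manifest$file[i]),
                          frame_rate = manifest$frame_rate[i]),
      error = function(e) {
        all_log[[length(all_log) + 1L]] <<- data.frame(
          trial = id, item = "trial", reason = conditionMessage(e))
        NULL
      })
    if (is.null(series)) next
    ex <- extract_trial(series, calibration, ...)
    if (nrow(ex$results) > 0) {
      ex$results <- cbind(data.frame(subject = manifest$subject[i],
                                     condition = manifest$condition[i],
                                     trial = manifest$trial[i]),
                          ex$results)
      all_res[[length(all_res) + 1L]] <- ex$results
    }
    if (nrow(ex$log) > 0)
      all_log[[length(all_log) + 1L]] <- cbind(data.frame(trial = id),
                                               ex$log)
  }
  results <- if (length(all_res)) do.call(rbind, all_res) else data.frame()
  logdf <- if (length(all_log)) do.call(rbind, all_log) else
    data.frame(trial = character(0), item = character(0),
               reason = character(0))
  write_trial_csv(results, file.path(output_dir, "results.csv"))
  write.csv(logdf, file.path(output_dir, "extract_log.csv"),
            row.names = FALSE)
  if (nrow(results) == 0L) stop("no valid gait cycles extracted")
  invisible(results)
}

#' Compare two systems' gait parameter outputs
#'
#' Matches the two inputs by subject, condition and parameter and computes,
#' per parameter and condition, the full agreement battery: per-system
#' means and SDs, the between-system difference (candidate minus
#' reference), the ICC(1,k)/(2,k)/(3,k) family with confidence intervals
#' and qualitative labels, Cronbach's alpha, the validity regression of the
#' reference on the candidate, and the Bland–Altman analysis (differences
#' taken reference minus candidate).
#'
#' @param reference data.frame (or CSV path) with columns `subject`,
#'   `condition`, `parameter`, `value` — the criterion system.
#' @param candidate same layout — the system under validation.
#' @param output_dir optional directory to write `agreement.csv`.
#' @return data.frame with one row per parameter x condition.
#' @export
run_compare <- function(reference, candidate, output_dir = NULL) {
  load_df <- function(x) {
    if (is.character(x)) x <- read.csv(x, stringsAsFactors = FALSE)
    need <- c("subject", "condition", "parameter", "value")
    if (!all(need %in% names(x)))
      stop("comparison input needs columns: ", paste(need, collapse = ", "))
    x[need]
  }
  a <- load_df(reference); b <- load_df(candidate)
  merged <- merge(a, b, by = c("subject", "condition", "parameter"),
                  suffixes = c("_ref", "_cand"))
  if (nrow(merged) == 0L) stop("no overlapping rows between the two inputs")
  combos <- unique(merged[c("parameter", "condition")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- merged[merged$parameter == combos$parameter[i] &
                  merged$condition == combos$condition[i], ]
    if (nrow(sub) < 3L) next
    m <- cbind(ref = sub$value_ref, cand = sub$value_cand)
    i1k <- icc(m, "1,k"); i2k <- icc(m, "2,k"); i3k <- icc(m, "3,k")
    al <- cronbach_alpha(m)
    reg <- tryCatch(validity_regression(sub$value_cand, sub$value_ref),
                    error = function(e) NULL)
    ba <- bland_altman(sub$value_ref, sub$value_cand)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = combos$parameter[i], condition = combos$condition[i],
      n = nrow(sub),
      mean_ref = mean(sub$value_ref), sd_ref = sd(sub$value_ref),
      mean_cand = mean(sub$value_cand), sd_cand = sd(sub$value_cand),
      diff = mean(sub$value_cand) - mean(sub$value_ref),
      icc1k = i1k$estimate, icc2k = i2k$estimate,
      icc2k_lo = i2k$ci95[1], icc2k_hi = i2k$ci95[2],
      icc3k = i3k$estimate, icc3k_lo = i3k$ci95[1], icc3k_hi = i3k$ci95[2],
      icc3k_label = i3k$label,
      alpha = al$alpha,
      slope = if (is.null(reg)) NA_real_ else reg$slope,
      constant = if (is.null(reg)) NA_real_ else reg$constant,
      slope_lo = if (is.null(reg)) NA_real_ else reg$ci95_slope[1],
      slope_hi = if (is.null(reg)) NA_real_ else reg$ci95_slope[2],
      r_squared = if (is.null(reg)) NA_real_ else reg$r_squared,
      bias = ba$bias, bias_lo = ba$ci95_bias[1], bias_hi = ba$ci95_bias[2],
      p_bias = ba$p_bias, loa_lo = ba$loa[1], loa_hi = ba$loa[2],
      prop_equation = sprintf("y = %.3fx %+.3f (p = %.3f)", ba$prop_slope,
                              ba$prop_intercept, ba$p_prop),
      prop_slope = ba$prop_slope, p_prop = ba$p_prop,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out, file.path(output_dir, "agreement.csv"), row.names = FALSE)
  }
  out
}

#' Per-trial parameter means for system comparison
#'
#' Collapses per-cycle extraction results to one value per subject,
#' condition and parameter (mean over cycles of both sides), the long
#' layout [run_compare()] consumes.
#'
#' @param results per-cycle results from [run_extract()].
#' @param params parameter columns to keep.
#' @return data.frame with `subject`, `condition`, `parameter`, `value`.
#' @export
summarize_trials <- function(results,
                             params = c("stride_time_s", "stride_length_mm",
                                        "step_length_mm", "gait_speed_mps",
                                        "hip_flexion_peak",
                                        "hip_extension_peak",
                                        "knee_flexion_peak",
                                        "knee_extension_peak", "tla_peak")) {
  params <- intersect(params, names(results))
  rows <- list()
  for (p in params) {
    ag <- stats::aggregate(results[[p]],
                           by = list(subject = results$subject,
                                     condition = results$condition),
                           FUN = function(v) mean(v[is.finite(v)]))
    rows[[length(rows) + 1L]] <- data.frame(
      subject = ag$subject, condition = ag$condition, parameter = p,
      value = ag$x, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
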