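interp_at <- function(time, values, t) {
  ok <- is.finite(time) & is.finite(values)
  approx(time[ok], values[ok], xout = t, rule = 2)$y
}

#' Per-cycle spatiotemporal gait parameters
#'
#' For each valid cycle: stride time (cycle duration), stride length
#' (forward displacement of the ipsilateral heel between this cycle's heel
#' contact and the next ipsilateral contact, mm), step length (forward
#' distance from this ipsilateral contact position to the next
#' contralateral contact position, mm), and gait speed (forward mid-hip
#' displacement across the cycle divided by the stride time, m/s). Heel
#' positions at contact times are linearly interpolated between frames.
#' Metrics whose "next contact" falls beyond the recording are NA for the
#' final cycle.
#'
#' @param series_world a metric sagittal [keypoint_series()].
#' @param cycles a `gait_cycles` data.frame from [segment_cycles()] (one
#'   side, or both sides row-bound).
#' @param contacts named list with elements `L` and `R`: heel-contact time
#'   vectors from [detect_heel_contacts()].
#' @return data.frame with one row per valid cycle: `side`, `cycle`,
#'   `stride_time_s`, `stride_length_mm`, `step_length_mm`,
#'   `gait_speed_mps`.
#' @export
stride_metrics <- function(series_world, cycles, contacts) {
  cyc <- cycles[cycles$valid, , drop = FALSE]
  if (nrow(cyc) == 0L) stop("no valid cycles")
  midhip <- if ("MidHip" %in% series_world$nodes) "MidHip" else
    node_for(series_world, cyc$side[1], "hip")
  out <- data.frame(
    side = cyc$side, cycle = cyc$cycle,
    stride_time_s = cyc$duration,
    stride_length_mm = NA_real_, step_length_mm = NA_real_,
    gait_speed_mps = NA_real_, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(cyc))) {
    side <- cyc$side[i]
    other <- if (side == "L") "R" else "L"
    heel <- node_for(series_world, side, "heel")
    heel_c <- node_for(series_world, other, "heel")
    tc <- cyc$heel_contact[i]
    # next ipsilateral contact after this one
    nxt <- contacts[[side]][contacts[[side]] > tc + 1e-9]
    if (length(nxt) > 0) {
      x0 <- interp_at(series_world$time, series_world$x[, heel], tc)
      x1 <- interp_at(series_world$time, series_world$x[, heel], nxt[1])
      out$stride_length_mm[i] <- (x1 - x0) * 1000
    }
    # next contralateral contact
    nxt_c <- contacts[[other]][contacts[[other]] > tc + 1e-9]
    if (length(nxt_c) > 0) {
      x0 <- interp_at(series_world$time, series_world$x[, heel], tc)
      xc <- interp_at(series_world$time, series_world$x[, heel_c], nxt_c[1])
      out$step_length_mm[i] <- (xc - x0) * 1000
    }
    xh0 <- interp_at(series_world$time, series_world$x[, midhip], cyc$t_start[i])
    xh1 <- interp_at(series_world$time, series_world$x[, midhip], cyc$t_end[i])
    out$gait_speed_mps[i] <- (xh1 - xh0) / cyc$duration[i]
  }
  out
}

#' Aggregate per-cycle parameters by side
#'
#' Per-side mean and SD over valid cycles for each parameter, plus a pooled
#' `LR` row per parameter: the LR mean is the unweighted mean of the two
#' side means and the LR SD is pooled over all cycles of both sides. If one
#' side has no cycles the LR row falls back to the present side with a
#' warning.
#'
#' @param cycle_metrics data.frame from [stride_metrics()] (or any
#'   per-cycle table with a `side` column and numeric parameter columns).
#' @param params parameter column names (default: all numeric columns
#'   except `cycle`).
#' @return data.frame with columns `parameter`, `side` (`L`, `R`, `LR`),
#'   `mean`, `sd`, `n`.
#' @export
aggregate_sides <- function(cycle_metrics, params = NULL) {
  if (is.null(params)) {
    num <- vapply(cycle_metrics, is.numeric, logical(1))
    params <- setdiff(names(cycle_metrics)[num], c("cycle"))
  }
  rows <- list()
  for (p in params) {
    vals <- list(L = cycle_metrics[[p]][cycle_metrics$side == "L"],
                 R = cycle_metrics[[p]][cycle_metrics$side == "R"])
    vals <- lapply(vals, function(v) v[is.finite(v)])
    for (s in c("L", "R")) {
      v <- vals[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, side = s,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) sd(v) else if (length(v) == 1L) 0 else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
    both <- c(vals$L, vals$R)
    have <- c(length(vals$L) > 0, length(vals$R) > 0)
    lr_mean <- if (all(have)) {
      (mean(vals$L) + mean(vals$R)) / 2
    } else if (any(have)) {
      warning("parameter ", p, ": one side has no cycles; LR falls back to ",
              c("L", "R")[have])
      mean(both)
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = p, side = "LR", mean = lr_mean,
      sd = if (length(both) > 1L) sd(both) else if (length(both) == 1L) 0 else NA_real_,
      n = length(both), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Between-system difference of a parameter mean
#'
#' `candidate_mean - reference_mean`, optionally rounded to a reporting
#' precision. The direction is explicit in the argument order; the opposite
#' convention (reference minus candidate, as in Bland–Altman bias) is
#' obtained by swapping arguments.
#'
#' @param candidate_mean candidate-system mean.
#' @param reference_mean reference-system mean (same parameter and units).
#' @param digits optional number of decimals for reporting.
#' @return numeric difference.
#' @export
system_difference <- function(candidate_mean, reference_mean, digits = NULL) {
  d <- candidate_mean - reference_mean
  if (!is.null(digits)) d <- round(d, digits)
  d
}
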