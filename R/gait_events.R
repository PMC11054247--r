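node_for <- function(series, side, what) {
  cand <- switch(what,
    hip = c(paste0(side, "Hip"), "MidHip"),
    knee = paste0(side, "Knee"),
    ankle = paste0(side, "Ankle"),
    heel = c(paste0(side, "Heel"), paste0(side, "Ankle")),
    toe = c(paste0(side, "BigToe"), paste0(side, "Ankle")),
    stop("unknown node role: ", what))
  hit <- cand[cand %in% series$nodes]
  if (length(hit) == 0L) stop("series lacks a ", what, " node for side ", side)
  hit[1]
}

#' Forward ankle-under-hip crossing times
#'
#' The gait-cycle start events: times at which the horizontal offset
#' `d(t) = x_ankle - x_hip` of the given side crosses zero from negative to
#' positive (the swing-phase ankle passing under the hip moving forward).
#' Crossings are sub-frame localised by linear interpolation between the
#' bracketing samples; an exact-zero sample counts as the crossing time
#' itself. Crossings closer together than `min_cycle_gap` are merged,
#' keeping the first.
#'
#' @param series_world a metric sagittal [keypoint_series()]
#'   (`units = "m"`).
#' @param side `"L"` or `"R"`.
#' @param min_cycle_gap minimum separation between crossings in s
#'   (default 0.4).
#' @return numeric vector of crossing times (s), possibly empty.
#' @export
ankle_hip_crossings <- function(series_world, side, min_cycle_gap = 0.4) {
  ankle <- node_for(series_world, side, "ankle")
  hip <- node_for(series_world, side, "hip")
  d <- series_world$x[, ankle] - series_world$x[, hip]
  t <- series_world$time
  ok <- is.finite(d)
  if (sum(ok) < 2L) stop("fewer than 2 usable frames for side ", side)
  d <- d[ok]; t <- t[ok]
  times <- numeric(0)
  for (i in seq_len(length(d) - 1L)) {
    if (d[i] < 0 && d[i + 1] > 0) {
      times <- c(times, t[i] + (t[i + 1] - t[i]) * (-d[i]) / (d[i + 1] - d[i]))
    } else if (d[i] == 0) {
      # exact-zero sample: the crossing time is that sample; at the series
      # start the history is taken as approaching from behind
      prev <- if (i > 1L) d[i - 1L] else -Inf
      if (prev < 0 && d[i + 1] > 0)
        times <- c(times, t[i])
    }
  }
  if (length(times) > 1L) {
    keep <- times[1]
    for (tt in times[-1]) if (tt - keep[length(keep)] >= min_cycle_gap)
      keep <- c(keep, tt)
    times <- keep
  }
  times
}

#' Kinematic heel-contact detection
#'
#' Heel contacts are local minima of the heel's vertical position that
#' coincide (within `match_window` seconds) with the heel's forward
#' velocity dropping below `vel_frac` of its trial maximum — the heel is
#' both low and nearly stationary at contact. Minima closer together than
#' `min_separation` are clustered and the lowest kept.
#'
#' @param series_world a metric sagittal [keypoint_series()].
#' @param side `"L"` or `"R"`.
#' @param vel_frac forward-velocity gate as a fraction of the trial maximum
#'   (default 0.2).
#' @param match_window max time between the height minimum and the velocity
#'   drop (default 0.1 s).
#' @param min_separation cycle-scale clustering window in s (default 0.4).
#' @return numeric vector of contact times (s), possibly empty.
#' @export
detect_heel_contacts <- function(series_world, side, vel_frac = 0.2,
                                 match_window = 0.1, min_separation = 0.4) {
  heel <- node_for(series_world, side, "heel")
  y <- series_world$y[, heel]
  x <- series_world$x[, heel]
  t <- series_world$time
  ok <- is.finite(y) & is.finite(x)
  if (sum(ok) < 3L) return(numeric(0))
  y <- y[ok]; x <- x[ok]; t <- t[ok]
  n <- length(y)
  # forward velocity, central differences
  vx <- c(NA_real_, (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]), NA_real_)
  vmax <- max(vx, na.rm = TRUE)
  if (!is.finite(vmax) || vmax <= 0) return(numeric(0))
  # strict-on-one-side local minima of heel height
  i <- 2:(n - 1)
  is_min <- y[i] <= y[i - 1] & y[i] <= y[i + 1] & (y[i] < y[i - 1] | y[i] < y[i + 1])
  cand <- i[is_min]
  if (length(cand) == 0L) return(numeric(0))
  slow <- vapply(cand, function(j) {
    win <- which(abs(t - t[j]) <= match_window)
    any(vx[win] < vel_frac * vmax, na.rm = TRUE)
  }, logical(1))
  cand <- cand[slow]
  if (length(cand) == 0L) return(numeric(0))
  # cluster by min_separation, keep the lowest heel in each cluster
  contacts <- integer(0)
  cluster <- cand[1]
  for (j in cand[-1]) {
    if (t[j] - t[cluster[length(cluster)]] < min_separation) {
      cluster <- c(cluster, j)
    } else {
      contacts <- c(contacts, cluster[which.min(y[cluster])])
      cluster <- j
    }
  }
  contacts <- c(contacts, cluster[which.min(y[cluster])])
  t[contacts]
}

#' Segment gait cycles from crossing and contact events
#'
#' One cycle per consecutive pair of ipsilateral ankle-under-hip crossings.
#' A cycle is invalid if its duration lies outside `duration_range`, it
#' lacks an ipsilateral heel contact, or it overlaps a data-gap span.
#'
#' @param side `"L"` or `"R"`.
#' @param crossings ipsilateral crossing times from
#'   [ankle_hip_crossings()] (needs at least 2).
#' @param contacts_ipsi ipsilateral heel-contact times.
#' @param contacts_contra contralateral heel-contact times (stored for
#'   step-length computation; may be empty).
#' @param duration_range valid cycle duration window in s (default
#'   `c(0.4, 2.5)`).
#' @param gap_spans optional data.frame with columns `t0`, `t1` of time
#'   spans invalidated by long data gaps.
#' @return data.frame of class `gait_cycles`: one row per cycle with
#'   `side`, `t_start`, `t_end`, `duration`, `heel_contact`,
#'   `contra_contact`, `valid`, `reason`.
#' @export
segment_cycles <- function(side, crossings, contacts_ipsi = numeric(0),
                           contacts_contra = numeric(0),
                           duration_range = c(0.4, 2.5), gap_spans = NULL) {
  if (length(crossings) < 2L)
    stop("need at least 2 crossings to form a cycle (got ",
         length(crossings), ")")
  nc <- length(crossings) - 1L
  out <- data.frame(
    side = rep(side, nc),
    cycle = seq_len(nc),
    t_start = crossings[-length(crossings)],
    t_end = crossings[-1],
    duration = diff(crossings),
    heel_contact = NA_real_,
    contra_contact = NA_real_,
    valid = TRUE, reason = "", stringsAsFactors = FALSE
  )
  for (i in seq_len(nc)) {
    hc <- contacts_ipsi[contacts_ipsi >= out$t_start[i] &
                        contacts_ipsi < out$t_end[i]]
    if (length(hc) > 0) out$heel_contact[i] <- hc[1]
    cc <- contacts_contra[contacts_contra >= out$t_start[i] &
                          contacts_contra < out$t_end[i]]
    if (length(cc) > 0) out$contra_contact[i] <- cc[1]
    if (out$duration[i] < duration_range[1] ||
        out$duration[i] > duration_range[2]) {
      out$valid[i] <- FALSE; out$reason[i] <- "duration"
    } else if (is.na(out$heel_contact[i])) {
      out$valid[i] <- FALSE; out$reason[i] <- "no heel contact"
    } else if (!is.null(gap_spans) && nrow(gap_spans) > 0 &&
               any(gap_spans$t0 < out$t_end[i] &
                   gap_spans$t1 > out$t_start[i])) {
      out$valid[i] <- FALSE; out$reason[i] <- "data gap"
    }
  }
  class(out) <- c("gait_cycles", "data.frame")
  out
}

#' Phase of a time point within a gait cycle
#'
#' `100 * (t - t_start) / (t_end - t_start)`, the percent-of-cycle scale on
#' which peak phases are reported (0 at the ankle-under-hip crossing).
#'
#' @param t time in s, `t_start <= t < t_end`.
#' @param t_start,t_end cycle boundaries in s.
#' @return phase in percent, in [0, 100).
#' @export
phase_of <- function(t, t_start, t_end) {
  stopifnot(t_end > t_start)
  if (any(t < t_start | t >= t_end))
    stop("t outside the cycle [t_start, t_end)")
  100 * (t - t_start) / (t_end - t_start)
}

#' Time spans of long data gaps for a set of nodes
#'
#' Returns the time intervals over which any of the given nodes is missing,
#' for invalidating overlapping cycles.
#'
#' @param series a [keypoint_series()].
#' @param nodes node names to check (default all).
#' @return data.frame with columns `t0`, `t1` (possibly zero rows).
#' @export
find_gap_spans <- function(series, nodes = series$nodes) {
  nodes <- intersect(nodes, series$nodes)
  miss <- rowSums(is.na(series$x[, nodes, drop = FALSE]) |
                  is.na(series$y[, nodes, drop = FALSE])) > 0
  if (!any(miss)) return(data.frame(t0 = numeric(0), t1 = numeric(0)))
  runs <- rle(miss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  w <- which(runs$values)
  data.frame(t0 = series$time[starts[w]], t1 = series$time[ends[w]])
}
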