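#' Construct a keypoint series
#'
#' A `keypoint_series` holds time-ordered 2D keypoints from one camera as
#' three frames-by-nodes matrices (`x`, `y`, `conf`), plus the frame rate and
#' trial metadata. Undetected points are `NA` in `x`/`y`. Coordinates are in
#' pixels as read; pipeline stages that convert to metres set
#' `units = "m"`.
#'
#' @param x,y numeric frames-by-nodes matrices of coordinates.
#' @param conf matrix of per-point confidences in [0, 1]; `NA` where unknown.
#' @param frame_rate frames per second (> 0).
#' @param nodes node names (defaults to `colnames(x)`).
#' @param frame_index integer frame indices (default `0:(n-1)`).
#' @param camera_id `"side"` or `"front"`.
#' @param subject_height subject stature in cm (may be `NA`).
#' @param trial_id,subject_id,condition trial metadata labels; `condition`
#'   is one of `"com"`, `"max"`, `"tandem"` or `NA`.
#' @param units `"px"` (raw) or `"m"` (converted to real space).
#' @return object of class `keypoint_series`.
#' @export
keypoint_series <- function(x, y, conf = NULL, frame_rate,
                            nodes = colnames(x), frame_index = NULL,
                            camera_id = "side", subject_height = NA_real_,
                            trial_id = NA_character_,
                            subject_id = NA_character_,
                            condition = NA_character_, units = "px") {
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(conf)) conf <- matrix(1, nrow(x), ncol(x))
  conf <- as.matrix(conf)
  stopifnot(identical(dim(x), dim(y)), identical(dim(x), dim(conf)))
  if (nrow(x) < 2L) stop("a keypoint series needs at least 2 frames")
  if (!is.numeric(frame_rate) || frame_rate <= 0) stop("frame_rate must be > 0")
  if (is.null(nodes)) stop("node names are required")
  colnames(x) <- colnames(y) <- colnames(conf) <- nodes
  if (is.null(frame_index)) frame_index <- seq_len(nrow(x)) - 1L
  if (anyDuplicated(frame_index)) stop("duplicate frame index")
  o <- order(frame_index)
  structure(
    list(x = x[o, , drop = FALSE], y = y[o, , drop = FALSE],
         conf = conf[o, , drop = FALSE], nodes = nodes,
         frame_index = as.integer(frame_index[o]),
         time = as.integer(frame_index[o]) / frame_rate,
         frame_rate = frame_rate, camera_id = camera_id,
         subject_height = subject_height, trial_id = trial_id,
         subject_id = subject_id, condition = condition, units = units),
    class = "keypoint_series"
  )
}

#' @export
print.keypoint_series <- function(x, ...) {
  cat(sprintf("<keypoint_series> %d frames @ %g Hz, %d nodes [%s], camera %s, units %s\n",
              nrow(x$x), x$frame_rate, length(x$nodes),
              paste(utils::head(x$nodes, 4), collapse = ","),
              x$camera_id, x$units))
  invisible(x)
}

n_frames <- function(series) nrow(series$x)

#' Read per-frame keypoint files or a long-format CSV
#'
#' Accepts either a directory of per-frame JSON files in the OpenPose
#' BODY_25 output dialect (a `people` array whose first entry carries a flat
#' `pose_keypoints_2d` vector of x, y, confidence triples) or a single
#' long-format CSV with columns `frame, node, x, y, confidence`. Points with
#' confidence 0 (the estimator's "not detected" convention) are flagged
#' missing. More than one detected person in a frame is an error.
#'
#' @param path directory of `*.json` frame files, or a `.csv` file.
#' @param frame_rate frames per second of the recording.
#' @param nodes node subset to retain (default [GAIT_NODES] superset rule:
#'   any recognised node present is kept if listed here).
#' @param ... metadata passed to [keypoint_series()] (`camera_id`,
#'   `subject_height`, `trial_id`, `subject_id`, `condition`).
#' @return a [keypoint_series()].
#' @export
read_keypoint_files <- function(path, frame_rate, nodes = GAIT_NODES, ...) {
  if (length(path) != 1L || !file.exists(path))
    stop("input path does not exist: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.json$", full.names = TRUE)
    if (length(files) == 0L) stop("no .json frame files in ", path)
    idx <- vapply(files, frame_index_from_name, integer(1))
    if (anyDuplicated(idx)) stop("duplicate frame index in ", path)
    nf <- length(files)
    x <- y <- conf <- matrix(NA_real_, nf, length(nodes),
                             dimnames = list(NULL, nodes))
    for (i in seq_len(nf)) {
      kp <- read_openpose_frame(files[i])
      keep <- intersect(nodes, rownames(kp))
      x[i, keep] <- kp[keep, 1]
      y[i, keep] <- kp[keep, 2]
      conf[i, keep] <- kp[keep, 3]
    }
    miss <- is.na(conf) | conf == 0
    x[miss] <- NA_real_; y[miss] <- NA_real_
    keypoint_series(x, y, conf, frame_rate, nodes = nodes,
                    frame_index = idx, ...)
  } else {
    df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) stop("unreadable keypoint CSV: ",
                                            conditionMessage(e)))
    need <- c("frame", "node", "x", "y", "confidence")
    if (!all(need %in% names(df)))
      stop("keypoint CSV must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df[c("frame", "node")]))
      stop("duplicate frame index / node pair in ", path)
    frames <- sort(unique(df$frame))
    keep_nodes <- intersect(nodes, unique(df$node))
    if (length(keep_nodes) == 0L) stop("no recognised nodes in ", path)
    x <- y <- conf <- matrix(NA_real_, length(frames), length(keep_nodes),
                             dimnames = list(NULL, keep_nodes))
    fi <- match(df$frame, frames)
    ni <- match(df$node, keep_nodes)
    ok <- !is.na(ni)
    x[cbind(fi[ok], ni[ok])] <- df$x[ok]
    y[cbind(fi[ok], ni[ok])] <- df$y[ok]
    conf[cbind(fi[ok], ni[ok])] <- df$confidence[ok]
    miss <- is.na(conf) | conf == 0
    x[miss] <- NA_real_; y[miss] <- NA_real_
    keypoint_series(x, y, conf, frame_rate, nodes = keep_nodes,
                    frame_index = frames, ...)
  }
}

frame_index_from_name <- function(f) {
  m <- regmatches(basename(f), gregexpr("[0-9]+", basename(f)))[[1]]
  if (length(m) == 0L) stop("cannot parse a frame index from file name: ", f)
  as.integer(m[length(m)])
}

read_openpose_frame <- function(file) {
  j <- tryCatch(jsonlite::read_json(file, simplifyVector = TRUE),
                error = function(e) stop("unreadable frame file ", file, ": ",
                                         conditionMessage(e)))
  people <- j$people
  np <- if (is.data.frame(people)) nrow(people) else length(people)
  if (np == 0L) {
    kp <- matrix(NA_real_, length(BODY25_NODES), 3,
                 dimnames = list(BODY25_NODES, c("x", "y", "conf")))
    return(kp)
  }
  if (np > 1L) stop("more than one person detected in ", file)
  flat <- if (is.data.frame(people)) unlist(people$pose_keypoints_2d[1])
          else unlist(people[[1]]$pose_keypoints_2d)
  if (length(flat) != 3L * length(BODY25_NODES))
    stop("malformed pose_keypoints_2d in ", file,
         " (expected ", 3L * length(BODY25_NODES), " values)")
  kp <- matrix(flat, ncol = 3, byrow = TRUE,
               dimnames = list(BODY25_NODES, c("x", "y", "conf")))
  kp
}

#' Write a keypoint series as a long-format CSV
#'
#' Columns `frame, node, x, y, confidence`; coordinates are written at 17
#' significant digits so that [read_keypoint_files()] round-trips them
#' bit-exactly. Missing points are written with confidence 0 and coordinates
#' 0 (the estimator's own convention).
#'
#' @param series a [keypoint_series()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_keypoint_series <- function(series, path) {
  nf <- n_frames(series)
  nn <- length(series$nodes)
  fmt <- function(v) sprintf("%.17g", v)
  x <- as.vector(t(series$x)); y <- as.vector(t(series$y))
  cf <- as.vector(t(series$conf))
  miss <- is.na(x) | is.na(y)
  x[miss] <- 0; y[miss] <- 0; cf[miss] <- 0
  cf[is.na(cf)] <- 0
  df <- data.frame(
    frame = rep(series$frame_index, each = nn),
    node = rep(series$nodes, nf),
    x = fmt(x), y = fmt(y), confidence = fmt(cf),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Confidence-gate and gap-fill a keypoint series
#'
#' Points with confidence below `confidence_threshold` become missing.
#' Interior missing runs of length at most `max_gap_frames` are filled by
#' per-coordinate linear interpolation; longer runs (and leading/trailing
#' runs) stay missing. Filled samples are given confidence equal to the
#' threshold, which marks them as interpolated and makes the operation
#' idempotent. A per-node fill report is attached as attribute
#' `"fill_report"`.
#'
#' @param series a [keypoint_series()].
#' @param confidence_threshold validity threshold in [0, 1] (default 0.3).
#' @param max_gap_frames longest interior gap to interpolate (default 5).
#' @return the cleaned [keypoint_series()] with a `fill_report` attribute
#'   (data.frame: node, n_below_threshold, n_filled, n_missing).
#' @export
clean_series <- function(series, confidence_threshold = 0.3,
                         max_gap_frames = 5L) {
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1,
            max_gap_frames >= 0)
  nf <- n_frames(series)
  report <- data.frame(node = series$nodes, n_below_threshold = 0L,
                       n_filled = 0L, n_missing = 0L,
                       stringsAsFactors = FALSE)
  for (jn in seq_along(series$nodes)) {
    cf <- series$conf[, jn]
    low <- !is.na(cf) & cf < confidence_threshold
    report$n_below_threshold[jn] <- sum(low & !is.na(series$x[, jn]))
    series$x[low, jn] <- NA_real_
    series$y[low, jn] <- NA_real_
    miss <- is.na(series$x[, jn]) | is.na(series$y[, jn])
    if (!any(miss)) next
    runs <- rle(miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      s <- starts[r]; e <- ends[r]
      interior <- s > 1L && e < nf
      if (interior && runs$lengths[r] <= max_gap_frames) {
        idx <- c(s - 1L, e + 1L)
        fill <- (s):(e)
        series$x[fill, jn] <- approx(series$time[idx], series$x[idx, jn],
                                     xout = series$time[fill])$y
        series$y[fill, jn] <- approx(series$time[idx], series$y[idx, jn],
                                     xout = series$time[fill])$y
        series$conf[fill, jn] <- confidence_threshold
        report$n_filled[jn] <- report$n_filled[jn] + runs$lengths[r]
      } else {
        report$n_missing[jn] <- report$n_missing[jn] + runs$lengths[r]
      }
    }
  }
  attr(series, "fill_report") <- report
  series
}

#' Zero-phase low-pass smoothing of a keypoint series
#'
#' Applies a 4th-order zero-phase Butterworth low-pass (a 2nd-order filter
#' run forward and backward with [signal::filtfilt()]) independently to each
#' coordinate. Each contiguous complete run of samples is filtered
#' separately; missing samples stay missing, and runs too short to filter
#' are left untouched. `cutoff_hz = NULL` is the identity.
#'
#' @param series a [keypoint_series()].
#' @param cutoff_hz cutoff frequency in Hz, `0 < cutoff_hz < frame_rate/2`,
#'   or `NULL` for no smoothing (default 6).
#' @param order effective filter order after the forward-backward pass
#'   (default 4; must be even).
#' @return the smoothed [keypoint_series()].
#' @export
smooth_series <- function(series, cutoff_hz = 6, order = 4L) {
  if (is.null(cutoff_hz)) return(series)
  nyq <- series$frame_rate / 2
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop("cutoff_hz must be in (0, frame_rate/2) = (0, ", nyq, ")")
  if (order %% 2 != 0) stop("order must be even (forward-backward pass)")
  bf <- signal::butter(order / 2, cutoff_hz / nyq, type = "low")
  # padding long enough for the filter transient to decay below ~1e-11
  r <- max(abs(polyroot(rev(bf$a))))
  pad_full <- max(3L * (order + 1L), ceiling(-25 / log(r)))
  min_len <- 3L * (order + 1L) + 1L
  # forward-backward pass with odd (mirror) edge padding: zero phase, unit
  # DC gain, and linear in the input including constant shifts
  filt_padded <- function(x) {
    n <- length(x)
    pad <- min(n - 1L, pad_full)
    head_pad <- 2 * x[1] - x[(pad + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
    y <- as.numeric(signal::filter(bf, c(head_pad, x, tail_pad)))
    y <- rev(as.numeric(signal::filter(bf, rev(y))))
    y[(pad + 1):(pad + n)]
  }
  smooth_col <- function(v) {
    miss <- is.na(v)
    runs <- rle(!miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      if (runs$lengths[r] >= min_len) {
        seg <- starts[r]:ends[r]
        v[seg] <- filt_padded(v[seg])
      }
    }
    v
  }
  series$x <- apply(series$x, 2, smooth_col)
  series$y <- apply(series$y, 2, smooth_col)
  series
}

#' Write per-trial gait results to CSV
#'
#' One row per gait cycle per side with the spatiotemporal and kinematic
#' summary fields. An empty result set produces a header-only file with a
#' warning.
#'
#' @param trial_results data.frame of per-cycle results (one row per cycle
#'   per side).
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial_results, path) {
  if (nrow(trial_results) == 0L)
    warning("empty result set: writing header-only file")
  num <- vapply(trial_results, is.numeric, logical(1))
  out <- trial_results
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  tryCatch(write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}
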