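#' Camera calibration parameters
#'
#' Intrinsics, Brown–Conrady distortion coefficients, a perspective
#' correction homography and the scene constants needed to convert side
#' camera pixels to metric sagittal coordinates: the camera-to-walking-path
#' depth (default 1.5 m) and the centre-of-lens height above the walking
#' surface (default 0.805 m). `stitch_offset` is the vertical pixel offset
#' applied to points imaged in the lower field of a two-field stitched
#' camera.
#'
#' @param fx,fy focal lengths in px (> 0).
#' @param cx,cy principal point in px.
#' @param dist distortion coefficients `c(k1, k2, p1, p2, k3)`.
#' @param homography invertible 3x3 perspective-correction matrix.
#' @param depth_to_path side-camera-to-path-centre distance in m.
#' @param lens_height centre-of-lens height above the floor in m.
#' @param stitch_offset vertical px offset for lower-field points.
#' @return object of class `camera_calibration`.
#' @export
camera_calibration <- function(fx = 1200, fy = 1200, cx = 960, cy = 600,
                               dist = c(0, 0, 0, 0, 0),
                               homography = diag(3),
                               depth_to_path = 1.5, lens_height = 0.805,
                               stitch_offset = 0) {
  stopifnot(fx > 0, fy > 0, length(dist) == 5, depth_to_path > 0)
  homography <- matrix(as.numeric(homography), 3, 3)
  if (abs(det(homography)) <= 1e-12) stop("homography is not invertible")
  structure(
    list(fx = fx, fy = fy, cx = cx, cy = cy,
         dist = setNames(as.numeric(dist), c("k1", "k2", "p1", "p2", "k3")),
         homography = homography, depth_to_path = depth_to_path,
         lens_height = lens_height, stitch_offset = stitch_offset),
    class = "camera_calibration"
  )
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat(sprintf("<camera_calibration> fx=%g fy=%g c=(%g,%g) depth=%gm lens=%gm k1=%g\n",
              x$fx, x$fy, x$cx, x$cy, x$depth_to_path, x$lens_height,
              x$dist["k1"]))
  invisible(x)
}

#' Read a calibration config file
#'
#' YAML file whose keys match the [camera_calibration()] fields (units: px
#' for intrinsics, m for `depth_to_path` and `lens_height`); `homography`
#' may be a flat length-9 row-major vector.
#'
#' @param path YAML file path.
#' @return a [camera_calibration()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$homography))
    cfg$homography <- matrix(as.numeric(unlist(cfg$homography)), 3, 3,
                             byrow = TRUE)
  if (!is.null(cfg$dist)) cfg$dist <- as.numeric(unlist(cfg$dist))
  do.call(camera_calibration, cfg)
}

as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2, byrow = FALSE,
                                   nrow = length(p) / 2)
  as.matrix(p)
}

#' Forward Brown–Conrady distortion of ideal pixel points
#'
#' Maps ideal (distortion-free) pixel coordinates to the distorted pixel
#' coordinates the lens would record. This is the forward model inverted by
#' [undistort_point()]; the synthetic walker uses it to emulate a real lens.
#'
#' @param p point(s): length-2 vector or n x 2 matrix of (u, v) px.
#' @param calibration a [camera_calibration()].
#' @return matrix of distorted points, same shape as `p` (n x 2).
#' @export
distort_point <- function(p, calibration) {
  p <- as_points(p)
  d <- calibration$dist
  xn <- (p[, 1] - calibration$cx) / calibration$fx
  yn <- (p[, 2] - calibration$cy) / calibration$fy
  r2 <- xn^2 + yn^2
  radial <- 1 + d["k1"] * r2 + d["k2"] * r2^2 + d["k3"] * r2^3
  xd <- xn * radial + 2 * d["p1"] * xn * yn + d["p2"] * (r2 + 2 * xn^2)
  yd <- yn * radial + d["p1"] * (r2 + 2 * yn^2) + 2 * d["p2"] * xn * yn
  cbind(u = xd * calibration$fx + calibration$cx,
        v = yd * calibration$fy + calibration$cy)
}

#' Undistort pixel points (inverse Brown–Conrady)
#'
#' Returns the ideal pixel coordinate whose forward distortion reproduces
#' the observed point, by fixed-point iteration on the normalised
#' coordinates (the standard compensation loop), run until the pixel-space
#' update falls below `tol` or `max_iter` is reached.
#'
#' @param p observed point(s): length-2 vector or n x 2 matrix (u, v) px.
#' @param calibration a [camera_calibration()].
#' @param tol convergence tolerance in px (default 1e-8).
#' @param max_iter iteration cap (default 50).
#' @return matrix of undistorted points (n x 2).
#' @export
undistort_point <- function(p, calibration, tol = 1e-8, max_iter = 50L) {
  p <- as_points(p)
  d <- calibration$dist
  xd <- (p[, 1] - calibration$cx) / calibration$fx
  yd <- (p[, 2] - calibration$cy) / calibration$fy
  x <- xd; y <- yd
  scale <- max(calibration$fx, calibration$fy)
  for (it in seq_len(max_iter)) {
    r2 <- x^2 + y^2
    radial <- 1 + d["k1"] * r2 + d["k2"] * r2^2 + d["k3"] * r2^3
    dx <- 2 * d["p1"] * x * y + d["p2"] * (r2 + 2 * x^2)
    dy <- d["p1"] * (r2 + 2 * y^2) + 2 * d["p2"] * x * y
    x_new <- (xd - dx) / radial
    y_new <- (yd - dy) / radial
    step <- sqrt((x_new - x)^2 + (y_new - y)^2) * scale
    x <- x_new; y <- y_new
    if (all(is.finite(step)) && max(step) < tol) {
      return(cbind(u = x * calibration$fx + calibration$cx,
                   v = y * calibration$fy + calibration$cy))
    }
  }
  bad <- which(!is.finite(step) | step >= tol)[1]
  stop(sprintf("undistortion did not converge for point (%.2f, %.2f)",
               p[bad, 1], p[bad, 2]))
}

#' Apply a homography to pixel points
#'
#' Standard projective mapping with homogeneous normalisation.
#'
#' @param p point(s): length-2 vector or n x 2 matrix (u, v) px.
#' @param H invertible 3x3 matrix.
#' @return matrix of mapped points (n x 2).
#' @export
apply_homography <- function(p, H) {
  p <- as_points(p)
  q <- cbind(p, 1) %*% t(H)
  w <- q[, 3]
  if (any(is.finite(w) & abs(w) < 1e-12))
    stop("homography maps a point to infinity (w ~ 0)")
  cbind(u = q[, 1] / w, v = q[, 2] / w)
}

#' Convert side-camera pixels to sagittal real-space coordinates
#'
#' Pinhole scaling at the fixed camera-to-path depth: forward position
#' `x = (u - cx) * depth_to_path / fx + rail_offset` and height
#' `y = lens_height - (v - cy) * depth_to_path / fy` (image v grows
#' downward, world y up with 0 at the walking surface). Points must already
#' be undistorted and perspective-corrected.
#'
#' @param p point(s): length-2 vector or n x 2 matrix (u, v) px.
#' @param calibration a [camera_calibration()].
#' @param rail_offset forward camera-rail position in m (scalar or one per
#'   point; default 0, static camera).
#' @return matrix with columns `x`, `y` in metres (sagittal plane).
#' @export
side_to_world <- function(p, calibration, rail_offset = 0) {
  p <- as_points(p)
  Z <- calibration$depth_to_path
  cbind(x = (p[, 1] - calibration$cx) * Z / calibration$fx + rail_offset,
        y = calibration$lens_height - (p[, 2] - calibration$cy) * Z / calibration$fy)
}

#' Project sagittal real-space coordinates to ideal side-camera pixels
#'
#' Exact inverse of [side_to_world()]; the synthetic walker's projection
#' model.
#'
#' @param p_world matrix with columns `x`, `y` in metres.
#' @inheritParams side_to_world
#' @return matrix of ideal pixel points (n x 2).
#' @export
world_to_side <- function(p_world, calibration, rail_offset = 0) {
  p <- as_points(p_world)
  Z <- calibration$depth_to_path
  cbind(u = (p[, 1] - rail_offset) * calibration$fx / Z + calibration$cx,
        v = (calibration$lens_height - p[, 2]) * calibration$fy / Z + calibration$cy)
}

#' Convert front-camera pixels to frontal real-space coordinates
#'
#' Metric scale from the subject's stature: `scale = stature_m /
#' stature_px`, where `stature_px` is the pixel span between the reference
#' nodes (head/neck to heel or ankle) in the frame. Lateral position is
#' measured from the image centre.
#'
#' @param p point(s): length-2 vector or n x 2 matrix (u, v) px.
#' @param calibration a [camera_calibration()].
#' @param subject_height_cm subject stature in cm.
#' @param stature_px pixel span of the reference nodes (> 0).
#' @return matrix with columns `x` (lateral, m, from image centre) and `y`
#'   (height above the lowest reference, m).
#' @export
front_to_world <- function(p, calibration, subject_height_cm, stature_px) {
  if (!is.finite(stature_px) || stature_px <= 0)
    stop("reference nodes missing or degenerate (stature_px = ", stature_px, ")")
  p <- as_points(p)
  scale <- (subject_height_cm / 100) / stature_px
  cbind(x = (p[, 1] - calibration$cx) * scale,
        y = (calibration$cy - p[, 2]) * scale)
}

#' Mean lateral offset from the walking-path centre line
#'
#' Averages the mid-hip lateral displacement (metres, signed) over the valid
#' frames of a frontal series.
#'
#' @param lateral_m numeric vector of per-frame mid-hip lateral positions in
#'   metres (NA for invalid frames).
#' @return mean offset in metres.
#' @export
estimate_path_offset <- function(lateral_m) {
  v <- lateral_m[is.finite(lateral_m)]
  if (length(v) == 0L) stop("no valid frontal frames")
  mean(v)
}

#' Convert a whole side-camera keypoint series to real-space coordinates
#'
#' Applies, per point: lower-field stitch offset, [undistort_point()],
#' [apply_homography()] with the calibration's perspective correction, then
#' [side_to_world()]. Missing points stay missing.
#'
#' @param series a pixel-unit [keypoint_series()] from the side camera.
#' @param calibration a [camera_calibration()].
#' @param rail_offset per-frame forward rail position in m (scalar or
#'   vector of length `n_frames`; default 0).
#' @param lower_field_nodes node names imaged in the lower camera field
#'   (their v gets `stitch_offset` added before conversion).
#' @return a [keypoint_series()] with `units = "m"` (x forward, y up).
#' @export
series_to_world <- function(series, calibration, rail_offset = 0,
                            lower_field_nodes = character()) {
  stopifnot(inherits(series, "keypoint_series"),
            inherits(calibration, "camera_calibration"))
  if (identical(series$units, "m")) return(series)
  nf <- n_frames(series)
  if (length(rail_offset) == 1L) rail_offset <- rep(rail_offset, nf)
  stopifnot(length(rail_offset) == nf)
  out <- series
  for (jn in seq_along(series$nodes)) {
    v_off <- if (series$nodes[jn] %in% lower_field_nodes)
      calibration$stitch_offset else 0
    ok <- is.finite(series$x[, jn]) & is.finite(series$y[, jn])
    if (!any(ok)) next
    px <- cbind(series$x[ok, jn], series$y[ok, jn] + v_off)
    px <- undistort_point(px, calibration)
    px <- apply_homography(px, calibration$homography)
    w <- side_to_world(px, calibration, rail_offset[ok])
    out$x[ok, jn] <- w[, 1]
    out$y[ok, jn] <- w[, 2]
  }
  out$units <- "m"
  out
}
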