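# Shared fixtures, built in code.

# Noise-free comfortable-walk trial, generated once per test run.
fixture_env <- new.env()

default_trial <- function() {
  if (is.null(fixture_env$trial))
    fixture_env$trial <- generate_trial(walker_config())
  fixture_env$trial
}

default_world <- function() {
  if (is.null(fixture_env$world))
    fixture_env$world <- series_to_world(default_trial()$side,
                                         default_calibration())
  fixture_env$world
}

# A small random pixel keypoint series for I/O round trips.
random_series <- function(n_frames = 12, nodes = c("MidHip", "RKnee",
                                                   "RAnkle"),
                          frame_rate = 60, seed = 99) {
  withr::with_seed(seed, {
    x <- matrix(runif(n_frames * length(nodes), 0, 1920), n_frames,
                dimnames = list(NULL, nodes))
    y <- matrix(runif(n_frames * length(nodes), 0, 1080), n_frames,
                dimnames = list(NULL, nodes))
    conf <- matrix(runif(n_frames * length(nodes), 0.31, 1), n_frames,
                   dimnames = list(NULL, nodes))
    keypoint_series(x, y, conf, frame_rate, nodes = nodes)
  })
}

# Write an OpenPose-dialect JSON frame file; kp is a named list of
# c(x, y, conf) triples, all other BODY_25 nodes are zero-filled.
write_openpose_frame <- function(path, kp, n_people = 1) {
  body25 <- gait2d:::BODY25_NODES
  flat <- rep(0, 3 * length(body25))
  for (nm in names(kp)) {
    i <- match(nm, body25)
    flat[(3 * i - 2):(3 * i)] <- kp[[nm]]
  }
  person <- list(pose_keypoints_2d = flat)
  obj <- list(version = 1.3, people = rep(list(person), n_people))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

# World-unit series built directly from coordinate matrices.
world_series <- function(x, y, frame_rate = 60) {
  keypoint_series(x, y, NULL, frame_rate, nodes = colnames(x), units = "m")
}
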