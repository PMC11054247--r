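test_that("per-frame JSON files are read with correct times and missing flags", {
  dir <- withr::local_tempdir()
  for (i in 0:2) {
    kp <- list(MidHip = c(960, 540, 0.9), RKnee = c(950, 700, 0.8),
               RAnkle = c(955, 860, if (i == 1) 0 else 0.7))
    write_openpose_frame(file.path(dir, sprintf("f_%012d_keypoints.json", i)),
                         kp)
  }
  s <- read_keypoint_files(dir, frame_rate = 60)
  expect_equal(n_frames <- nrow(s$x), 3)
  expect_equal(s$time, c(0, 1, 2) / 60)
  expect_equal(unname(s$x[1, "MidHip"]), 960)
  # confidence 0 means not detected
  expect_true(is.na(s$x[2, "RAnkle"]))
  expect_false(is.na(s$x[1, "RAnkle"]))
})

test_that("reader rejects multi-person frames and empty directories", {
  dir <- withr::local_tempdir()
  expect_error(read_keypoint_files(dir, 60), "no .json")
  write_openpose_frame(file.path(dir, "f_000000_keypoints.json"),
                       list(MidHip = c(1, 2, 0.9)), n_people = 2)
  expect_error(read_keypoint_files(dir, 60), "more than one person")
  expect_error(read_keypoint_files(file.path(dir, "nope"), 60),
               "does not exist")
})

test_that("duplicate frame indices are a format error", {
  dir <- withr::local_tempdir()
  write_openpose_frame(file.path(dir, "a_000001_keypoints.json"),
                       list(MidHip = c(1, 2, 0.9)))
  write_openpose_frame(file.path(dir, "b_000001_keypoints.json"),
                       list(MidHip = c(1, 2, 0.9)))
  expect_error(read_keypoint_files(dir, 60), "duplicate frame index")
})

test_that("write/read round trip reproduces coordinates bit-exactly", {
  s <- random_series()
  f <- withr::local_tempfile(fileext = ".csv")
  write_keypoint_series(s, f)
  s2 <- read_keypoint_files(f, frame_rate = s$frame_rate,
                            nodes = s$nodes)
  expect_identical(s2$x, s$x)
  expect_identical(s2$y, s$y)
  expect_identical(s2$conf, s$conf)
  expect_identical(s2$time, s$time)
})

test_that("clean_series interpolates short gaps and reports longer ones", {
  x <- matrix(c(100, NA, 102, 1:3 * 0), 3, 2,
              dimnames = list(NULL, c("RKnee", "MidHip")))
  y <- matrix(c(200, NA, 204, 1:3 * 0), 3, 2,
              dimnames = list(NULL, c("RKnee", "MidHip")))
  s <- keypoint_series(x, y, NULL, 60)
  cl <- clean_series(s, max_gap_frames = 1)
  expect_equal(unname(cl$x[2, "RKnee"]), 101)
  expect_equal(unname(cl$y[2, "RKnee"]), 202)

  # a run of max_gap_frames + 1 stays missing and is reported
  x2 <- matrix(c(1, NA, NA, 4, 5), 5, 1, dimnames = list(NULL, "RKnee"))
  s2 <- keypoint_series(x2, x2, NULL, 60)
  cl2 <- clean_series(s2, max_gap_frames = 1)
  expect_true(all(is.na(cl2$x[2:3, 1])))
  rep2 <- attr(cl2, "fill_report")
  expect_equal(rep2$n_missing[rep2$node == "RKnee"], 2)
})

test_that("gap filling matches an independent linear-interpolation oracle", {
  withr::with_seed(7, {
    n <- 200
    x <- matrix(cumsum(rnorm(n)), n, 1, dimnames = list(NULL, "RKnee"))
    y <- matrix(cumsum(rnorm(n)), n, 1, dimnames = list(NULL, "RKnee"))
    conf <- matrix(1, n, 1)
    # random dropout, runs capped at 2 by construction of the mask
    drop <- runif(n) < 0.05
    drop[1] <- drop[n] <- FALSE
    conf[drop, 1] <- 0.1
    s <- keypoint_series(x, y, conf, 60)
    cl <- clean_series(s, confidence_threshold = 0.3, max_gap_frames = 2)
    # oracle: straight-line interpolation over the kept samples
    keep <- !drop
    ox <- approx(which(keep), x[keep, 1], xout = seq_len(n))$y
    oy <- approx(which(keep), y[keep, 1], xout = seq_len(n))$y
    runs <- rle(drop)
    short <- rep(runs$lengths <= 2, runs$lengths)
    expect_lt(max(abs(cl$x[short | keep, 1] - ox[short | keep])), 1e-12)
    expect_lt(max(abs(cl$y[short | keep, 1] - oy[short | keep])), 1e-12)
  })
})

test_that("clean_series is idempotent", {
  withr::with_seed(11, {
    n <- 60
    x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("A", "B")))
    conf <- matrix(runif(n * 2), n, 2)
    s <- keypoint_series(x, x, conf, 60, nodes = c("A", "B"))
  })
  c1 <- clean_series(s)
  c2 <- clean_series(c1)
  expect_equal(c2$x, c1$x)
  expect_equal(c2$y, c1$y)
  expect_equal(c2$conf, c1$conf)
})

test_that("smoothing preserves DC, passes a 1 Hz sinusoid, rejects noise", {
  fr <- 60
  n <- 5 * fr
  t <- (0:(n - 1)) / fr
  const <- matrix(5, n, 1, dimnames = list(NULL, "A"))
  s_const <- keypoint_series(const, const, NULL, fr)
  sm <- smooth_series(s_const, cutoff_hz = 6)
  expect_equal(sm$x[, 1], const[, 1], tolerance = 1e-9)

  sine <- matrix(sin(2 * pi * 1 * t), n, 1, dimnames = list(NULL, "A"))
  s_sine <- keypoint_series(sine, sine, NULL, fr)
  sm2 <- smooth_series(s_sine, cutoff_hz = 6)
  core <- (fr / 2):(n - fr / 2)   # discard 0.5 s edges
  expect_lt(max(abs(sm2$x[core, 1] - sine[core, 1])), 0.01)

  withr::with_seed(3, noise <- rnorm(n, 0, 2))
  ramp <- matrix(seq(0, 100, length.out = n) + noise, n, 1,
                 dimnames = list(NULL, "A"))
  s_ramp <- keypoint_series(ramp, ramp, NULL, fr)
  sm3 <- smooth_series(s_ramp, cutoff_hz = 6)
  resid_in <- ramp[, 1] - seq(0, 100, length.out = n)
  resid_out <- sm3$x[, 1] - seq(0, 100, length.out = n)
  expect_lt(var(resid_out[core]), var(resid_in[core]))
})

test_that("smoothing commutes with constant offsets and validates the cutoff", {
  s <- random_series(n_frames = 120)
  sm_a <- smooth_series(s, 6)
  s_off <- s; s_off$x <- s$x + 123.4; s_off$y <- s$y - 55
  sm_b <- smooth_series(s_off, 6)
  expect_equal(sm_b$x, sm_a$x + 123.4, tolerance = 1e-9)
  expect_equal(sm_b$y, sm_a$y - 55, tolerance = 1e-9)
  expect_error(smooth_series(s, 30), "cutoff_hz")
  expect_identical(smooth_series(s, NULL), s)
})

test_that("trial CSV writer emits one row per cycle per side and round-trips", {
  res <- data.frame(side = rep(c("L", "R"), each = 4), cycle = rep(1:4, 2),
                    stride_time_s = runif(8, 0.9, 1.1),
                    stride_length_mm = runif(8, 1300, 1500))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(res, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 8)
  expect_identical(back$stride_time_s, res$stride_time_s)
  expect_warning(write_trial_csv(res[0, ], f), "empty")
  expect_equal(nrow(read.csv(f)), 0)
})
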