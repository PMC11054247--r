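sine_series <- function(fr = 60, dur = 3, period = 1) {
  t <- seq(0, dur, by = 1 / fr)
  n <- length(t)
  x <- cbind(RAnkle = sin(2 * pi * t / period), RHip = rep(0, n),
             MidHip = rep(0, n))
  y <- cbind(RAnkle = rep(0.1, n), RHip = rep(0.9, n), MidHip = rep(0.9, n))
  world_series(x, y, fr)
}

test_that("crossings of a sine ankle-hip offset are found at its upward zeros", {
  ws <- sine_series()
  cr <- ankle_hip_crossings(ws, "R")
  expect_equal(cr, c(0, 1, 2), tolerance = 1 / 120)
})

test_that("a constant-positive offset yields no crossings and short series error", {
  t <- seq(0, 2, by = 1 / 60)
  x <- cbind(RAnkle = rep(0.3, length(t)), RHip = rep(0, length(t)))
  ws <- world_series(x, x * 0 + 0.5, 60)
  expect_equal(ankle_hip_crossings(ws, "R"), numeric(0))
  x2 <- cbind(RAnkle = c(NA, NA, 1), RHip = c(0, 0, 0))
  ws2 <- world_series(x2, x2 * 0, 60)
  expect_error(ankle_hip_crossings(ws2, "R"), "fewer than 2")
})

test_that("crossing times match a dense brute-force sign-scan oracle", {
  fr <- 60
  withr::with_seed(13, {
    t <- seq(0, 10, by = 1 / fr)
    raw <- rnorm(length(t))
  })
  # band-limited offset signal (~1 Hz), amplitude well above zero noise
  bf <- signal::butter(2, 1.5 / (fr / 2))
  d <- signal::filtfilt(bf, raw) * 10
  x <- cbind(RAnkle = d, RHip = rep(0, length(t)))
  ws <- world_series(x, x * 0 + 0.5, fr)
  cr <- ankle_hip_crossings(ws, "R", min_cycle_gap = 0)
  # oracle: 10x oversampled linear interpolation, scan for sign changes
  tt <- seq(0, max(t), by = 1 / (10 * fr))
  dd <- approx(t, d, xout = tt)$y
  ups <- which(dd[-length(dd)] < 0 & dd[-1] > 0)
  oracle <- tt[ups]
  expect_equal(length(cr), length(oracle))
  expect_lt(max(abs(cr - oracle)), 1 / (2 * fr))
})

test_that("crossings are invariant to a common forward translation and merge rule holds", {
  ws <- sine_series()
  cr0 <- ankle_hip_crossings(ws, "R")
  ws2 <- ws
  ws2$x[, "RAnkle"] <- ws$x[, "RAnkle"] + 57.3
  ws2$x[, "RHip"] <- ws$x[, "RHip"] + 57.3
  expect_equal(ankle_hip_crossings(ws2, "R"), cr0, tolerance = 1e-12)
  # crossings 0.25 s apart merge at the default 0.4 s gap, keeping the first
  ws3 <- sine_series(period = 0.25, dur = 1.5)
  cr3 <- ankle_hip_crossings(ws3, "R")
  expect_true(all(diff(cr3) >= 0.4))
  expect_equal(cr3[1], 0, tolerance = 1 / 120)
})

test_that("heel contacts on the simulator are within one frame of ground truth", {
  tr <- default_trial()
  ws <- default_world()
  fr <- tr$truth$config$frame_rate
  for (s in c("L", "R")) {
    det <- detect_heel_contacts(ws, s)
    truth <- tr$truth$contacts[[s]]
    # every true contact matched by a detection within 1 frame
    for (tc in truth) expect_lt(min(abs(det - tc)), 1 / fr + 1e-9)
  }
})

test_that("standing still produces no heel contacts and drift does not move them", {
  t <- seq(0, 3, by = 1 / 60)
  n <- length(t)
  x <- cbind(RHeel = rep(1, n), RHip = rep(1, n))
  y <- cbind(RHeel = rep(0.05, n), RHip = rep(0.9, n))
  expect_equal(detect_heel_contacts(world_series(x, y, 60), "R"),
               numeric(0))
  tr <- default_trial()
  ws <- default_world()
  det0 <- detect_heel_contacts(ws, "L")
  ws2 <- ws
  ws2$x <- ws$x + 3.21   # uniform forward shift of every node
  expect_equal(detect_heel_contacts(ws2, "L"), det0, tolerance = 1e-12)
})

test_that("cycles segment by the fencepost rule with duration and contact gates", {
  cyc <- segment_cycles("L", crossings = 0:4 * 1.0,
                        contacts_ipsi = 0:3 + 0.45)
  expect_equal(nrow(cyc), 4)
  expect_true(all(cyc$valid))
  # a 3.0 s cycle is invalid with reason "duration"
  cyc2 <- segment_cycles("L", crossings = c(0, 3.0, 4.0),
                         contacts_ipsi = c(1.5, 3.5))
  expect_false(cyc2$valid[1])
  expect_equal(cyc2$reason[1], "duration")
  expect_true(cyc2$valid[2])
  # no ipsilateral contact invalidates
  cyc3 <- segment_cycles("L", crossings = c(0, 1), contacts_ipsi = numeric(0))
  expect_equal(cyc3$reason, "no heel contact")
  # overlap with a data gap invalidates
  cyc4 <- segment_cycles("L", crossings = c(0, 1, 2),
                         contacts_ipsi = c(0.4, 1.4),
                         gap_spans = data.frame(t0 = 0.5, t1 = 0.6))
  expect_false(cyc4$valid[1])
  expect_equal(cyc4$reason[1], "data gap")
  expect_true(cyc4$valid[2])
  expect_error(segment_cycles("L", crossings = 1), "at least 2")
})

test_that("cycles are disjoint half-open intervals covering the crossing span", {
  tr <- default_trial()
  ws <- default_world()
  for (s in c("L", "R")) {
    cr <- ankle_hip_crossings(ws, s)
    cyc <- segment_cycles(s, cr, detect_heel_contacts(ws, s))
    expect_equal(cyc$t_start, cr[-length(cr)])
    expect_equal(cyc$t_end, cr[-1])
    expect_equal(cyc$t_start[-1], cyc$t_end[-nrow(cyc)])
  }
})

test_that("simulator cycles match the configured stride count and time", {
  tr <- default_trial()
  ws <- default_world()
  cfg <- tr$truth$config
  for (s in c("L", "R")) {
    cyc <- segment_cycles(s, ankle_hip_crossings(ws, s),
                          detect_heel_contacts(ws, s))
    expect_equal(sum(cyc$valid), cfg$n_strides)
    expect_lt(max(abs(cyc$duration - cfg$stride_time)),
              1 / cfg$frame_rate)
  }
})

test_that("phase normalisation is linear in time with the documented bounds", {
  expect_equal(phase_of(2, 2, 4), 0)
  expect_equal(phase_of(3, 2, 4), 50)
  expect_equal(phase_of(2 + 0.709 * 2, 2, 4), 70.9)
  expect_error(phase_of(4, 2, 4), "outside")
  expect_error(phase_of(1.99, 2, 4), "outside")
})
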