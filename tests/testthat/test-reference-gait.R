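# Synthetic reference kinematics and the stride-phase convention.

test_that("implied stride length is speed times cycle duration", {
  ref <- study_reference()
  expect_equal(ref$stride_length, 1.18 * 1.21, tolerance = 1e-12)
})

test_that("trajectories are exactly periodic with matching velocities", {
  ref <- study_reference()
  a0 <- eval_reference(ref, 0)
  a100 <- eval_reference(ref, 100)
  expect_equal(a0, a100, tolerance = 1e-10)
  v0 <- eval_reference(ref, 0, deriv = 1)
  v100 <- eval_reference(ref, 100, deriv = 1)
  expect_equal(v0, v100, tolerance = 1e-10)
})

test_that("the contralateral leg is the ipsilateral pattern shifted by 50%", {
  ref <- study_reference()
  ph <- c(0, 13, 27.5, 61, 88)
  expect_equal(eval_reference(ref, ph, "left"),
               eval_reference(ref, ph + 50, "right"), tolerance = 1e-12)
})

test_that("analytic reference velocity matches finite differences", {
  ref <- study_reference()
  ph <- seq(5, 95, by = 7)
  h <- 1e-3   # percent of stride
  v <- eval_reference(ref, ph, deriv = 1)
  fd <- (eval_reference(ref, ph + h) - eval_reference(ref, ph - h)) /
    (2 * h / 100 * ref$cycle_duration)
  expect_equal(v, fd, tolerance = 1e-5)
})

test_that("phase_of implements the stride-phase convention", {
  expect_equal(phase_of(0, 1.21), 0)
  expect_equal(phase_of(1.21, 1.21), 0)
  expect_equal(phase_of(0.6413, 1.21), 53)
  expect_equal(phase_of(2.42 + 0.121, 1.21), 10, tolerance = 1e-9)
})

test_that("malformed harmonic sets are rejected", {
  expect_error(make_reference(harmonics = list(a0 = 1:3)), "a0, A, B")
  expect_error(make_reference(harmonics = list(a0 = 1:2,
                                               A = matrix(0, 2, 4),
                                               B = matrix(0, 2, 4))),
               "malformed|non-periodic")
  expect_error(make_reference(harmonics = list(a0 = c(0, 0, NA),
                                               A = matrix(0, 3, 4),
                                               B = matrix(0, 3, 4))),
               "malformed|non-periodic")
})

test_that("zero adjustment reproduces the reference", {
  ref <- study_reference()
  adj <- kinematic_adjustment()
  out <- adjust_reference(ref, adj)
  ph <- seq(0, 99, by = 3)
  expect_equal(eval_reference(out, ph), eval_reference(ref, ph),
               tolerance = 1e-12)
})

test_that("an adjustment at one ankle knot changes only the ankle trajectory", {
  ref <- study_reference()
  adj <- kinematic_adjustment(ankle = c(0.03, rep(0, 7)))
  out <- adjust_reference(ref, adj)
  ph <- seq(0, 99, by = 1)
  a <- eval_reference(out, ph); b <- eval_reference(ref, ph)
  expect_equal(a[, "hip"], b[, "hip"], tolerance = 1e-12)
  expect_equal(a[, "knee"], b[, "knee"], tolerance = 1e-12)
  expect_gt(max(abs(a[, "ankle"] - b[, "ankle"])), 0.01)
})

test_that("adjustments at the bound are attained and beyond-bound rejected", {
  bound <- 5 * pi / 180
  adj <- kinematic_adjustment(hip = rep(bound, 8), bound = bound)
  out <- adjust_reference(study_reference(), adj)
  d <- eval_reference(out, seq(0, 99, 0.5))[, "hip"] -
    eval_reference(study_reference(), seq(0, 99, 0.5))[, "hip"]
  expect_equal(max(abs(d)), bound, tolerance = 0.02)
  expect_error(kinematic_adjustment(hip = rep(bound * 1.2, 8), bound = bound),
               "bound")
})

test_that("reference kinematics survive a file round trip", {
  ref <- study_reference()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference(ref, path, n = 400)
  back <- read_reference(path)
  ph <- seq(0, 99, by = 2)
  expect_equal(eval_reference(back, ph), eval_reference(ref, ph),
               tolerance = 5e-3)
})

test_that("the baseline tracks the reference closely over steady cycles", {
  base <- baseline_sim()
  ref <- study_reference()
  d <- base$data
  sel <- d$time > base$cycle_duration
  for (j in c("hip_r", "knee_r", "ankle_r")) {
    refv <- eval_reference(ref, d$phase[sel])[, sub("_r", "", j)]
    rmse <- sqrt(mean((d[[j]][sel] - refv)^2)) * 180 / pi
    expect_lt(rmse, 2.5)   # degrees; design tolerance
  }
})
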