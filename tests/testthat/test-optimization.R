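# Five-criterion fitness, seeded GA and representative-solution selection.

test_that("self-comparison nulls the comparative fitness terms", {
  base <- baseline_sim()
  f <- fitness(base, base)
  br <- f$breakdown
  expect_equal(br[["fall"]], 0)
  expect_equal(br[["distance"]], 0)
  expect_equal(br[["torque_similarity"]], 0, tolerance = 1e-9)
  expect_gt(br[["hs_impulse"]], 0)
  expect_gt(br[["abs_power"]], 0)
  expect_equal(f$scalar, br[["hs_impulse"]] + br[["abs_power"]],
               tolerance = 1e-9)
})

test_that("a fall activates the time-to-fall penalty", {
  model <- study_model()
  ref <- study_reference()
  zero <- default_gains(hip = c(kp = 0, ki = 0, kd = 0),
                        knee = c(kp = 0, ki = 0, kd = 0),
                        ankle = c(kp = 0, ki = 0, kd = 0),
                        hat_upright = c(kp = 0, kd = 0),
                        pelvis_pitch = c(kp = 0, kd = 0))
  fallen <- cached("fallen_sim",
                   simulate_walking(model, ref, gains = zero, n_cycles = 4))
  f <- fitness(fallen, baseline_sim())
  expect_gt(f$breakdown[["fall"]], 0)
})

test_that("fitness is linear in the weights", {
  base <- baseline_sim()
  act <- active_sim()
  f1 <- fitness(act, base, fitness_weights())
  f2 <- fitness(act, base, fitness_weights(2, 2, 2, 2, 2))
  expect_equal(f2$scalar, 2 * f1$scalar, tolerance = 1e-12)
  expect_error(fitness_weights(0, 0, 0, 0, 0), "at least one")
})

test_that("mismatched time bases are rejected", {
  base <- baseline_sim()
  other <- base
  other$cycle_duration <- 1.0
  expect_error(fitness(other, base), "time base")
})

test_that("the GA is deterministic for a fixed seed", {
  fn <- function(x) sum((x - c(0.2, -0.4, 0.1))^2)
  st <- ga_settings(pop_size = 12, generations = 10)
  r1 <- ga_minimize(fn, rep(-1, 3), rep(1, 3), st, seed = 7)
  r2 <- ga_minimize(fn, rep(-1, 3), rep(1, 3), st, seed = 7)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$par, r2$par)
  r3 <- ga_minimize(fn, rep(-1, 3), rep(1, 3), st, seed = 8)
  expect_false(identical(r1$history, r3$history))
})

test_that("the GA best fitness is monotonically non-increasing (elitism)", {
  fn <- function(x) sum(abs(x)) + cos(10 * sum(x))
  r <- ga_minimize(fn, rep(-2, 5), rep(2, 5),
                   ga_settings(pop_size = 16, generations = 25), seed = 3)
  expect_true(all(diff(r$history) <= 1e-12))
})

test_that("the GA recovers a known quadratic minimizer within 5% of the bound range", {
  target <- c(0.31, -0.22, 0.05, 0.4)
  fn <- function(x) sum((x - target)^2)
  r <- ga_minimize(fn, rep(-1, 4), rep(1, 4),
                   ga_settings(pop_size = 40, generations = 60), seed = 1)
  expect_true(all(abs(r$par - target) < 0.05 * 2))
})

test_that("with the exoskeleton disabled the GA stays at the zero adjustment", {
  # fitness is already minimal at the baseline kinematics: the best scalar
  # cannot exceed the zero-adjustment fitness (the zero individual is in the
  # initial population and elitism preserves it)
  model <- study_model_exo()
  ref <- study_reference()
  base <- baseline_sim()
  st <- ga_settings(pop_size = 4, generations = 2, n_cycles = 2)
  ga <- ga_optimize(model, exo_params(enabled = FALSE), ref, base,
                    settings = st, seed = 1)
  zero_sim <- simulate_walking(model, ref,
                               exo = exo_params(enabled = FALSE), n_cycles = 2)
  f0 <- fitness(zero_sim, base)$scalar
  expect_lte(ga$value, f0 * 1.01 + 1e-9)
})

test_that("select_representative discards the outlier and returns the median", {
  mk <- function(offset) list(torque = rep(offset, 50))
  # three clustered + one distant: the distant one is the outlier
  sols <- list(mk(0), mk(1), mk(2), mk(40))
  rep_sol <- select_representative(sols)
  expect_equal(attr(rep_sol, "outlier"), 4L)
  expect_equal(rep_sol$torque[1], 1)   # the central profile of {0, 1, 2}
  # brute-force check of the outlier rule on random profiles
  set.seed(11)
  for (i in 1:10) {
    profs <- lapply(1:4, function(j) list(torque = rnorm(30)))
    dmat <- matrix(0, 4, 4)
    for (a in 1:3) for (b in (a + 1):4)
      dmat[a, b] <- dmat[b, a] <-
        sqrt(sum((profs[[a]]$torque - profs[[b]]$torque)^2))
    expect_equal(attr(select_representative(profs), "outlier"),
                 which.max(rowSums(dmat)))
  }
  expect_error(select_representative(sols[1:3]), "4 solutions")
})

test_that("four identical solutions give that common solution back", {
  sols <- replicate(4, list(torque = sin(1:40)), simplify = FALSE)
  rep_sol <- select_representative(sols)
  expect_equal(rep_sol$torque, sin(1:40))
})
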