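# The articulated 10-segment model and its dynamics core.

test_that("the default model has 10 bodies and 12 generalized coordinates", {
  model <- study_model()
  expect_length(model$bodies, 10)
  expect_length(model$coord_names, 12)
  expect_length(joint_coord_names(), 9)
  expect_equal(total_mass(model), 80, tolerance = 1e-10)
  worn <- study_model_exo()
  expect_equal(total_mass(worn) - total_mass(model), 0.8, tolerance = 1e-10)
})

test_that("invalid configurations are rejected", {
  config <- study_config()
  broken <- config
  broken$segments <- broken$segments[-3, ]
  expect_error(build_model(broken), "10 segments")
  broken <- config
  broken$joints$name[2] <- broken$joints$name[1]
  expect_error(build_model(broken), "duplicate")
  broken <- config
  broken$joints$parent[4] <- "no_such_segment"
  expect_error(build_model(broken), "topology")
  broken <- config
  broken$segments$mass[5] <- -1
  expect_error(build_model(broken), "mass")
  expect_error(segment_spec("s", mass = 1, length = 0.3, com_offset = 0.5,
                            inertia_com = 0.01), "com_offset")
})

test_that("free fall from rest gives pelvis ydd = -g and zero joint accelerations", {
  model <- study_model()
  qdd <- forward_dynamics(model, standing_state(2))
  expect_equal(qdd[2], -9.81, tolerance = 1e-12)
  expect_equal(qdd[-2], rep(0, 11), tolerance = 1e-9)
})

test_that("forward dynamics matches an independent double-pendulum oracle", {
  # thigh + shank as a pinned two-link chain; the oracle is a hand-derived
  # Lagrangian formulation in absolute angles
  Lt <- 0.441; Ls <- 0.443; m1 <- 11.3; m2 <- 3.5
  c1 <- 0.181; c2 <- 0.195; I1 <- 0.24; I2 <- 0.044; g <- 9.81
  spec <- list(parent = c(-1L, 0L), jpos = rbind(c(0, 0), c(0, -Lt)),
               com = rbind(c(0, -c1), c(0, -c2)),
               mass = c(m1, m2), icom = c(I1, I2),
               floating = FALSE, gravity = g)
  oracle <- function(q, qd, tau) {
    th2 <- q[1] + q[2]
    w1 <- qd[1]; w2 <- qd[1] + qd[2]
    A11 <- I1 + m1 * c1^2 + m2 * Lt^2
    A22 <- I2 + m2 * c2^2
    A12 <- m2 * Lt * c2 * cos(th2 - q[1])
    C <- c(-m2 * Lt * c2 * sin(th2 - q[1]) * w2^2,
           m2 * Lt * c2 * sin(th2 - q[1]) * w1^2)
    G <- c((m1 * c1 + m2 * Lt) * g * sin(q[1]), m2 * c2 * g * sin(th2))
    Tm <- rbind(c(1, 0), c(1, 1))
    qdd_abs <- solve(rbind(c(A11, A12), c(A12, A22)),
                     solve(t(Tm), tau) - C - G)
    solve(Tm, qdd_abs)
  }
  set.seed(42)
  for (i in 1:25) {
    q <- runif(2, -2, 2); qd <- runif(2, -4, 4); tau <- runif(2, -20, 20)
    a <- anextrapush:::planar_chain_accel(spec, q, qd, tau, NULL)
    b <- oracle(q, qd, tau)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("equal and opposite collinear forces on one segment cancel", {
  model <- study_model()
  y <- standing_state(1.5)
  # two points on the right thigh; forces along their connecting line
  p1 <- c(0, -0.1); p2 <- c(0, -0.3)
  f <- c(0, 250)   # the line p1-p2 is the local y axis (world y at zero pose)
  wr <- rbind(c(3, p1, f), c(3, p2, -f))
  qdd0 <- forward_dynamics(model, y)
  qdd1 <- forward_dynamics(model, y, wrenches = wr)
  expect_equal(qdd1, qdd0, tolerance = 1e-9)
})

test_that("mechanical energy is conserved in free flight", {
  model <- study_model()
  ref <- study_reference()
  y0 <- initial_state(model, ref)
  y0[2] <- y0[2] + 3
  sim <- simulate_walking(model, ref, n_cycles = 1, contact_enabled = FALSE,
                          control_enabled = FALSE, y0 = y0,
                          fall_fraction = -10)
  spec <- anextrapush:::build_ctx_spec(model, ref, contact_enabled = FALSE,
                                       control_enabled = FALSE)
  ptr <- anextrapush:::walker_context(spec)
  Y <- as.matrix(sim$data[, c(coordinate_names(),
                              paste0("d_", coordinate_names()))])
  E <- sapply(c(1, nrow(Y)), function(i)
    anextrapush:::walker_energy(ptr, c(Y[i, ], numeric(6))))
  drift_per_s <- abs(diff(E)) / abs(E[1]) / sim$t_end
  expect_lt(drift_per_s, 1e-6)
})

test_that("integration is deterministic (identical inputs, identical result)", {
  model <- study_model()
  ref <- study_reference()
  s1 <- simulate_walking(model, ref, n_cycles = 1)
  s2 <- simulate_walking(model, ref, n_cycles = 1)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$events, s2$events)
})

test_that("an unactuated model collapses with a recorded fall event", {
  model <- study_model()
  ref <- study_reference()
  zero <- default_gains(hip = c(kp = 0, ki = 0, kd = 0),
                        knee = c(kp = 0, ki = 0, kd = 0),
                        ankle = c(kp = 0, ki = 0, kd = 0),
                        hat_upright = c(kp = 0, kd = 0),
                        pelvis_pitch = c(kp = 0, kd = 0))
  sim <- simulate_walking(model, ref, gains = zero, n_cycles = 1)
  expect_true(sim$fell)
  expect_true("fall" %in% sim$events$label)
  expect_lt(event_times(sim, "fall")[1], ref$cycle_duration)
})

test_that("the four-cycle baseline walks 4.84 s without falling", {
  base <- baseline_sim()
  expect_false(base$fell)
  expect_equal(base$t_end, 4 * 1.21, tolerance = 1e-9)
  expect_false("fall" %in% base$events$label)
})

test_that("the unpowered worn exoskeleton mass barely changes peak torques", {
  base <- baseline_sim()
  nop <- cached("nopower",
    simulate_walking(study_model_exo(), study_reference(),
                     exo = exo_params(enabled = FALSE)))
  expect_false(nop$fell)
  # peaks compared over 25-60% of stride: the heel-strike impact transient
  # (which the work metrics likewise avoid) is excluded; 10% tolerance
  for (j in c("tau_hip_r", "tau_knee_r", "tau_ankle_r")) {
    s0 <- cycle_series(base, j); s1 <- cycle_series(nop, j)
    sel <- s0$phase >= 25 & s0$phase <= 60
    pk0 <- max(abs(s0$value[sel]))
    expect_lt(abs(max(abs(s1$value[sel])) - pk0) / pk0, 0.10)
  }
})
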