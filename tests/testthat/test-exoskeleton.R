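# Brake state machine, tendon elongation, three-spool transmission, wrenches.

test_that("the brake engages and disengages on the half-open phase interval", {
  par <- exo_params(4.85, 29, 53)
  model <- study_model_exo()
  y <- standing_state()
  st <- brake_state()
  st <- brake_update(30, par, st, model, y)
  expect_true(st$engaged)
  expect_length(st$engage_snapshot, 2)
  st2 <- brake_update(40, par, st, model, y)   # idempotent within the cycle
  expect_identical(st2$engage_snapshot, st$engage_snapshot)
  st3 <- brake_update(53 + 1e-9, par, st2, model, y)
  expect_false(st3$engaged)
  expect_null(st3$engage_snapshot)
})

test_that("a disabled exoskeleton never engages", {
  par <- exo_params(4.85, 29, 53, enabled = FALSE)
  st <- brake_state()
  for (ph in seq(0, 99, by = 7))
    st <- brake_update(ph, par, st, study_model_exo(), standing_state())
  expect_false(st$engaged)
})

test_that("elongation is zero at the engagement snapshot", {
  model <- study_model_exo()
  geom <- exo_geometry()
  y <- standing_state()
  br <- brake_update(30, exo_params(), brake_state(), model, y, geom)
  expect_equal(tendon_elongation(model, y, geom, br), 0)
})

test_that("posterior translation enters elongation one-to-one", {
  model <- study_model_exo()
  geom <- exo_geometry(anchor_position = c(5, 0.05))  # far anchor: d ~ -x
  y <- standing_state()
  br <- brake_update(30, exo_params(), brake_state(), model, y, geom)
  y2 <- y
  y2[1] <- y2[1] - 0.05   # whole body carried 5 cm posteriorly
  e <- tendon_elongation(model, y2, geom, br)
  expect_equal(e, 0.05, tolerance = 1e-3)
})

test_that("the spool ratio multiplies the shank-attachment term", {
  model <- study_model_exo()
  y <- standing_state()
  for (ratio in c(5, 8)) {
    geom <- exo_geometry(spool_ratio = ratio)
    br <- brake_update(30, exo_params(), brake_state(), model, y, geom)
    # pure dorsiflexion changes the shank-attachment distance only
    y2 <- y
    y2[7] <- 0.15
    d0 <- anextrapush:::exo_distances(model, y, geom)
    d1 <- anextrapush:::exo_distances(model, y2, geom)
    expect_equal(tendon_elongation(model, y2, geom, br),
                 (d1[["anchor"]] - d0[["anchor"]]) +
                   ratio * (d1[["shank"]] - d0[["shank"]]),
                 tolerance = 1e-10)
  }
})

test_that("the rigid tendon carries five times the elastic-tendon force", {
  model <- study_model_exo()
  geom <- exo_geometry()
  y <- standing_state()
  br <- brake_update(30, exo_params(), brake_state(), model, y, geom)
  y2 <- y; y2[1] <- -0.1; y2[7] <- 0.1
  wr <- exo_wrenches(model, y2, geom, exo_params(), br)
  expect_gt(wr$F_elastic, 0)
  expect_equal(wr$F_rigid, 5 * wr$F_elastic)
  # slack tendon: all wrenches vanish
  wr0 <- exo_wrenches(model, y, geom, exo_params(), brake_state())
  expect_equal(wr0$F_elastic, 0)
  expect_length(wr0$wrenches, 0)
})

test_that("an engaged stretched tendon plantarflexes the ankle", {
  model <- study_model_exo()
  geom <- exo_geometry()
  y <- standing_state()
  br <- brake_update(30, exo_params(), brake_state(), model, y, geom)
  y2 <- y; y2[1] <- -0.1; y2[7] <- 0.1
  wr <- exo_wrenches(model, y2, geom, exo_params(), br)
  tau <- assist_torque(model, y2, wr)
  expect_lt(tau, 0)   # CCW-positive convention: plantarflexion is negative
})

test_that("assist torque is linear in tendon stiffness at a fixed state", {
  model <- study_model_exo()
  geom <- exo_geometry()
  y <- standing_state()
  br <- brake_update(30, exo_params(), brake_state(), model, y, geom)
  y2 <- y; y2[1] <- -0.08; y2[7] <- 0.12
  t1 <- assist_torque(model, y2, exo_wrenches(model, y2, geom,
                                              exo_params(stiffness = 2), br))
  t2 <- assist_torque(model, y2, exo_wrenches(model, y2, geom,
                                              exo_params(stiffness = 4), br))
  expect_equal(t2, 2 * t1, tolerance = 1e-10)
})

test_that("with a large spool ratio the translation share of elongation vanishes", {
  model <- study_model_exo()
  y <- standing_state()
  y2 <- y; y2[1] <- -0.05; y2[7] <- 0.1
  share <- sapply(c(5, 50, 500), function(ratio) {
    geom <- exo_geometry(spool_ratio = ratio)
    br <- brake_update(30, exo_params(), brake_state(), model, y, geom)
    d0 <- anextrapush:::exo_distances(model, y, geom)
    d1 <- anextrapush:::exo_distances(model, y2, geom)
    (d1[["anchor"]] - d0[["anchor"]]) / tendon_elongation(model, y2, geom, br)
  })
  expect_true(all(diff(share) < 0))
  expect_lt(share[3], 0.05)
})

test_that("the simulated tendon force is unilateral and peaks before disengagement", {
  act <- active_sim()
  expect_false(act$fell)
  d <- act$data
  expect_true(all(d$tendon_force >= 0))
  expect_true(all(d$elongation >= 0))
  # force only while the brake is engaged
  expect_true(all(d$tendon_force[!d$brake_engaged] == 0))
  # peak force arrives late in the engagement interval, near heel-off
  pk <- d$phase[d$time > 1.21 & d$time < 2.42][
    which.max(d$tendon_force[d$time > 1.21 & d$time < 2.42])]
  expect_gt(pk, 40)
  expect_lt(pk, 53)
})

test_that("assist torque drops to zero within one sample of disengagement", {
  act <- active_sim()
  d <- act$data
  dis <- event_times(act, "brake_disengaged")
  for (t in dis) {
    after <- which(d$time > t + 1e-12)[1:2]
    expect_true(all(abs(d$assist_torque[after]) < 1e-9))
  }
})

test_that("the exoskeleton is passive: returned energy never exceeds harvested", {
  act <- active_sim()
  d <- act$data
  dt <- diff(d$time)
  pw <- act$body_mass * d$exo_power    # W, on the body
  returned <- sum(pmax(pw[-1], 0) * dt)
  absorbed <- sum(pmax(-pw[-1], 0) * dt)
  expect_lt(returned, absorbed + 1e-6)
  # energy bookkeeping: absorbed = returned + dumped at disengagements,
  # to integration/quadrature tolerance
  expect_equal(absorbed - returned, act$dissipated_energy,
               tolerance = 0.05 * absorbed)
})

test_that("stored tendon energy matches the work absorbed from the body", {
  act <- active_sim()
  d <- act$data
  # while engaged, d/dt (k m e^2 / 2) = -P_exo_on_body (ideal mechanism)
  k <- act$exo$stiffness * act$body_mass
  eng <- event_times(act, "brake_engaged")[2]
  dis <- event_times(act, "brake_disengaged")[2]
  sel <- d$time >= eng & d$time < dis
  E_stored <- 0.5 * k * tail(d$elongation[sel], 1)^2
  pw <- act$body_mass * d$exo_power
  W_absorbed <- -pracma::trapz(d$time[sel], pw[sel])
  expect_equal(W_absorbed, E_stored, tolerance = 0.05)
})

test_that("R-level wrenches agree with the compiled simulation outputs", {
  act <- active_sim()
  d <- act$data
  i <- which(d$brake_engaged & d$phase > 45 & d$time > 1.21)[1]
  y <- unlist(d[i, c(coordinate_names(), paste0("d_", coordinate_names()))])
  eng <- rev(event_times(act, "brake_engaged")[event_times(act, "brake_engaged") <= d$time[i]])[1]
  j <- which.min(abs(d$time - eng))
  y0 <- unlist(d[j, c(coordinate_names(), paste0("d_", coordinate_names()))])
  model <- study_model_exo()
  geom <- act$geometry
  snap <- unname(anextrapush:::exo_distances(model, c(y0, numeric(6)), geom))
  br <- brake_state(TRUE, snap)
  e_r <- tendon_elongation(model, c(y, numeric(6)), geom, br)
  expect_equal(e_r, d$elongation[i], tolerance = 1e-6)
  wr <- exo_wrenches(model, c(y, numeric(6)), geom, act$exo, br)
  expect_equal(wr$F_elastic / act$body_mass, d$tendon_force[i],
               tolerance = 1e-6)
  expect_equal(assist_torque(model, c(y, numeric(6)), wr), d$assist_torque[i],
               tolerance = 1e-6)
})
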