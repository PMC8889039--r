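# Sweep machinery, push-off work metrics and regressions.

test_that("the default grid enumerates the full Cartesian product", {
  expect_equal(nrow(enumerate_triplets(sweep_grid())), 616)
  g <- sweep_grid(1, 20, 50)
  expect_equal(nrow(enumerate_triplets(g)), 1)
  g2 <- sweep_grid(c(1, 2), c(20, 25, 30), c(40, 45, 50, 55, 60))
  expect_equal(nrow(enumerate_triplets(g2)), 30)
})

test_that("positive ankle work rectifies and integrates correctly", {
  ph <- seq(0, 99.9, by = 0.1)
  zero <- data.frame(phase = ph, value = 0)
  expect_equal(positive_ankle_work(zero), 0)
  neg <- data.frame(phase = ph, value = -1)
  expect_equal(positive_ankle_work(neg), 0)
  rect <- data.frame(phase = ph, value = as.numeric(ph >= 45 & ph <= 55))
  # grid-edge cells of the indicator add ~1% to the exact 1 * 0.10 * 1.21
  expect_equal(positive_ankle_work(rect, c(40, 60), 1.21), 0.121,
               tolerance = 0.015)
  expect_error(positive_ankle_work(rect, c(-5, 60)), "window")
})

test_that("reduction percentage is plain arithmetic on work values", {
  expect_equal(reduction_pct(0.3, 0.3), 0)
  expect_equal(reduction_pct(0, 0.3), 100)
  expect_equal(reduction_pct(0.177, 0.30), 41)
  expect_lt(reduction_pct(0.4, 0.3), 0)
  expect_error(reduction_pct(0.1, 0), "positive")
})

test_that("the negative-power exclusion removes inadequate-assistance intervals", {
  ph <- seq(0, 99.9, by = 0.1)
  p0 <- data.frame(phase = ph, value = as.numeric(ph >= 45 & ph <= 55))
  # assisted: power zeroed on 45-50 (true saving) but pushed negative on
  # 50-55 (additional negative power: excluded, no credit)
  pa <- p0
  pa$value[ph >= 45 & ph <= 50] <- 0
  pa$value[ph > 50 & ph <= 55] <- -0.5
  sv <- ankle_work_savings(pa, p0, c(40, 60), 1.21)
  expect_equal(sv$savings, 0.0605, tolerance = 0.025)  # only the 45-50 part
  expect_equal(sv$reduction_pct, 50, tolerance = 0.5)
})

test_that("disengagement timings classify into the three groups", {
  expect_equal(classify_disengagement(44), "premature")
  expect_equal(classify_disengagement(47), "premature")
  expect_equal(classify_disengagement(50), "premature")
  expect_equal(classify_disengagement(51), "on-time")
  expect_equal(classify_disengagement(53), "on-time")
  expect_equal(classify_disengagement(55), "on-time")
  expect_equal(classify_disengagement(56), "overdue")
  expect_equal(classify_disengagement(62), "overdue")
})

test_that("the sweep regression reproduces hand-computable cases", {
  x <- c(1, 2, 3, 4)
  lr <- linreg_sweep(x, 2 * x + 1)
  expect_equal(lr$slope, 2, tolerance = 1e-12)
  expect_equal(lr$intercept, 1, tolerance = 1e-12)
  expect_equal(lr$r2, 1, tolerance = 1e-12)
  flat <- linreg_sweep(x, rep(3, 4))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r2, 0)
  tri <- linreg_sweep(c(1, 2, 3), c(1, 3, 2))
  expect_equal(tri$r2, 0.25, tolerance = 1e-12)   # Pearson r = 0.5
  expect_error(linreg_sweep(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("gait events are detected from synthetic contact forces", {
  base <- baseline_sim()
  fake <- base
  n <- nrow(fake$data)
  ph <- fake$data$phase
  zero <- numeric(n)
  on <- function(a, b) 200 * as.numeric(ph >= a & ph <= b)
  fake$data$fn_heel_r <- on(10, 52)
  fake$data$fn_mtp_r <- on(12, 58)
  fake$data$fn_toe_r <- on(14, 60)
  fake$data$fn_heel_l <- zero
  fake$data$fn_mtp_l <- zero
  fake$data$fn_toe_l <- zero
  ev <- detect_events(fake)
  hs <- ev$phase[ev$label == "heel_strike_r"]
  ho <- ev$phase[ev$label == "heel_off_r"]
  to <- ev$phase[ev$label == "toe_off_r"]
  expect_true(all(abs(hs - 10) < 0.3))
  expect_true(all(abs(ho - 52) < 0.3))
  expect_true(all(abs(to - 60) < 0.3))
  expect_length(ev$phase[ev$label == "heel_strike_l"], 0)
})

test_that("a single-triplet sweep produces one record and resumes from checkpoints", {
  dir <- withr::local_tempdir()
  rec <- run_sweep(sweep_grid(4.85, 29, 53), study_model_exo(),
                   baseline_sim(), study_reference(), checkpoint_dir = dir)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$group, "on-time")
  expect_false(is.na(rec$reduction_pct))
  expect_length(list.files(dir), 1)
  # resumable: a second run reads the checkpoint instead of simulating
  t0 <- Sys.time()
  rec2 <- run_sweep(sweep_grid(4.85, 29, 53), study_model_exo(),
                    baseline_sim(), study_reference(), checkpoint_dir = dir)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_equal(rec2$reduction_pct, rec$reduction_pct, tolerance = 1e-9)
})

test_that("contralateral torques barely change across assisted conditions", {
  base <- baseline_sim()
  act <- active_sim()
  # RMS difference over the contralateral stance (its landing transient at
  # 55-70% of the ipsilateral cycle excluded), relative to the peak
  for (j in c("tau_hip_l", "tau_knee_l", "tau_ankle_l")) {
    a <- cycle_series(act, j); b <- cycle_series(base, j)
    sel <- a$phase < 55 | a$phase > 75
    rel <- sqrt(mean((a$value[sel] - b$value[sel])^2)) / max(abs(b$value))
    expect_lt(rel, 0.15)
  }
})
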