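# Genetic-algorithm adjustment of the reference kinematics under exoskeleton
# assistance.
#
# When the exoskeleton applies forces to the body, slightly adjusted
# reference kinematics are needed to retain a stable and physiological gait.
# The decision variables are per-joint angle offsets at evenly spaced
# stride-phase knots (hip, knee, ankle of the exoskeleton-side leg by
# default), bounded so the solution stays close to the NO-EXO kinematics.
# Fitness is a weighted sum of five criteria, each normalized by its NO-EXO
# baseline value: time until a fall, distance traveled compared to baseline,
# ground-reaction-force impulse at heel strike, total absolute joint power,
# and similarity of the torque profiles to baseline outside the assistance
# window.  Lower is better.

#' Fitness weights
#'
#' @param w_fall,w_distance,w_hs_impulse,w_abs_power,w_torque_similarity
#'   non-negative weights of the five criteria (defaults all 1).
#' @return list of class `fitness_weights`.
#' @export
fitness_weights <- function(w_fall = 1, w_distance = 1, w_hs_impulse = 1,
                            w_abs_power = 1, w_torque_similarity = 1) {
  w <- c(w_fall = w_fall, w_distance = w_distance, w_hs_impulse = w_hs_impulse,
         w_abs_power = w_abs_power, w_torque_similarity = w_torque_similarity)
  if (any(w < 0) || all(w == 0)) stop("weights must be >= 0 with at least one > 0")
  structure(as.list(w), class = "fitness_weights")
}

# distance traveled relative to the belt over the simulated interval
sim_distance <- function(sim) {
  d <- sim$data
  (d$pelvis_x[nrow(d)] - d$pelvis_x[1]) +
    sim$model$config$belt_speed * (d$time[nrow(d)] - d$time[1])
}

# vertical-GRF impulse in +/- half_window % of stride around each heel strike
hs_impulse <- function(sim, half_window = 2) {
  d <- sim$data
  hs <- c(event_times(sim, "heel_strike_r"), event_times(sim, "heel_strike_l"))
  tot <- 0
  dt <- half_window / 100 * sim$cycle_duration
  fy <- d$grf_y_r + d$grf_y_l
  for (t in hs) {
    sel <- d$time >= t - dt & d$time <= t + dt
    if (sum(sel) > 1) tot <- tot + pracma::trapz(d$time[sel], fy[sel])
  }
  tot
}

total_abs_power <- function(sim) {
  d <- sim$data
  tot <- 0
  for (j in joint_coord_names())
    tot <- tot + pracma::trapz(d$time, abs(d[[paste0("power_", j)]]))
  tot
}

# cycles over which a simulation's representative profile is taken:
# steady cycles 2-4 where available, else whatever completed
rep_cycles <- function(sim) {
  ncyc <- floor(sim$t_end / sim$cycle_duration + 1e-9)
  if (ncyc >= 2) 2:min(4, ncyc) else NULL
}

# L2 distance between torque profiles outside the assistance window; a
# simulation that fell before completing a cycle is compared over the time
# it survived
torque_distance_outside <- function(sim, baseline, window) {
  ph <- seq(0, 99.5, by = 0.5)
  sel <- ph < window[1] | ph > window[2]
  cyc_b <- rep_cycles(baseline)
  cyc_s <- rep_cycles(sim)
  tot <- 0
  for (j in c("tau_hip_r", "tau_knee_r", "tau_ankle_r")) {
    b <- cycle_series(baseline, j, cycle = cyc_b, dphase = 0.5)$value
    if (is.null(cyc_s)) {
      keep <- sel & (ph / 100 * sim$cycle_duration < sim$t_end)
      a <- approx(sim$data$time, sim$data[[j]],
                  xout = ph / 100 * sim$cycle_duration, rule = 2)$y
      tot <- tot + sqrt(mean((a[keep] - b[keep])^2))
    } else {
      a <- cycle_series(sim, j, cycle = cyc_s, dphase = 0.5)$value
      tot <- tot + sqrt(mean((a[sel] - b[sel])^2))
    }
  }
  tot
}

#' Fitness of an assisted simulation
#'
#' @param sim assisted-condition `walker_sim`.
#' @param baseline the NO-EXO representative `walker_sim`.
#' @param weights a `fitness_weights`.
#' @return list with `scalar` (lower is better) and the per-criterion
#'   `breakdown` (each normalized by its baseline value where applicable).
#' @export
fitness <- function(sim, baseline, weights = fitness_weights()) {
  if (abs(sim$cycle_duration - baseline$cycle_duration) > 1e-9)
    stop("mismatched time bases between simulation and baseline")
  Ttot <- sim$n_cycles * sim$cycle_duration
  t_fall <- if (sim$fell) event_times(sim, "fall")[1] else Ttot
  c_fall <- (Ttot - t_fall) / Ttot

  d0 <- sim_distance(baseline)
  c_dist <- abs(sim_distance(sim) - d0) / abs(d0)

  i0 <- hs_impulse(baseline)
  c_imp <- if (i0 > 0) hs_impulse(sim) / i0 else 0

  p0 <- total_abs_power(baseline)
  c_pow <- total_abs_power(sim) / p0

  window <- if (!is.null(sim$exo))
    c(sim$exo$engage_phase, sim$exo$disengage_phase) else c(0, 0)
  tau0 <- torque_distance_outside(baseline, baseline, window)  # 0 by construction
  c_tau <- torque_distance_outside(sim, baseline, window)

  br <- c(fall = c_fall, distance = c_dist, hs_impulse = c_imp,
          abs_power = c_pow, torque_similarity = c_tau)
  w <- unlist(weights)
  list(scalar = sum(w * br), breakdown = br)
}

#' Seeded real-coded genetic algorithm minimizer
#'
#' Tournament selection, blend crossover, Gaussian mutation with sigma a
#' fraction of the bound range, elitism, and an initial population seeded
#' around zero (the first individual is exactly the zero/centre point).
#' Deterministic for a given seed.
#'
#' @param fn objective to minimize, taking a numeric vector.
#' @param lower,upper bounds (recycled to the problem dimension).
#' @param settings list: `pop_size`, `generations`, `tournament`,
#'   `mutation_sigma_frac`, `elitism`, `crossover_prob`, `mutation_prob`.
#' @param seed integer RNG seed.
#' @param center optional centre of the initial population (default
#'   midpoint of the bounds, i.e. zero for symmetric bounds).
#' @return list with `par`, `value`, `history` (best fitness per
#'   generation), `population`.
#' @export
ga_minimize <- function(fn, lower, upper, settings = ga_settings(), seed = 1,
                        center = NULL) {
  n <- max(length(lower), length(upper))
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (is.null(center)) center <- (lower + upper) / 2
  s <- settings
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sigma <- s$mutation_sigma_frac * (upper - lower)
  pop <- t(vapply(seq_len(s$pop_size), function(i) {
    if (i == 1) center
    else pmin(pmax(center + rnorm(n, 0, sigma), lower), upper)
  }, numeric(n)))
  fit <- apply(pop, 1, fn)
  history <- numeric(s$generations)
  for (g in seq_len(s$generations)) {
    ord <- order(fit)
    newpop <- pop[ord[seq_len(s$elitism)], , drop = FALSE]
    newfit <- fit[ord[seq_len(s$elitism)]]
    while (nrow(newpop) < s$pop_size) {
      pick <- function() {
        cand <- sample.int(s$pop_size, s$tournament)
        cand[which.min(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      child <- if (runif(1) < s$crossover_prob) {
        a <- runif(n); a * p1 + (1 - a) * p2
      } else p1
      mut <- runif(n) < s$mutation_prob
      child[mut] <- child[mut] + rnorm(sum(mut), 0, sigma[mut])
      child <- pmin(pmax(child, lower), upper)
      newpop <- rbind(newpop, child)
      newfit <- c(newfit, fn(child))
    }
    pop <- newpop; fit <- newfit
    history[g] <- min(fit)
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best], history = history,
       population = pop)
}

#' Genetic-algorithm settings
#' @param pop_size population size.
#' @param generations number of generations.
#' @param tournament tournament size.
#' @param mutation_sigma_frac Gaussian mutation sigma as a fraction of the
#'   bound range.
#' @param elitism individuals carried over unchanged.
#' @param crossover_prob,mutation_prob operator probabilities.
#' @param exo_side_only adjust only the exoskeleton-side leg.
#' @param n_knots phase knots per joint.
#' @param bound absolute offset bound (rad).
#' @param n_cycles simulated cycles per fitness evaluation.
#' @return list of settings.
#' @export
ga_settings <- function(pop_size = 32, generations = 40, tournament = 3,
                        mutation_sigma_frac = 0.1, elitism = 2,
                        crossover_prob = 0.9, mutation_prob = 0.25,
                        exo_side_only = TRUE, n_knots = 8,
                        bound = 5 * pi / 180, n_cycles = 4) {
  as.list(environment())
}

#' GA adjustment of reference kinematics under assistance
#'
#' Minimizes the five-criterion fitness over bounded per-joint knot offsets,
#' starting from the NO-EXO reference kinematics (the zero adjustment, which
#' is always a member of the initial population).
#'
#' @param model a `walker_model` built with the exoskeleton mass.
#' @param exo_par an `exo_params`.
#' @param base_reference the NO-EXO `gait_reference`.
#' @param baseline the NO-EXO representative `walker_sim`.
#' @param weights a `fitness_weights`.
#' @param settings a [ga_settings()] list.
#' @param seed integer RNG seed.
#' @param geometry an `exo_geometry`.
#' @param ... passed to [simulate_walking()].
#' @return list with `adjustment` (a `kinematic_adjustment`), `reference`
#'   (the adjusted `gait_reference`), `value`, `history`, `seed`.
#' @export
ga_optimize <- function(model, exo_par, base_reference, baseline,
                        weights = fitness_weights(), settings = ga_settings(),
                        seed = 1, geometry = exo_geometry(), ...) {
  nk <- settings$n_knots
  n <- 3 * nk
  decode <- function(x) kinematic_adjustment(
    hip = x[1:nk], knee = x[nk + 1:nk], ankle = x[2 * nk + 1:nk],
    n_knots = nk, bound = settings$bound)
  fell_all <- TRUE
  obj <- function(x) {
    ref <- adjust_reference(base_reference, decode(x))
    sim <- simulate_walking(model, ref, exo = exo_par, geometry = geometry,
                            n_cycles = settings$n_cycles, ...)
    if (!sim$fell) fell_all <<- FALSE
    fitness(sim, baseline, weights)$scalar
  }
  res <- ga_minimize(obj, rep(-settings$bound, n), rep(settings$bound, n),
                     settings, seed, center = numeric(n))
  if (fell_all)
    stop("all individuals fell in every generation: infeasible exoskeleton parameters or gains")
  list(adjustment = decode(res$par),
       reference = adjust_reference(base_reference, decode(res$par)),
       value = res$value, history = res$history, seed = seed)
}

#' Select the representative solution of four repeated optimizations
#'
#' The heuristic optimization is repeated four times per parameter triplet;
#' the solution with the largest summed L2 torque-profile distance to the
#' other three is discarded as the outlier, and of the remaining three the
#' one with the median joint-torque characteristic -- the most central
#' profile, i.e. the smallest summed distance to the other two -- is
#' returned.
#'
#' @param solutions list of exactly four solutions; each either a
#'   `walker_sim` or a list with element `torque` (a numeric torque-profile
#'   vector on a common grid).
#' @return the representative solution (an element of `solutions`), with
#'   attribute `"outlier"` giving the discarded index.
#' @export
select_representative <- function(solutions) {
  if (length(solutions) != 4) stop("exactly 4 solutions are required")
  prof <- lapply(solutions, function(s) {
    if (inherits(s, "walker_sim")) {
      cyc <- max(1, min(3, floor(s$t_end / s$cycle_duration)))
      c(cycle_series(s, "tau_hip_r", cycle = cyc, dphase = 0.5)$value,
        cycle_series(s, "tau_knee_r", cycle = cyc, dphase = 0.5)$value,
        cycle_series(s, "tau_ankle_r", cycle = cyc, dphase = 0.5)$value)
    } else s$torque
  })
  dmat <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    dmat[i, j] <- dmat[j, i] <- sqrt(sum((prof[[i]] - prof[[j]])^2))
  }
  outlier <- which.max(rowSums(dmat))
  keep <- setdiff(1:4, outlier)
  tot <- rowSums(dmat[keep, keep])
  rep_idx <- keep[which.min(tot)]    # the most central (median) profile
  out <- solutions[[rep_idx]]
  attr(out, "outlier") <- outlier
  attr(out, "index") <- rep_idx
  out
}
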