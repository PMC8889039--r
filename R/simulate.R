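# Time-stepping of the walking model: builds the compiled dynamics context,
# integrates with a stiff-capable variable-step scheme (deSolve::lsoda,
# default rtol 1e-6 -- penalty contact is stiff), splits the integration at
# the a-priori-known brake engagement/disengagement times (switching is
# instantaneous and commanded open-loop in stride phase), and detects falls
# by root-finding on pelvis height.

default_ref_pelvis <- function(model, shape = default_gait_shape()) {
  list(y0 = model$standing_hip_height - shape$pelvis_drop,
       amp = shape$pelvis_amp, peak_phase = shape$pelvis_peak_phase)
}

# Full C++ context specification
build_ctx_spec <- function(model, reference = NULL, gains = NULL,
                           contact = NULL, exo_par = NULL, exo_geom = NULL,
                           contact_enabled = TRUE, control_enabled = TRUE) {
  if (is.null(reference)) reference <- make_reference(config = model$config)
  if (is.null(gains)) gains <- default_gains()
  if (is.null(contact)) contact <- default_contact_params()
  if (is.null(exo_geom)) exo_geom <- exo_geometry()
  stiff <- if (is.null(exo_par)) 1 else exo_par$stiffness
  g <- model$config$geometry
  list(
    chain = model$chain,
    belt_speed = model$config$belt_speed,
    contact = list(enabled = isTRUE(contact_enabled),
                   spheres = unname(model$spheres),
                   normal_stiffness = contact$normal_stiffness,
                   normal_damping = contact$normal_damping,
                   friction_coefficient = contact$friction_coefficient,
                   velocity_smoothing = contact$velocity_smoothing,
                   exponent = contact$exponent),
    reference = list(cycle_duration = reference$cycle_duration,
                     a0 = unname(reference$coef$a0),
                     A = unname(reference$coef$A),
                     B = unname(reference$coef$B)),
    control = list(enabled = isTRUE(control_enabled),
                   integrator_limit = gains$integrator_limit,
                   joints = control_matrix(gains, model$config)),
    exo = list(spool_ratio = exo_geom$spool_ratio,
               stiffness = stiff,
               body_mass = model$config$body_mass,
               anchor = exo_geom$anchor_position,
               spool_local = exo_geom$spool_axis_local,
               shank_local = exo_geom$shank_attachment_local,
               foot_body = 5L, shank_body = 4L)
  )
}

# Minimal context for kinematic queries on a bare model
model_ctx <- function(model) {
  ref <- list(cycle_duration = 1, a0 = numeric(3),
              A = matrix(0, 3, 1), B = matrix(0, 3, 1))
  spec <- list(chain = model$chain, belt_speed = 0,
               contact = list(enabled = FALSE, spheres = unname(model$spheres),
                              normal_stiffness = 0, normal_damping = 0,
                              friction_coefficient = 1, velocity_smoothing = 0.01,
                              exponent = 1.5),
               reference = ref,
               control = list(enabled = FALSE, integrator_limit = 1,
                              joints = control_matrix(default_gains(), model$config)),
               exo = list(spool_ratio = 5, stiffness = 1,
                          body_mass = model$config$body_mass,
                          anchor = c(1, 0.05), spool_local = c(-0.05, -0.05),
                          shank_local = c(-0.05, -0.16),
                          foot_body = 5L, shank_body = 4L))
  walker_context(spec)
}

#' Initial state consistent with the reference at t = 0
#'
#' Pelvis pose and velocity from the reference pelvis law, joint angles and
#' velocities from the reference trajectories (right leg at phase 0%, left at
#' 50%), metatarsophalangeal joints at rest, PID integrators at zero.
#'
#' @param model a `walker_model`.
#' @param reference a `gait_reference`.
#' @param settle initial pelvis lowering (m) pre-loading the contact so the
#'   model does not free-fall onto the belt at t = 0.
#' @return numeric state vector (length 30: 12 q, 12 qdot, 6 integrators).
#' @export
initial_state <- function(model, reference, settle = 0.002) {
  pel <- reference$pelvis
  if (is.null(pel)) pel <- default_ref_pelvis(model)
  Tc <- reference$cycle_duration
  ang_r <- eval_reference(reference, 0, "right")
  ang_l <- eval_reference(reference, 0, "left")
  vel_r <- eval_reference(reference, 0, "right", deriv = 1)
  vel_l <- eval_reference(reference, 0, "left", deriv = 1)
  y_p <- pel$y0 + pel$amp * cos(4 * pi * (0 - pel$peak_phase)) - settle
  yd_p <- -pel$amp * 4 * pi / Tc * sin(4 * pi * (0 - pel$peak_phase))
  th_p <- thd_p <- 0
  if (!is.null(pel$pitch_coef)) {
    th_p <- eval_pelvis_pitch(pel$pitch_coef, 0)
    thd_p <- eval_pelvis_pitch(pel$pitch_coef, 0, deriv = 1, period = Tc)
  }
  q <- c(0, y_p, th_p,
         0, ang_r[1, "hip"], ang_r[1, "knee"], ang_r[1, "ankle"], 0,
         ang_l[1, "hip"], ang_l[1, "knee"], ang_l[1, "ankle"], 0)
  qd <- c(0, yd_p, thd_p,
          0, vel_r[1, "hip"], vel_r[1, "knee"], vel_r[1, "ankle"], 0,
          vel_l[1, "hip"], vel_l[1, "knee"], vel_l[1, "ankle"], 0)
  c(q, qd, numeric(6))
}

output_names <- function() {
  c(paste0("tau_", joint_coord_names()),
    "grf_x_r", "grf_y_r", "grf_x_l", "grf_y_l",
    paste0("fn_", rownames_spheres()),
    "tendon_force", "elongation", "assist_torque", "exo_power",
    "hat_angle", "pelvis_com_y")
}
rownames_spheres <- function() c("heel_r", "mtp_r", "toe_r", "heel_l", "mtp_l", "toe_l")

#' Simulate treadmill walking
#'
#' Integrates the torque-driven walking model over `n_cycles` chained
#' identical gait cycles, with optional exoskeleton assistance.  The brake is
#' commanded open-loop in the stride phase of the exoskeleton-side (right)
#' leg: engagement and disengagement happen at known times, where the
#' integration is split and the elongation snapshot captured.  A fall
#' (pelvis height below `fall_fraction` of standing hip height) terminates
#' the integration and is recorded as an event.
#'
#' @param model a `walker_model` (build with `exo_mass = TRUE` for the worn
#'   device).
#' @param reference a `gait_reference`.
#' @param gains a `controller_gains`.
#' @param contact a `contact_params`.
#' @param exo an `exo_params`, or `NULL` for the no-exoskeleton condition.
#' @param geometry an `exo_geometry`.
#' @param n_cycles number of gait cycles (default: the reference's).
#' @param dt_out output sampling interval (s); default cycle/1000 (0.1%
#'   of stride).
#' @param rtol,atol integrator tolerances.
#' @param fall_fraction pelvis-height fall threshold as a fraction of
#'   standing hip height.
#' @param contact_enabled,control_enabled,gravity_enabled switches used by
#'   diagnostics and conservation audits.
#' @param y0 optional initial state (default [initial_state()]).
#' @return object of class `walker_sim`: list with `data` (one row per
#'   sample: time, phase, coordinates, velocities, body-mass-normalized
#'   torques/powers/GRFs/tendon force, per-sphere normal forces), `events`
#'   (label, time, phase), and metadata.
#' @export
simulate_walking <- function(model, reference = NULL, gains = default_gains(),
                             contact = default_contact_params(),
                             exo = NULL, geometry = exo_geometry(),
                             n_cycles = NULL, dt_out = NULL,
                             rtol = 1e-6, atol = 1e-8,
                             fall_fraction = 0.7,
                             contact_enabled = TRUE, control_enabled = TRUE,
                             gravity_enabled = TRUE, y0 = NULL) {
  if (is.null(reference)) reference <- make_reference(config = model$config)
  Tc <- reference$cycle_duration
  if (is.null(n_cycles)) n_cycles <- reference$n_cycles
  if (is.null(dt_out)) dt_out <- Tc / 1000
  t_end <- n_cycles * Tc

  mdl <- model
  if (!gravity_enabled) mdl$chain$gravity <- 0
  spec <- build_ctx_spec(mdl, reference, gains, contact, exo, geometry,
                         contact_enabled, control_enabled)
  ptr <- walker_context(spec)
  if (is.null(y0)) y0 <- initial_state(model, reference)

  exo_on <- !is.null(exo) && isTRUE(exo$enabled)
  # brake switching times (known a priori: open-loop in stride phase)
  ev <- NULL
  if (exo_on) {
    cyc <- seq_len(n_cycles) - 1
    ev <- rbind(data.frame(label = "brake_engaged",
                           time = (cyc + exo$engage_phase / 100) * Tc),
                data.frame(label = "brake_disengaged",
                           time = (cyc + exo$disengage_phase / 100) * Tc))
    ev <- ev[order(ev$time), ]
    ev <- ev[ev$time < t_end, ]
  }
  bounds <- sort(unique(c(0, if (!is.null(ev)) ev$time, t_end)))
  grid <- seq(0, t_end, by = dt_out)
  y_fall <- fall_fraction * model$standing_hip_height

  rhs <- function(t, y, p) list(walker_rhs(ptr, t, y))
  rootf <- function(t, y, p) y[2] - y_fall

  walker_set_brake(ptr, FALSE, 0, 0)
  times_all <- c(); Y_all <- NULL; eng_all <- c(); snap_all <- NULL
  snap_now <- c(0, 0)
  events <- data.frame(label = character(), time = numeric())
  y <- y0; engaged <- FALSE; fell <- FALSE; dissipated <- 0
  kph <- if (exo_on) exo$stiffness * model$config$body_mass else 0

  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    # brake transition at t0?
    if (exo_on && any(abs(ev$time - t0) < 1e-12)) {
      lab <- ev$label[which.min(abs(ev$time - t0))]
      if (lab == "brake_engaged") {
        d <- walker_exo_dist(ptr, y)
        walker_set_brake(ptr, TRUE, d[1], d[2])
        snap_now <- c(d[1], d[2])
        engaged <- TRUE
      } else {
        if (engaged) {   # remaining stored energy is dumped into the damper
          e_rem <- tendon_elongation_ctx(ptr, y, snap_now)
          dissipated <- dissipated + 0.5 * kph * e_rem^2
        }
        walker_set_brake(ptr, FALSE, 0, 0)
        snap_now <- c(0, 0)
        engaged <- FALSE
      }
      events <- rbind(events, data.frame(label = lab, time = t0))
    }
    tt <- unique(c(t0, grid[grid > t0 + 1e-12 & grid < t1 - 1e-12], t1))
    sol <- deSolve::ode(y = y, times = tt, func = rhs, parms = NULL,
                        method = "lsodar", rootfunc = rootf,
                        rtol = rtol, atol = atol, maxsteps = 50000)
    sol <- unclass(sol)
    nrec <- nrow(sol)
    keep <- if (i == 1) seq_len(nrec) else seq(2, nrec)
    times_all <- c(times_all, sol[keep, 1])
    Y_all <- rbind(Y_all, sol[keep, -1, drop = FALSE])
    eng_all <- c(eng_all, rep(as.numeric(engaged), length(keep)))
    snap_all <- rbind(snap_all, matrix(snap_now, length(keep), 2, byrow = TRUE))
    y <- sol[nrec, -1]
    if (sol[nrec, 1] < t1 - 1e-9) {  # fall root triggered
      events <- rbind(events,
                      data.frame(label = "fall", time = sol[nrec, 1]))
      fell <- TRUE
      break
    }
  }

  out <- walker_outputs(ptr, times_all, Y_all, eng_all, snap_all)
  colnames(out) <- output_names()
  bm <- model$config$body_mass
  qn <- coordinate_names()
  dat <- data.frame(time = times_all, phase = phase_of(times_all, Tc))
  for (k in seq_along(qn)) dat[[qn[k]]] <- Y_all[, k]
  for (k in seq_along(qn)) dat[[paste0("d_", qn[k])]] <- Y_all[, 12 + k]
  tq <- out[, paste0("tau_", joint_coord_names()), drop = FALSE] / bm
  colnames(tq) <- paste0("tau_", joint_coord_names())
  dat <- cbind(dat, tq)
  for (j in joint_coord_names())
    dat[[paste0("power_", j)]] <- dat[[paste0("tau_", j)]] * dat[[paste0("d_", j)]]
  for (cc in c("grf_x_r", "grf_y_r", "grf_x_l", "grf_y_l"))
    dat[[cc]] <- out[, cc] / bm
  for (cc in paste0("fn_", rownames_spheres())) dat[[cc]] <- out[, cc]
  dat$tendon_force <- out[, "tendon_force"] / bm
  dat$elongation <- out[, "elongation"]
  dat$assist_torque <- out[, "assist_torque"] / bm
  dat$exo_power <- out[, "exo_power"] / bm
  dat$hat_angle <- out[, "hat_angle"]
  dat$pelvis_com_y <- out[, "pelvis_com_y"]
  dat$brake_engaged <- eng_all > 0.5

  events$phase <- if (nrow(events)) phase_of(events$time, Tc) else numeric(0)
  res <- structure(list(
    data = dat, events = events, fell = fell,
    dissipated_energy = dissipated,
    model = model, reference = reference, exo = exo, geometry = geometry,
    gains = gains, contact = contact,
    cycle_duration = Tc, n_cycles = n_cycles,
    body_mass = bm, t_end = max(times_all)
  ), class = "walker_sim")
  res$events <- rbind(res$events, detect_events(res))
  res$events <- res$events[order(res$events$time), ]
  rownames(res$events) <- NULL
  res
}

# elongation from the context's stored snapshot
tendon_elongation_ctx <- function(ptr, y, snap) {
  o <- walker_outputs(ptr, 0, matrix(y, nrow = 1), 1, matrix(snap, 1, 2))
  o[1, which(output_names() == "elongation")]
}

#' @export
print.walker_sim <- function(x, ...) {
  cat(sprintf("<walker_sim>: %.2f s simulated (%d cycle(s) of %.2f s)%s\n",
              x$t_end, x$n_cycles, x$cycle_duration,
              if (x$fell) " -- FELL" else ""))
  cat(sprintf("  condition: %s\n",
              if (is.null(x$exo)) "NO-EXO"
              else if (!x$exo$enabled) "NO-POWER"
              else sprintf("ACTIVE (k=%.2f N/m/kg, engage %g%%, disengage %g%%)",
                           x$exo$stiffness, x$exo$engage_phase, x$exo$disengage_phase)))
  invisible(x)
}
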