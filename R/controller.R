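# Joint-level tracking control ("biological torques").
#
# Hip, knee and ankle joints are driven by local PID controllers tracking the
# reference kinematics; the lumbo-sacral joint is driven by a PD feedback on
# the world orientation of the HAT segment (keeping the trunk upright); the
# metatarsophalangeal joints are passive rotary springs.  Torques produced by
# the PID controllers stand in for the body's own net joint moments and are
# reported as biological torques.

#' Default controller gains
#'
#' Per-joint PID gains (N m/rad, N m/(rad s), N m s/rad) for the tracked
#' joints, the HAT-upright PD gains, and the integrator clamp.  Defaults are
#' stiff tracking, tuned once against the default model (see the methods
#' vignette) and frozen.
#'
#' @param hip,knee,ankle named numeric `c(kp=, ki=, kd=)`.
#' @param hat_upright named numeric `c(kp=, kd=)` on HAT world orientation.
#' @param pelvis_pitch named numeric `c(kp=, kd=)`: the lumbo-sacral
#'   controller also rights the pelvis by reacting against the HAT.
#' @param integrator_limit clamp on the integral torque contribution (N m).
#' @return list of class `controller_gains`.
#' @export
default_gains <- function(hip = c(kp = 2400, ki = 150, kd = 110),
                          knee = c(kp = 1800, ki = 125, kd = 60),
                          ankle = c(kp = 1400, ki = 125, kd = 40),
                          hat_upright = c(kp = 5000, kd = 800),
                          pelvis_pitch = c(kp = 5000, kd = 800),
                          integrator_limit = 60) {
  for (g in list(hip, knee, ankle)) stopifnot(all(g >= 0))
  stopifnot(all(hat_upright >= 0), integrator_limit > 0)
  structure(list(hip = hip, knee = knee, ankle = ankle,
                 hat_upright = hat_upright, pelvis_pitch = pelvis_pitch,
                 integrator_limit = integrator_limit),
            class = "controller_gains")
}

#' PID tracking torques
#'
#' Functional single-step evaluation of the per-joint PID law
#' `tau = kp*e + ki*int(e) + kd*edot` with the integral contribution clamped
#' at `+/-integrator_limit`.  Used by the simulation core (where the
#' integrator state is part of the ODE state) and directly for testing the
#' control law.
#'
#' @param q,qdot current joint angles and velocities (rad, rad/s), named or
#'   ordered hip, knee, ankle per leg.
#' @param ref,refdot reference angles and velocities at the current time.
#' @param gains a `controller_gains` object.
#' @param integrator_state accumulated integral of the error (rad s),
#'   same length as `q`.
#' @param joint_types character vector mapping each entry of `q` to
#'   `"hip"`, `"knee"` or `"ankle"`.
#' @param dt time step used to advance the integrator state (s).
#' @return list with `torques` (N m) and the updated `integrator_state`.
#' @export
pid_torques <- function(q, qdot, ref, refdot, gains = default_gains(),
                        integrator_state = numeric(length(q)),
                        joint_types = c("hip", "knee", "ankle"),
                        dt = 0) {
  stopifnot(length(q) == length(qdot), length(q) == length(ref),
            length(q) == length(integrator_state),
            length(joint_types) == length(q))
  e <- ref - q
  edot <- refdot - qdot
  tau <- numeric(length(q))
  lim <- gains$integrator_limit
  for (i in seq_along(q)) {
    g <- gains[[joint_types[i]]]
    ti <- g[["ki"]] * integrator_state[i]
    ti <- min(max(ti, -lim), lim)
    tau[i] <- g[["kp"]] * e[i] + ti + g[["kd"]] * edot[i]
    # conditional anti-windup: stop integrating past the clamp
    raw <- g[["ki"]] * integrator_state[i]
    if (!((raw >= lim && e[i] > 0) || (raw <= -lim && e[i] < 0)))
      integrator_state[i] <- integrator_state[i] + e[i] * dt
  }
  list(torques = tau, integrator_state = integrator_state)
}

# Control matrix handed to the C++ context: one row per controlled
# coordinate: coord (1-based), mode (0 PID, 1 HAT-upright, 2 passive),
# refset (0 hip, 1 knee, 2 ankle), phase offset, integrator slot, kp, ki, kd.
control_matrix <- function(gains, config) {
  z <- c(0, 0)
  pp <- gains$pelvis_pitch
  rows <- rbind(
    c(4,  1, 0, 0,   0, gains$hat_upright[["kp"]], 0, gains$hat_upright[["kd"]],
      pp[["kp"]], pp[["kd"]]),
    c(5,  0, 0, 0,   1, gains$hip[["kp"]],   gains$hip[["ki"]],   gains$hip[["kd"]], z),
    c(6,  0, 1, 0,   2, gains$knee[["kp"]],  gains$knee[["ki"]],  gains$knee[["kd"]], z),
    c(7,  0, 2, 0,   3, gains$ankle[["kp"]], gains$ankle[["ki"]], gains$ankle[["kd"]], z),
    c(8,  2, 0, 0,   0, config$mtp_stiffness, 0, config$mtp_damping, z),
    c(9,  0, 0, 0.5, 4, gains$hip[["kp"]],   gains$hip[["ki"]],   gains$hip[["kd"]], z),
    c(10, 0, 1, 0.5, 5, gains$knee[["kp"]],  gains$knee[["ki"]],  gains$knee[["kd"]], z),
    c(11, 0, 2, 0.5, 6, gains$ankle[["kp"]], gains$ankle[["ki"]], gains$ankle[["kd"]], z),
    c(12, 2, 0, 0,   0, config$mtp_stiffness, 0, config$mtp_damping, z)
  )
  colnames(rows) <- c("coord", "mode", "refset", "phoff", "integ", "kp", "ki", "kd",
                      "kp2", "kd2")
  rows
}
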