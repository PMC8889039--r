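# Penalty sphere-plane contact with belt-relative friction.

#' Contact parameters
#'
#' Parameters of the penalty foot-ground contact law: a Hunt-Crossley
#' nonlinear spring-damper normal force
#' `F_n = k * delta^e * (1 + c * delta_dot)` (clamped at zero) and a
#' tanh-regularized Coulomb friction force opposing the belt-relative
#' tangential velocity, `F_t = -mu * F_n * tanh(v_rel / v_smooth)`.
#'
#' Friction is driven by the velocity relative to the moving belt surface
#' (which travels posteriorly at the belt speed), so the belt does work on the
#' stance foot: this is the energy-harvesting channel of the exoskeleton.
#'
#' @param normal_stiffness contact stiffness `k` (N/m^e).
#' @param normal_damping penetration-rate damping factor `c` (s/m).
#' @param friction_coefficient Coulomb friction coefficient `mu`.
#' @param velocity_smoothing tangential smoothing velocity `v_smooth` (m/s).
#' @param exponent Hunt-Crossley exponent `e`.
#' @return list of class `contact_params`.
#' @export
default_contact_params <- function(normal_stiffness = 6e5,
                                   normal_damping = 2.0,
                                   friction_coefficient = 1.0,
                                   velocity_smoothing = 0.01,
                                   exponent = 1.5) {
  stopifnot(normal_stiffness >= 0, normal_damping >= 0,
            friction_coefficient > 0, velocity_smoothing > 0)
  structure(list(normal_stiffness = normal_stiffness,
                 normal_damping = normal_damping,
                 friction_coefficient = friction_coefficient,
                 velocity_smoothing = velocity_smoothing,
                 exponent = exponent), class = "contact_params")
}

#' Contact wrench of one sphere against the treadmill plane
#'
#' Total function of the sphere state: returns the normal and friction force
#' acting on a contact sphere penetrating the plane `y = 0`.
#'
#' @param sphere_world_pos numeric length-2, world position of the sphere
#'   centre (m).
#' @param sphere_world_vel numeric length-2, world velocity of the sphere
#'   centre (m/s).
#' @param radius sphere radius (m).
#' @param belt_speed belt speed (m/s); the belt surface moves at
#'   `-belt_speed` along world x.
#' @param params a `contact_params` object.
#' @return named numeric `c(normal_force = , friction_force = )` (N).
#' @export
contact_wrench <- function(sphere_world_pos, sphere_world_vel, radius = 0.02,
                           belt_speed = 0, params = default_contact_params()) {
  pen <- radius - sphere_world_pos[2]
  if (pen <= 0) return(c(normal_force = 0, friction_force = 0))
  pendot <- -sphere_world_vel[2]
  fn <- params$normal_stiffness * pen^params$exponent *
    (1 + params$normal_damping * pendot)
  fn <- max(fn, 0)
  vrel <- sphere_world_vel[1] + belt_speed
  ft <- -params$friction_coefficient * fn *
    tanh(vrel / params$velocity_smoothing)
  c(normal_force = fn, friction_force = ft)
}
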