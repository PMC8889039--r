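# AN-EXTRA-Push exoskeleton model: brake state machine, elastic-tendon
# elongation, three-spool transmission and the external forces it applies to
# the foot and shank.
#
# Mechanism: an elastic tendon connects a braking/pretensioning module
# anchored in front of the treadmill to the outer spools of a three-spool
# structure on the foot; a rigid tendon connects the inner spool (radius
# 1/spool_ratio of the outer) to an attachment on the shank.  Both the spool
# axis and the shank attachment sit posterior to the ankle, so tendon tension
# generates plantarflexion torque.  While the brake is engaged the posterior
# travel of the stance foot (dragged by the belt) and ankle dorsiflexion both
# lengthen the elastic tendon; the stored energy recoils into push-off.
# Constant-force-spring pretension and brake transients are not modeled:
# elongation is referenced to the engagement snapshot and clamped at zero
# (ideal unilateral spring).

#' Exoskeleton parameters
#'
#' @param stiffness elastic tendon stiffness normalized to body mass
#'   (N/m per kg).
#' @param engage_phase brake engagement timing (% of stride, ipsilateral
#'   convention: 0% = leg most anterior).
#' @param disengage_phase brake disengagement timing (% of stride).
#' @param enabled logical; a disabled exoskeleton never engages (the
#'   unpowered, worn-mass-only condition).
#' @return list of class `exo_params`.
#' @export
exo_params <- function(stiffness = 4.85, engage_phase = 29,
                       disengage_phase = 53, enabled = TRUE) {
  stopifnot(stiffness > 0)
  if (!(engage_phase >= 0 && engage_phase < disengage_phase &&
        disengage_phase < 100))
    stop("require 0 <= engage_phase < disengage_phase < 100")
  structure(list(stiffness = stiffness, engage_phase = engage_phase,
                 disengage_phase = disengage_phase, enabled = isTRUE(enabled)),
            class = "exo_params")
}

#' Exoskeleton geometry
#'
#' @param anchor_position world position (m) of the tendon exit of the
#'   braking/pretensioning module, anterior of the treadmill near belt
#'   height.
#' @param spool_axis_local spool-axis point in the foot frame (origin at the
#'   ankle), posterior to the ankle.
#' @param shank_attachment_local rigid-tendon attachment in the shank frame
#'   (origin at the knee), posterior to the ankle.
#' @param spool_ratio outer/inner spool radius ratio of the three-spool
#'   transmission.
#' @return list of class `exo_geometry`.
#' @export
exo_geometry <- function(anchor_position = c(1.0, 0.05),
                         spool_axis_local = c(-0.065, -0.045),
                         shank_attachment_local = c(-0.065, -0.16),
                         spool_ratio = 5) {
  stopifnot(spool_ratio > 0, length(anchor_position) == 2)
  if (spool_axis_local[1] >= 0)
    stop("spool axis must be posterior to the ankle joint centre")
  if (shank_attachment_local[1] >= 0)
    stop("shank attachment must be posterior to the ankle joint centre")
  structure(list(anchor_position = anchor_position,
                 spool_axis_local = spool_axis_local,
                 shank_attachment_local = shank_attachment_local,
                 spool_ratio = spool_ratio), class = "exo_geometry")
}

#' Brake state
#'
#' @param engaged logical.
#' @param engage_snapshot numeric length-2, the anchor-to-spool and
#'   shank-attachment-to-spool distances captured at engagement; present iff
#'   engaged.
#' @return list of class `brake_state`.
#' @export
brake_state <- function(engaged = FALSE, engage_snapshot = NULL) {
  if (engaged && is.null(engage_snapshot))
    stop("an engaged brake requires an engagement snapshot")
  if (!engaged) engage_snapshot <- NULL
  structure(list(engaged = engaged, engage_snapshot = engage_snapshot),
            class = "brake_state")
}

# world positions of the foot spool-axis point and shank attachment
exo_points <- function(model, y, geometry) {
  sp <- walker_point_state(model_ctx(model), 5L, geometry$spool_axis_local, y)
  sh <- walker_point_state(model_ctx(model), 4L, geometry$shank_attachment_local, y)
  list(spool = sp[1:2], spool_vel = sp[3:4],
       shank = sh[1:2], shank_vel = sh[3:4])
}

exo_distances <- function(model, y, geometry) {
  p <- exo_points(model, y, geometry)
  c(anchor = sqrt(sum((geometry$anchor_position - p$spool)^2)),
    shank = sqrt(sum((p$shank - p$spool)^2)))
}

#' Update the brake state machine
#'
#' The brake engages when the stride phase of the exoskeleton-side leg
#' crosses the engagement timing and disengages at the disengagement timing
#' (half-open interval `[engage, disengage)`); switching is instantaneous.
#' At engagement the anchor-to-spool and shank-attachment-to-spool distances
#' are captured as the elongation reference.
#'
#' @param phase stride phase (%) of the exoskeleton-side leg.
#' @param params an `exo_params`.
#' @param state current `brake_state`.
#' @param model a `walker_model` (needed to capture the snapshot).
#' @param y state vector of the model at the current time.
#' @param geometry an `exo_geometry`.
#' @return updated `brake_state`.
#' @export
brake_update <- function(phase, params, state = brake_state(),
                         model = NULL, y = NULL,
                         geometry = exo_geometry()) {
  inside <- params$enabled &&
    phase >= params$engage_phase && phase < params$disengage_phase
  if (inside && !state$engaged) {
    snap <- if (!is.null(model) && !is.null(y))
      unname(exo_distances(model, y, geometry)) else c(0, 0)
    return(brake_state(TRUE, snap))
  }
  if (!inside && state$engaged) return(brake_state(FALSE))
  state
}

#' Elastic tendon elongation
#'
#' While the brake is engaged the elongation is
#' `e = max(0, [d_anchor - d_anchor0] + spool_ratio * [l_shank - l_shank0])`
#' where `d_anchor` is the anchor-to-spool distance, `l_shank` the
#' shank-attachment-to-spool distance and the `0` subscripts the engagement
#' snapshot.  Disengaged, the tendon is kept taut but unstretched: 0.
#'
#' @param model a `walker_model`.
#' @param y model state vector.
#' @param geometry an `exo_geometry`.
#' @param brake a `brake_state`.
#' @return elongation (m), non-negative.
#' @export
tendon_elongation <- function(model, y, geometry, brake) {
  if (!brake$engaged) return(0)
  d <- exo_distances(model, y, geometry)
  max(0, (d[["anchor"]] - brake$engage_snapshot[1]) +
        geometry$spool_ratio * (d[["shank"]] - brake$engage_snapshot[2]))
}

#' Exoskeleton wrenches on foot and shank
#'
#' The elastic tendon pulls the foot spool-axis point toward the anchor with
#' `F_elastic = body_mass * stiffness * elongation` (unilateral: never
#' negative); the rigid tendon carries `spool_ratio * F_elastic` and pulls
#' the shank attachment and the spool-axis point together (equal and
#' opposite).
#'
#' @inheritParams tendon_elongation
#' @param params an `exo_params`.
#' @param body_mass body mass used for the stiffness normalization (kg).
#' @return list with elements `elongation` (m), `F_elastic`, `F_rigid` (N)
#'   and `wrenches`: a list of `(body, point, force)` entries in world
#'   coordinates (`body` is `"foot"` or `"shank"`).
#' @export
exo_wrenches <- function(model, y, geometry, params, brake,
                         body_mass = model$config$body_mass) {
  e <- tendon_elongation(model, y, geometry, brake)
  if (e <= 0)
    return(list(elongation = 0, F_elastic = 0, F_rigid = 0, wrenches = list()))
  p <- exo_points(model, y, geometry)
  Fel <- body_mass * params$stiffness * e
  Frig <- geometry$spool_ratio * Fel
  u_anchor <- (geometry$anchor_position - p$spool)
  u_anchor <- u_anchor / sqrt(sum(u_anchor^2))
  u_shank <- (p$shank - p$spool)
  u_shank <- u_shank / sqrt(sum(u_shank^2))
  list(elongation = e, F_elastic = Fel, F_rigid = Frig,
       wrenches = list(
         list(body = "foot", point = p$spool, force = Fel * u_anchor),
         list(body = "foot", point = p$spool, force = Frig * u_shank),
         list(body = "shank", point = p$shank, force = -Frig * u_shank)))
}

#' Equivalent ankle assistance torque
#'
#' Reduces the exoskeleton wrenches to the equivalent torque about the ankle
#' joint (the generalized force on the ankle coordinate): the moment, about
#' the ankle joint centre, of the forces applied to the foot.  Normalized to
#' body mass.
#'
#' @param model a `walker_model`.
#' @param y model state vector.
#' @param wr result of [exo_wrenches()].
#' @param body_mass normalization mass (kg).
#' @return ankle torque (N m/kg); negative values are plantarflexing in the
#'   model's CCW convention.
#' @export
assist_torque <- function(model, y, wr, body_mass = model$config$body_mass) {
  if (length(wr$wrenches) == 0) return(0)
  ankle <- walker_point_state(model_ctx(model), 4L,
                              c(0, -model$config$geometry$L_shank), y)[1:2]
  tau <- 0
  for (w in wr$wrenches) {
    if (w$body != "foot") next
    r <- w$point - ankle
    tau <- tau + r[1] * w$force[2] - r[2] * w$force[1]
  }
  tau / body_mass
}
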