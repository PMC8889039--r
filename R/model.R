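# 10-segment planar walking model: segment specifications, joint topology and
# the articulated-chain builder used by the dynamics core.
#
# Coordinate conventions (used everywhere):
#   * world x anterior, y up; the belt surface moves at -belt_speed * x-hat
#   * all rotations CCW-positive in the sagittal plane (viewed from the
#     model's right); generalized coordinates are pelvis x, y, rotation plus
#     9 joint angles (child CCW relative to parent)
#   * clinical signs: hip flexion = +raw, knee flexion = -raw, ankle
#     dorsiflexion = +raw, metatarsophalangeal extension (toes up) = +raw

#' Segment specification
#'
#' A single rigid segment of the planar walking model.
#'
#' @param name segment label.
#' @param mass segment mass (kg), must be positive.
#' @param length segment length (m), must be positive.
#' @param com_offset distance of the centre of mass from the proximal joint
#'   along the segment axis (m), in `[0, length]`.
#' @param inertia_com moment of inertia about the COM (kg m^2), non-negative.
#' @param proximal_joint name of the joint connecting the segment to its
#'   parent, or `NA` for the root (pelvis).
#' @return a one-row `data.frame` with class `segment_spec` columns.
#' @export
segment_spec <- function(name, mass, length, com_offset, inertia_com,
                         proximal_joint = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(mass) || mass <= 0) stop("segment mass must be positive: ", name)
  if (!is.finite(length) || length <= 0) stop("segment length must be positive: ", name)
  if (com_offset < 0 || com_offset > length)
    stop("com_offset must lie within [0, length]: ", name)
  if (inertia_com < 0) stop("inertia_com must be non-negative: ", name)
  data.frame(name = name, mass = mass, length = length,
             com_offset = com_offset, inertia_com = inertia_com,
             proximal_joint = proximal_joint, stringsAsFactors = FALSE)
}

#' Default model configuration
#'
#' Builds the 10-segment sagittal-plane model (head-arms-trunk, pelvis and
#' paired thighs, shanks, feet and toes) from anthropometric regression
#' fractions scaled to a body mass and height.  The 9 joints are the
#' lumbo-sacral joint, two hips (coincident in the sagittal plane), two knees,
#' two ankles and two passive metatarsophalangeal joints.
#'
#' @param body_mass total body mass (kg).
#' @param height standing height (m).
#' @param belt_speed treadmill belt speed (m/s); the belt surface moves
#'   posteriorly at this speed.
#' @param gravity gravitational acceleration (m/s^2).
#' @param added_mass named numeric `c(shank = , foot = )` giving the orthosis
#'   mass attached to the exoskeleton-side shank and foot segment COMs (kg);
#'   applied only when the exoskeleton is worn.
#' @param mtp_stiffness passive rotary-spring stiffness of the
#'   metatarsophalangeal joints (N m/rad).
#' @param mtp_damping passive damping of the metatarsophalangeal joints
#'   (N m s/rad).
#' @return a list of class `model_config`.
#' @export
default_model_config <- function(body_mass = 80, height = 1.80,
                                 belt_speed = 1.18, gravity = 9.81,
                                 added_mass = c(shank = 0.3, foot = 0.5),
                                 mtp_stiffness = 15, mtp_damping = 0.8) {
  stopifnot(body_mass > 0, height > 0)
  # segment lengths (m)
  L_pelvis <- 0.070 * height          # hip centre to lumbo-sacral joint
  L_hat    <- 0.300 * height          # lumbo-sacral joint towards the head
  L_thigh  <- 0.245 * height
  L_shank  <- 0.246 * height
  foot_len <- 0.152 * height          # heel to toe tip
  ankle_h  <- 0.044 * height          # ankle joint height above the sole
  L_foot   <- 0.075 * height          # ankle to metatarsophalangeal joint span
  L_toes   <- foot_len - 0.038 * height - L_foot
  heel_x   <- -0.038 * height         # heel point, anterior of the ankle

  # mass fractions (de Leva-style regression, toes split off the foot)
  fr <- c(pelvis = 0.112, hat = 0.492, thigh = 0.1416, shank = 0.0433,
          foot = 0.0103, toes = 0.0034)
  fr <- fr / (fr["pelvis"] + fr["hat"] +
                2 * (fr["thigh"] + fr["shank"] + fr["foot"] + fr["toes"]))
  m <- fr * body_mass

  # radii of gyration about the COM, as fractions of segment length
  seg <- function(name, mass, len, com_frac, rg_frac, joint) {
    segment_spec(name, mass, len, com_frac * len,
                 mass * (rg_frac * len)^2, joint)
  }
  segments <- rbind(
    seg("pelvis", m[["pelvis"]], L_pelvis, 0.40, 0.80, NA_character_),
    seg("hat",    m[["hat"]],    L_hat,    0.40, 0.45, "lumbosacral"),
    seg("thigh_r", m[["thigh"]], L_thigh,  0.41, 0.329, "hip_r"),
    seg("shank_r", m[["shank"]], L_shank,  0.44, 0.255, "knee_r"),
    seg("foot_r",  m[["foot"]],  L_foot,   0.45, 0.45,  "ankle_r"),
    seg("toes_r",  m[["toes"]],  L_toes,   0.40, 0.30,  "mtp_r"),
    seg("thigh_l", m[["thigh"]], L_thigh,  0.41, 0.329, "hip_l"),
    seg("shank_l", m[["shank"]], L_shank,  0.44, 0.255, "knee_l"),
    seg("foot_l",  m[["foot"]],  L_foot,   0.45, 0.45,  "ankle_l"),
    seg("toes_l",  m[["toes"]],  L_toes,   0.40, 0.30,  "mtp_l")
  )

  joints <- data.frame(
    name   = c("lumbosacral", "hip_r", "knee_r", "ankle_r", "mtp_r",
               "hip_l", "knee_l", "ankle_l", "mtp_l"),
    parent = c("pelvis", "pelvis", "thigh_r", "shank_r", "foot_r",
               "pelvis", "thigh_l", "shank_l", "foot_l"),
    child  = c("hat", "thigh_r", "shank_r", "foot_r", "toes_r",
               "thigh_l", "shank_l", "foot_l", "toes_l"),
    passive_stiffness = c(NA, NA, NA, NA, mtp_stiffness,
                          NA, NA, NA, mtp_stiffness),
    stringsAsFactors = FALSE
  )

  structure(list(
    segments = segments, joints = joints,
    body_mass = body_mass, height = height,
    belt_speed = belt_speed, gravity = gravity,
    added_mass = added_mass,
    mtp_stiffness = mtp_stiffness, mtp_damping = mtp_damping,
    geometry = list(
      L_pelvis = L_pelvis, L_hat = L_hat, L_thigh = L_thigh,
      L_shank = L_shank, L_foot = L_foot, L_toes = L_toes,
      ankle_height = ankle_h, heel_x = heel_x,
      sphere_radius = 0.02,
      # contact sphere centres in their segment frames; sphere bottoms are
      # flush with the sole plane when the foot is flat
      heel_sphere = c(heel_x, -(ankle_h - 0.02)),
      mtp_sphere  = c(L_foot, -(ankle_h - 0.02)),
      mtp_joint   = c(L_foot, -(ankle_h - 0.03)),
      toe_sphere  = c(L_toes - 0.02, -0.01),
      foot_com_drop = -0.05, toes_com_drop = -0.01
    )
  ), class = "model_config")
}

validate_model_config <- function(config) {
  s <- config$segments
  if (nrow(s) != 10L) stop("model requires exactly 10 segments, got ", nrow(s))
  if (anyDuplicated(s$name)) stop("duplicate segment names")
  j <- config$joints
  if (nrow(j) != 9L) stop("model requires exactly 9 joints, got ", nrow(j))
  if (anyDuplicated(j$name)) stop("duplicate joint names")
  if (!all(j$parent %in% s$name) || !all(j$child %in% s$name))
    stop("disconnected topology: joint references unknown segment")
  mtp <- j$name[!is.na(j$passive_stiffness)]
  if (!setequal(mtp, c("mtp_r", "mtp_l")))
    stop("exactly the two metatarsophalangeal joints must carry passive stiffness")
  if (any(s$mass <= 0) || any(s$length <= 0)) stop("nonpositive mass/length")
  invisible(config)
}

#' Coordinate names of the walking model
#' @return character vector of the 12 generalized coordinates.
#' @export
coordinate_names <- function() {
  c("pelvis_x", "pelvis_y", "pelvis_rot",
    "lumbosacral", "hip_r", "knee_r", "ankle_r", "mtp_r",
    "hip_l", "knee_l", "ankle_l", "mtp_l")
}

joint_coord_names <- function() coordinate_names()[4:12]

#' Build the articulated walking model
#'
#' Assembles the planar kinematic tree (floating pelvis base + 9 revolute
#' joints, 12 generalized coordinates) from a model configuration.
#'
#' @param config a `model_config`, see [default_model_config()].
#' @param exo_mass logical; add the orthosis mass (`config$added_mass`) to the
#'   right shank and foot segment COMs, emulating the worn device.
#' @return an object of class `walker_model`.
#' @export
build_model <- function(config = default_model_config(), exo_mass = FALSE) {
  validate_model_config(config)
  g <- config$geometry
  s <- config$segments
  mass <- s$mass
  names(mass) <- s$name
  icom <- s$inertia_com
  names(icom) <- s$name
  if (isTRUE(exo_mass)) {   # point masses at segment COMs: inertia unchanged
    mass[["shank_r"]] <- mass[["shank_r"]] + config$added_mass[["shank"]]
    mass[["foot_r"]]  <- mass[["foot_r"]] + config$added_mass[["foot"]]
  }

  # body order: pelvis, hat, thigh_r, shank_r, foot_r, toes_r, thigh_l, ...
  order <- c("pelvis", "hat", "thigh_r", "shank_r", "foot_r", "toes_r",
             "thigh_l", "shank_l", "foot_l", "toes_l")
  parent <- c(-1L, 0L, 0L, 2L, 3L, 4L, 0L, 6L, 7L, 8L)
  jpos <- rbind(
    c(0, 0),                      # pelvis (floating base)
    c(0, g$L_pelvis),             # lumbosacral in pelvis
    c(0, 0),                      # hip_r in pelvis
    c(0, -g$L_thigh),             # knee_r in thigh
    c(0, -g$L_shank),             # ankle_r in shank
    g$mtp_joint,                  # mtp_r in foot
    c(0, 0), c(0, -g$L_thigh), c(0, -g$L_shank), g$mtp_joint
  )
  off <- s$com_offset
  names(off) <- s$name
  com <- rbind(
    c(0, off[["pelvis"]]),
    c(0, off[["hat"]]),
    c(0, -off[["thigh_r"]]), c(0, -off[["shank_r"]]),
    c(off[["foot_r"]], g$foot_com_drop), c(off[["toes_r"]], g$toes_com_drop),
    c(0, -off[["thigh_l"]]), c(0, -off[["shank_l"]]),
    c(off[["foot_l"]], g$foot_com_drop), c(off[["toes_l"]], g$toes_com_drop)
  )

  chain <- list(parent = parent, jpos = jpos, com = com,
                mass = unname(mass[order]), icom = unname(icom[order]),
                floating = TRUE, gravity = config$gravity)

  r <- g$sphere_radius
  spheres <- rbind(                      # body (1-based), lx, ly, radius
    c(5, g$heel_sphere, r), c(5, g$mtp_sphere, r), c(6, g$toe_sphere, r),
    c(9, g$heel_sphere, r), c(9, g$mtp_sphere, r), c(10, g$toe_sphere, r)
  )
  colnames(spheres) <- c("body", "lx", "ly", "r")
  rownames(spheres) <- c("heel_r", "mtp_r", "toe_r", "heel_l", "mtp_l", "toe_l")

  structure(list(
    config = config, chain = chain, spheres = spheres,
    bodies = order, exo_mass = isTRUE(exo_mass),
    body_mass = config$body_mass + if (isTRUE(exo_mass)) sum(config$added_mass) else 0,
    standing_hip_height = g$L_thigh + g$L_shank + g$ankle_height,
    coord_names = coordinate_names()
  ), class = "walker_model")
}

#' Total model mass
#' @param model a `walker_model`.
#' @return sum of all segment masses including any attached orthosis mass (kg).
#' @export
total_mass <- function(model) sum(model$chain$mass)

#' @export
print.walker_model <- function(x, ...) {
  cat("<walker_model>: 10 segments, 12 generalized coordinates\n")
  cat(sprintf("  total mass %.2f kg (orthosis %s), hip height %.3f m\n",
              total_mass(x), if (x$exo_mass) "worn" else "absent",
              x$standing_hip_height))
  invisible(x)
}

#' Forward dynamics of the walking model
#'
#' Solves `M(q) qdd = tau_generalized` for the joint accelerations given
#' applied joint torques and external point forces.  Deterministic; used
#' directly for diagnostics and oracle tests, and internally by the
#' integrator.
#'
#' @param model a `walker_model`.
#' @param state numeric vector: 12 generalized coordinates followed by 12
#'   velocities (extra entries such as controller integrator states are
#'   ignored).
#' @param torques applied joint torques (N m), length 9 in the order of
#'   `coordinate_names()[4:12]`.
#' @param wrenches external point forces: a matrix with columns
#'   `(body, lx, ly, fx, fy)` -- body index (1 = pelvis, ... in the order of
#'   `model$bodies`), attachment point in the body frame (m) and world-frame
#'   force (N); or `NULL`.
#' @param gravity_enabled include gravity.
#' @return numeric length-12 vector of generalized accelerations.
#' @export
forward_dynamics <- function(model, state, torques = numeric(9),
                             wrenches = NULL, gravity_enabled = TRUE) {
  stopifnot(length(torques) == 9)
  chain <- model$chain
  if (!gravity_enabled) chain$gravity <- 0
  q <- state[1:12]; qd <- state[13:24]
  if (!all(is.finite(c(q, qd)))) stop("non-finite state")
  tau <- c(0, 0, 0, torques)
  planar_chain_accel(chain, q, qd, tau,
                     if (is.null(wrenches)) NULL else as.matrix(wrenches))
}
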