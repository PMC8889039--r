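# Synthetic periodic reference gait kinematics.
#
# The reference emulates normative treadmill walking at a given cycle
# duration and belt speed.  It is constructed in task space -- a pelvis
# height trajectory plus an ankle-point/foot-pitch trajectory that is locked
# to the belt during stance (the stance foot travels posteriorly at exactly
# the belt speed) and rolls over the metatarsophalangeal contact during
# push-off -- and converted to hip/knee/ankle joint angles by two-link
# inverse kinematics.  Joint trajectories are stored as truncated Fourier
# series, so they are exactly periodic and C-infinity, with analytic
# derivatives.
#
# Stride-phase convention: 0% = ipsilateral leg most anterior; heel strike
# near 10%; contralateral events are shifted by 50%.

ref_joint_sets <- c("hip", "knee", "ankle")

default_gait_shape <- function() {
  list(
    phase_heel_strike = 0.08,   # start of belt-locked stance; the foot
                                # descends its last touchdown_lift onto the
                                # belt while already moving with it, so the
                                # detected heel strike lands near 10%
    phase_heel_off    = 0.45,   # heel-rise onset
    phase_toe_off     = 0.57,   # end of stance
    pitch_max         = 0.85,   # peak foot pitch during push-off (rad, CW)
    stance_mid_phase  = 0.27,   # phase at which the stance ankle passes x=0
    touchdown_lift    = 0.014,  # remaining descent at belt-lock onset (m)
    touchdown_dur     = 0.08,   # descent duration (fraction of stride)
    entry_pitch       = 0,      # optional toes-up pitch at belt-lock onset
    entry_pitch_dur   = 0.06,   # decay of the entry pitch (fraction)
    stance_overdrive  = 1.0,    # stance travel speed relative to the belt:
                                # >1 pre-compensates the distance lost in
                                # the touchdown transient each step
    # reference pelvis pitch over the stride (rad), half-cycle periodic
    # (harmonics of twice the stride frequency); zero by default -- the
    # trunk's own pitch waveform emerges from the closed loop
    pelvis_pitch_coef = c(0, 0, 0, 0, 0, 0, 0),
    pelvis_drop       = 0.031,  # mean pelvis lowering below standing (m)
    ground_sink       = 0.008,  # expected contact penetration built into
                                # the stance plane so touchdown is on time
    pelvis_amp        = 0.0265, # pelvis vertical half-excursion (m)
    pelvis_peak_phase = 0.305,  # phase of peak pelvis height (mid-stance)
    swing_knots = data.frame(   # swing-phase ankle-point path
      phase = c(0.68, 0.76, 0.86, 0.94, 1.00, 1.05),
      x     = c(-0.28, -0.05, 0.17, 0.26, 0.285, 0.280),
      y     = c(0.19, 0.205, 0.17, 0.14, 0.118, 0.095)
    ),
    # swing ankle-angle knots (rad, dorsiflexion positive); the push-off
    # plantarflexion recovers toward the almost-flat-foot landing posture
    swing_ankle = data.frame(
      phase = c(0.68, 0.78, 0.88, 1.00),
      angle = c(-0.28, -0.12, -0.08, -0.12)
    )
  )
}

smoothstep <- function(u) { u <- pmin(pmax(u, 0), 1); u * u * (3 - 2 * u) }

# half-cycle-periodic pelvis pitch waveform (rad); phi in cycle fractions
eval_pelvis_pitch <- function(coef, phi, deriv = 0, period = 1) {
  u <- 2 * phi                       # half-cycle phase
  out <- if (deriv == 0) rep(coef[1], length(phi)) else numeric(length(phi))
  nh <- (length(coef) - 1) / 2
  for (j in seq_len(nh)) {
    w <- 2 * pi * j
    a <- coef[2 * j]; b <- coef[2 * j + 1]
    if (deriv == 0) out <- out + a * cos(w * u) + b * sin(w * u)
    else out <- out + (2 * w / period) * (-a * sin(w * u) + b * cos(w * u))
  }
  out
}

# Task-space construction + IK on a dense phase grid; returns joint angle
# samples (radians, model CCW convention) and the pelvis height law.
build_base_kinematics <- function(cycle_duration, speed, config, shape, n = 2048) {
  g <- config$geometry
  Lt <- g$L_thigh; Ls <- g$L_shank
  stride <- speed * cycle_duration
  hip0 <- Lt + Ls + g$ankle_height
  y0 <- hip0 - shape$pelvis_drop - shape$ground_sink

  phi <- seq(0, 1, length.out = n + 1)[1:n]
  pelvis_y <- function(ph) y0 + shape$pelvis_amp * cos(4 * pi * (ph - shape$pelvis_peak_phase))

  hs <- shape$phase_heel_strike; ho <- shape$phase_heel_off
  to <- shape$phase_toe_off
  phi_mid <- shape$stance_mid_phase
  # world position of the metatarsophalangeal contact-sphere centre while the
  # foot is on the belt (belt-locked), centred so the ankle passes x = 0 at
  # the stance mid phase
  stride_eff <- stride * shape$stance_overdrive
  msx0 <- g$L_foot + stride_eff * (phi_mid - hs)
  ms_y <- 0.02 - shape$ground_sink      # sphere centre height, sunk
  ankle_rel <- c(-g$L_foot, g$ankle_height - 0.02)     # mtp sphere -> ankle

  pitch_stance <- function(ph)
    -shape$pitch_max * smoothstep((ph - ho) / (to - ho)) +
      shape$entry_pitch * (1 - smoothstep((ph - hs) / shape$entry_pitch_dur))
  heel_rel <- -g$heel_sphere                     # heel sphere centre -> ankle
  heel_off_x <- g$heel_sphere[1] - g$mtp_sphere[1]
  stance_point <- function(ph) {
    p <- pitch_stance(ph)
    msx <- msx0 - stride_eff * (ph - hs)
    # final descent onto the belt happens while already belt-locked
    lift <- shape$touchdown_lift * (1 - smoothstep((ph - hs) / shape$touchdown_dur))
    cp <- cos(p); sp <- sin(p)
    entry <- ph < hs + shape$entry_pitch_dur
    # entry rolls about the belt-locked heel contact; mid-stance and
    # push-off roll about the metatarsophalangeal contact
    x <- ifelse(entry,
                msx + heel_off_x + cp * heel_rel[1] - sp * heel_rel[2],
                msx + cp * ankle_rel[1] - sp * ankle_rel[2])
    y <- ifelse(entry,
                ms_y + sp * heel_rel[1] + cp * heel_rel[2] + lift,
                ms_y + sp * ankle_rel[1] + cp * ankle_rel[2] + lift)
    cbind(x = x, y = y, pitch = p)
  }

  # swing: spline through knots, joined to the stance segment at both ends
  sk <- shape$swing_knots
  sk$x <- sk$x * ifelse(sk$x > 0, shape$stance_overdrive, 1)
  pre <- stance_point(c(to - 0.02, to - 0.01, to))
  kn_phase <- c(to - 0.02, to - 0.01, to, sk$phase, 1 + hs, 1 + hs + 0.01, 1 + hs + 0.02)
  post <- stance_point(1e-9 + c(hs, hs + 0.01, hs + 0.02))
  kn_x <- c(pre[, 1], sk$x, post[, 1])
  kn_y <- c(pre[, 2], sk$y, post[, 2])
  fx <- splinefun(kn_phase, kn_x, method = "natural")
  fy <- splinefun(kn_phase, kn_y, method = "natural")

  in_stance <- phi >= hs & phi <= to
  in_swing_lo <- phi < hs          # early-cycle part of swing (wrapped)
  ank <- matrix(0, n, 3)
  ank[in_stance, ] <- stance_point(phi[in_stance])
  sw <- !in_stance
  swing_phase <- ifelse(in_swing_lo, phi + 1, phi)[sw]
  ank[sw, 1:2] <- cbind(fx(swing_phase), fy(swing_phase))

  # two-link inverse kinematics (hip at pelvis origin)
  yp <- pelvis_y(phi)
  dx <- ank[, 1]
  dyv <- yp - ank[, 2]
  D <- sqrt(dx^2 + dyv^2)
  D <- pmin(D, 0.999 * (Lt + Ls))
  cosk <- pmin(pmax((D^2 - Lt^2 - Ls^2) / (2 * Lt * Ls), -1), 1)
  kflex <- acos(cosk)
  alpha <- acos(pmin(pmax((Lt^2 + D^2 - Ls^2) / (2 * Lt * D), -1), 1))
  theta_line <- atan2(dx, dyv)
  theta_t <- theta_line + alpha
  theta_s <- theta_t - kflex

  # ankle angle: in stance from the foot pitch (the foot is on the belt);
  # in swing from a direct dorsiflexion profile splined between the toe-off
  # plantarflexion and the almost-flat-foot landing posture
  q_ankle <- ank[, 3] - theta_s
  at_phase <- function(ph) q_ankle[which.min(abs(phi - ph))]
  sa <- shape$swing_ankle
  fa <- splinefun(c(to, sa$phase, 1 + hs), c(at_phase(to), sa$angle, at_phase(hs)),
                  method = "natural")
  q_ankle[sw] <- fa(swing_phase)

  # hip joint angle accounts for the reference pelvis-pitch waveform: the
  # thigh world orientation from the IK minus the pitching pelvis
  pp <- eval_pelvis_pitch(shape$pelvis_pitch_coef, phi)

  list(phi = phi,
       hip = theta_t - pp, knee = -kflex, ankle = q_ankle,
       pelvis = list(y0 = y0, amp = shape$pelvis_amp,
                     peak_phase = shape$pelvis_peak_phase,
                     pitch_coef = shape$pelvis_pitch_coef),
       stride_length = stride)
}

# Least-squares truncated Fourier fit on a uniform grid (via FFT).
fourier_fit <- function(x, K) {
  n <- length(x)
  co <- fft(x) / n
  list(a0 = Re(co[1]),
       a = 2 * Re(co[2:(K + 1)]),
       b = -2 * Im(co[2:(K + 1)]))
}

fourier_eval <- function(a0, a, b, ph, deriv = 0, period = 1) {
  out <- if (deriv == 0) rep(a0, length(ph)) else numeric(length(ph))
  for (k in seq_along(a)) {
    w <- 2 * pi * k
    if (deriv == 0)
      out <- out + a[k] * cos(w * ph) + b[k] * sin(w * ph)
    else
      out <- out + (w / period) * (-a[k] * sin(w * ph) + b[k] * cos(w * ph))
  }
  out
}

#' Synthesize periodic reference gait kinematics
#'
#' Builds the periodic hip/knee/ankle reference trajectories used to drive
#' the walking model, either from a supplied harmonic coefficient set or from
#' the package's normative task-space construction (see the methods
#' vignette).  Trajectories are truncated Fourier series over stride phase:
#' exactly periodic, C1-continuous, with analytic derivatives.  The
#' contralateral leg uses the same trajectories shifted by 50% of stride.
#'
#' @param cycle_duration gait cycle duration (s).
#' @param speed belt / walking speed (m/s); implied stride length is
#'   `speed * cycle_duration`.
#' @param harmonics optional coefficient set: a list with `a0` (length-3
#'   vector) and `A`, `B` (3 x K matrices), rows ordered hip, knee, ankle.
#' @param n_cycles number of identical cycles chained together.
#' @param config model configuration used for limb geometry.
#' @param n_harmonics number of harmonics fitted to the constructed pattern.
#' @param shape construction shape parameters, see the vignette.
#' @return object of class `gait_reference`.
#' @export
make_reference <- function(cycle_duration = 1.21, speed = 1.18,
                           harmonics = NULL, n_cycles = 4,
                           config = default_model_config(),
                           n_harmonics = 14, shape = default_gait_shape()) {
  stopifnot(cycle_duration > 0, speed > 0, n_cycles >= 1)
  pelvis <- NULL
  if (is.null(harmonics)) {
    base <- build_base_kinematics(cycle_duration, speed, config, shape)
    co <- lapply(ref_joint_sets, function(j) fourier_fit(base[[j]], n_harmonics))
    a0 <- vapply(co, `[[`, numeric(1), "a0")
    A <- do.call(rbind, lapply(co, `[[`, "a"))
    B <- do.call(rbind, lapply(co, `[[`, "b"))
    pelvis <- base$pelvis
  } else {
    if (!is.list(harmonics) || !all(c("a0", "A", "B") %in% names(harmonics)))
      stop("harmonics must be a list with elements a0, A, B")
    a0 <- harmonics$a0; A <- as.matrix(harmonics$A); B <- as.matrix(harmonics$B)
    if (length(a0) != 3L || nrow(A) != 3L || nrow(B) != 3L ||
        ncol(A) != ncol(B) || !all(is.finite(c(a0, A, B))))
      stop("non-periodic or malformed coefficient set: need finite a0[3], A[3,K], B[3,K]")
    pelvis <- harmonics$pelvis
  }
  rownames(A) <- rownames(B) <- names(a0) <- ref_joint_sets
  structure(list(
    cycle_duration = cycle_duration, speed = speed,
    stride_length = speed * cycle_duration,
    n_cycles = n_cycles,
    coef = list(a0 = a0, A = A, B = B),
    pelvis = pelvis,
    phase_offset_contralateral = 50
  ), class = "gait_reference")
}

#' Stride phase of a time point
#'
#' @param t time (s), non-negative.
#' @param cycle_duration gait cycle duration (s).
#' @return stride phase in percent, in `[0, 100)`.
#' @export
phase_of <- function(t, cycle_duration) {
  stopifnot(all(t >= 0), cycle_duration > 0)
  (t %% cycle_duration) / cycle_duration * 100
}

#' Evaluate reference joint angles
#'
#' @param ref a `gait_reference`.
#' @param phase stride phase in percent (ipsilateral convention).
#' @param leg `"right"` (the exoskeleton side, phase as given) or `"left"`
#'   (shifted by the contralateral offset).
#' @param deriv 0 for angles (rad), 1 for angular velocities (rad/s).
#' @return matrix with one row per phase value, columns hip, knee, ankle
#'   (model CCW sign convention).
#' @export
eval_reference <- function(ref, phase, leg = c("right", "left"), deriv = 0) {
  leg <- match.arg(leg)
  ph <- (phase + if (leg == "left") ref$phase_offset_contralateral else 0) / 100
  ph <- ph %% 1
  out <- vapply(ref_joint_sets, function(j) {
    fourier_eval(ref$coef$a0[[j]], ref$coef$A[j, ], ref$coef$B[j, ], ph,
                 deriv = deriv, period = ref$cycle_duration)
  }, numeric(length(ph)))
  if (length(ph) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, ref_joint_sets))
  out
}

#' Kinematic adjustment
#'
#' Per-joint angle offsets at evenly spaced stride-phase knots, the decision
#' variables of the genetic-algorithm refinement of the reference kinematics.
#' The lumbo-sacral joint is excluded (it is feedback-controlled, not
#' trajectory-tracked).
#'
#' @param hip,knee,ankle numeric vectors of knot offsets (rad).
#' @param n_knots number of evenly spaced phase knots.
#' @param bound absolute bound on any offset (rad).
#' @return object of class `kinematic_adjustment`.
#' @export
kinematic_adjustment <- function(hip = numeric(n_knots),
                                 knee = numeric(n_knots),
                                 ankle = numeric(n_knots),
                                 n_knots = 8, bound = 5 * pi / 180) {
  off <- list(hip = hip, knee = knee, ankle = ankle)
  for (j in names(off)) {
    if (length(off[[j]]) != n_knots)
      stop("offset vector for ", j, " must have length ", n_knots)
    if (any(abs(off[[j]]) > bound + 1e-12))
      stop("adjustment exceeds solution-space bound for ", j)
  }
  structure(c(off, list(n_knots = n_knots, bound = bound,
                        knot_phases = seq(0, 100, length.out = n_knots + 1)[1:n_knots])),
            class = "kinematic_adjustment")
}

#' Adjust reference kinematics
#'
#' Adds a periodic-spline perturbation through the adjustment knots to the
#' hip/knee/ankle trajectories and re-fits the Fourier series (the
#' lumbo-sacral control is untouched).  A zero adjustment returns an
#' equivalent reference.
#'
#' @param base a `gait_reference`.
#' @param adjustment a `kinematic_adjustment`.
#' @return adjusted `gait_reference`.
#' @export
adjust_reference <- function(base, adjustment) {
  stopifnot(inherits(base, "gait_reference"),
            inherits(adjustment, "kinematic_adjustment"))
  K <- ncol(base$coef$A)
  n <- 512
  ph <- seq(0, 100, length.out = n + 1)[1:n]
  out <- base
  kp <- adjustment$knot_phases
  for (j in ref_joint_sets) {
    if (all(adjustment[[j]] == 0)) next
    f <- splinefun(c(kp, 100), c(adjustment[[j]], adjustment[[j]][1]),
                   method = "periodic")
    vals <- fourier_eval(base$coef$a0[[j]], base$coef$A[j, ], base$coef$B[j, ],
                         ph / 100) + f(ph)
    co <- fourier_fit(vals, K)
    out$coef$a0[[j]] <- co$a0
    out$coef$A[j, ] <- co$a
    out$coef$B[j, ] <- co$b
  }
  out
}

#' Write / read reference kinematics as a delimited time series
#'
#' The on-disk format is a tab-separated table with columns `phase` (percent)
#' and `hip`, `knee`, `ankle` (radians, model sign convention), one stride
#' sampled uniformly; user-supplied kinematics in this format can replace the
#' synthetic defaults.
#'
#' @param ref a `gait_reference`.
#' @param path file path.
#' @param n number of samples over the stride.
#' @return `write_reference` returns `path` invisibly; `read_reference`
#'   returns a `gait_reference`.
#' @export
write_reference <- function(ref, path, n = 200) {
  ph <- seq(0, 100, length.out = n + 1)[1:n]
  ang <- eval_reference(ref, ph)
  df <- data.frame(phase = ph, hip = ang[, "hip"], knee = ang[, "knee"],
                   ankle = ang[, "ankle"])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @param cycle_duration,speed,n_cycles stride timing metadata for the
#'   reconstructed reference.
#' @param n_harmonics harmonics fitted to the samples.
#' @export
read_reference <- function(path, cycle_duration = 1.21, speed = 1.18,
                           n_cycles = 4, n_harmonics = 14) {
  df <- read.delim(path)
  need <- c("phase", "hip", "knee", "ankle")
  if (!all(need %in% names(df))) stop("reference file must have columns: ",
                                      paste(need, collapse = ", "))
  df <- df[order(df$phase), ]
  n <- 512
  ph <- seq(0, 100, length.out = n + 1)[1:n]
  co <- lapply(ref_joint_sets, function(j) {
    v <- approx(c(df$phase, 100), c(df[[j]], df[[j]][1]), xout = ph,
                rule = 2)$y
    fourier_fit(v, n_harmonics)
  })
  make_reference(cycle_duration, speed,
                 harmonics = list(a0 = vapply(co, `[[`, numeric(1), "a0"),
                                  A = do.call(rbind, lapply(co, `[[`, "a")),
                                  B = do.call(rbind, lapply(co, `[[`, "b"))),
                 n_cycles = n_cycles)
}

#' @export
print.gait_reference <- function(x, ...) {
  cat(sprintf("<gait_reference>: cycle %.3f s, speed %.2f m/s, stride %.3f m, %d cycle(s)\n",
              x$cycle_duration, x$speed, x$stride_length, x$n_cycles))
  invisible(x)
}
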