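# Gait event detection from per-sphere contact normal forces.

# threshold crossings with a debounce: a crossing only counts if the signal
# stays on the new side for at least `hold` seconds
debounced_crossings <- function(time, on, hold, up = TRUE) {
  if (!up) on <- !on
  idx <- which(!on[-length(on)] & on[-1]) + 1
  keep <- vapply(idx, function(i) {
    t1 <- time[i] + hold
    all(on[i:max(which(time <= t1))])
  }, logical(1))
  time[idx[keep]]
}

#' Detect gait events from contact forces
#'
#' Heel strike, heel-off, foot contact and toe-off are detected from
#' threshold crossings of the per-sphere contact normal forces (threshold:
#' 1% of body weight), debounced so that brief bounces during the landing
#' transient are not reported as separate events.  A heel strike is the
#' first sustained heel-sphere loading of each stance; toe-off is the last
#' sphere of a foot leaving the belt.  Events are returned for both legs
#' (`_r` / `_l` suffixes) with the stride phase of the exoskeleton-side
#' (right) cycle.
#'
#' @param sim a `walker_sim`.
#' @param threshold_bw force threshold as a fraction of body weight.
#' @param debounce debounce time as a fraction of the cycle.
#' @return `data.frame` with columns `label`, `time`, `phase`.
#' @export
detect_events <- function(sim, threshold_bw = 0.01, debounce = 0.03) {
  d <- sim$data
  thr <- threshold_bw * sim$body_mass * sim$model$config$gravity
  hold <- debounce * sim$cycle_duration
  ev <- data.frame(label = character(), time = numeric())
  add <- function(ev, lab, times) if (length(times))
    rbind(ev, data.frame(label = lab, time = times)) else ev
  for (side in c("r", "l")) {
    heel_on <- d[[paste0("fn_heel_", side)]] > thr
    any_on <- pmax(d[[paste0("fn_heel_", side)]], d[[paste0("fn_mtp_", side)]],
                   d[[paste0("fn_toe_", side)]]) > thr
    fc <- debounced_crossings(d$time, any_on, hold, up = TRUE)
    to <- debounced_crossings(d$time, any_on, hold, up = FALSE)
    hs_all <- debounced_crossings(d$time, heel_on, hold, up = TRUE)
    ho_all <- debounced_crossings(d$time, heel_on, hold, up = FALSE)
    # first sustained heel loading per stance; last heel unloading per stance
    stance_of <- function(t) findInterval(t, fc)
    hs <- hs_all[!duplicated(stance_of(hs_all))]
    ho <- ho_all[rev(!duplicated(rev(stance_of(ho_all))))]
    ev <- add(ev, paste0("heel_strike_", side), hs)
    ev <- add(ev, paste0("heel_off_", side), ho)
    ev <- add(ev, paste0("foot_contact_", side), fc)
    ev <- add(ev, paste0("toe_off_", side), to)
  }
  ev <- ev[order(ev$time), ]
  ev$phase <- phase_of(ev$time, sim$cycle_duration)
  rownames(ev) <- NULL
  ev
}

#' Times of a named event
#' @param sim a `walker_sim`.
#' @param label event label, e.g. `"heel_strike_r"`.
#' @return numeric vector of event times (s).
#' @export
event_times <- function(sim, label) sim$events$time[sim$events$label == label]

#' Average walking speed relative to the belt
#'
#' Gait speed measured as the stride length of the stance foot relative to
#' the moving belt -- the displacement of the heel between consecutive
#' ipsilateral heel strikes in belt-fixed coordinates -- divided by the
#' cycle duration.  For a periodic gait this equals the belt speed.
#'
#' @param sim a `walker_sim`.
#' @return speed (m/s).
#' @export
gait_speed <- function(sim) {
  hs <- event_times(sim, "heel_strike_r")
  if (length(hs) < 2) stop("need at least two ipsilateral heel strikes")
  ctx <- model_ctx(sim$model)
  g <- sim$model$config$geometry
  heel_x <- vapply(hs, function(t) {
    i <- which.min(abs(sim$data$time - t))
    y <- unlist(sim$data[i, c(coordinate_names(), paste0("d_", coordinate_names()))])
    walker_point_state(ctx, 5L, g$heel_sphere, c(y, numeric(6)))[1]
  }, numeric(1))
  # belt-fixed coordinate: x_rel = x_world + belt_speed * t
  xrel <- heel_x + sim$model$config$belt_speed * hs
  Tc <- sim$cycle_duration
  ok <- diff(hs) > 0.7 * Tc & diff(hs) < 1.3 * Tc   # single-stride intervals
  if (!any(ok)) stop("no clean stride interval between heel strikes")
  mean(diff(xrel)[ok]) / Tc
}
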