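# Push-off work metrics and sweep statistics.
#
# The efficacy criterion is the reduction of positive biological ankle work:
# the integral of the positive part of the biological ankle power over the
# 40-60% stride window, compared between an assisted condition and the
# NO-EXO baseline.  Stride-phase intervals where the assisted condition would
# require *additional negative* power compared to baseline are not counted
# as adequate assistance and are excluded from the savings.

#' Extract one representative cycle on a uniform phase grid
#'
#' Interpolates a simulated signal onto a uniform stride-phase grid (0.1%
#' resolution) over one gait cycle.  The default representative cycle is the
#' 3rd of 4 chained cycles: steady-state, away from the start-up and final
#' transients.
#'
#' @param sim a `walker_sim`.
#' @param column column of `sim$data` to extract.
#' @param cycle which cycle (1-based), or a vector of cycles whose profiles
#'   are ensemble-averaged on the phase grid (the gait-lab convention for a
#'   representative stride).
#' @param dphase phase resolution (%).
#' @return `data.frame` with columns `phase` and `value`.
#' @export
cycle_series <- function(sim, column, cycle = 2:4, dphase = 0.1) {
  Tc <- sim$cycle_duration
  ph <- seq(0, 100 - dphase, by = dphase)
  acc <- numeric(length(ph))
  for (cyc in cycle) {
    t0 <- (cyc - 1) * Tc
    if (sim$t_end < cyc * Tc - 1e-9)
      stop("simulation does not span cycle ", cyc)
    sel <- sim$data$time >= t0 - 1e-9 & sim$data$time <= t0 + Tc + 1e-9
    acc <- acc + approx(sim$data$time[sel], sim$data[[column]][sel],
                        xout = t0 + ph / 100 * Tc, rule = 2)$y
  }
  data.frame(phase = ph, value = acc / length(cycle))
}

#' Biological ankle power of the exoskeleton-side leg
#' @inheritParams cycle_series
#' @return `data.frame` with columns `phase` and `value` (W/kg).
#' @export
ankle_power_cycle <- function(sim, cycle = 2:4, dphase = 0.1)
  cycle_series(sim, "power_ankle_r", cycle, dphase)

#' Positive ankle work over a stride-phase window
#'
#' Trapezoidal integral of the positive part of the ankle power over the
#' given window (default 40-60% of stride), converted from phase to time
#' with the cycle duration.
#'
#' @param power `data.frame` with columns `phase` (%) and `value` (W/kg), or
#'   a numeric power vector.
#' @param window numeric length-2 phase window (%), inside `[0, 100]`.
#' @param cycle_duration cycle duration (s).
#' @param phase phase grid (%), needed when `power` is a bare vector.
#' @return positive work (J/kg).
#' @export
positive_ankle_work <- function(power, window = c(40, 60),
                                cycle_duration = 1.21, phase = NULL) {
  if (is.data.frame(power)) { phase <- power$phase; power <- power$value }
  if (window[1] < 0 || window[2] > 100 || window[1] >= window[2])
    stop("window must lie inside [0, 100]")
  sel <- phase >= window[1] & phase <= window[2]
  if (sum(sel) < 2) return(0)
  pracma::trapz(phase[sel] / 100 * cycle_duration, pmax(power[sel], 0))
}

#' Exoskeleton-attributable savings of positive ankle work
#'
#' Compares the biological ankle power of an assisted condition against the
#' NO-EXO baseline over the push-off window.  Savings are
#' `integral(max(P0,0) - max(Pa,0))` over the window, with samples where the
#' assisted condition demands additional negative power
#' (`Pa < min(P0, 0)`) excluded interval-wise (they contribute no savings).
#'
#' @param power_active,power_baseline `data.frame`s from
#'   [ankle_power_cycle()] on the same phase grid.
#' @param window phase window (%).
#' @param cycle_duration cycle duration (s).
#' @return list with `baseline_work`, `active_work`, `savings` (J/kg) and
#'   `reduction_pct` (%).
#' @export
ankle_work_savings <- function(power_active, power_baseline,
                               window = c(40, 60), cycle_duration = 1.21) {
  stopifnot(nrow(power_active) == nrow(power_baseline),
            max(abs(power_active$phase - power_baseline$phase)) < 1e-9)
  ph <- power_active$phase
  pa <- power_active$value
  p0 <- power_baseline$value
  sel <- ph >= window[1] & ph <= window[2]
  ph <- ph[sel]; pa <- pa[sel]; p0 <- p0[sel]
  tt <- ph / 100 * cycle_duration
  w0 <- pracma::trapz(tt, pmax(p0, 0))
  contrib <- pmax(p0, 0) - pmax(pa, 0)
  contrib[pa < pmin(p0, 0)] <- 0           # negative-power exclusion rule
  sav <- pracma::trapz(tt, contrib)
  list(baseline_work = w0,
       active_work = pracma::trapz(tt, pmax(pa, 0)),
       savings = sav,
       reduction_pct = 100 * sav / w0)
}

#' Percent reduction of positive ankle work
#'
#' @param active_work,baseline_work positive ankle work (J/kg);
#'   `baseline_work` must be positive.
#' @return reduction with respect to baseline (%), negative if assistance
#'   increased the work.
#' @export
reduction_pct <- function(active_work, baseline_work) {
  if (baseline_work <= 0) stop("baseline work must be positive")
  100 * (baseline_work - active_work) / baseline_work
}

#' Classify a brake disengagement timing
#'
#' Disengagements at or before mid-push-off lose the stored energy before it
#' can assist (`premature`); a narrow window shortly after push-off
#' initiation is `on-time`; later disengagements (`overdue`) keep pulling
#' the ankle into plantarflexion after push-off and their effect saturates
#' once the tendon is no longer elongated.
#'
#' @param disengage_phase brake disengagement timing (% of stride).
#' @param premature_max last timing classified premature.
#' @param ontime_max last timing classified on-time.
#' @return `"premature"`, `"on-time"` or `"overdue"`.
#' @export
classify_disengagement <- function(disengage_phase, premature_max = 50,
                                   ontime_max = 55) {
  stopifnot(premature_max < ontime_max)
  ifelse(disengage_phase <= premature_max, "premature",
         ifelse(disengage_phase <= ontime_max, "on-time", "overdue"))
}

#' Linear regression of work reduction on a sweep parameter
#'
#' Ordinary least squares with the squared Pearson correlation as R^2 and
#' the two-sided t-test p-value (n - 2 df) for the slope.
#'
#' @param x sweep parameter values.
#' @param y positive-ankle-work reductions (%).
#' @return list with `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
linreg_sweep <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0) stop("constant sweep parameter")
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))   # quiet on numerically perfect fits
  r <- if (sd(y) == 0) 0 else cor(x, y)
  p <- if (sd(y) == 0) 1 else s$coefficients["x", "Pr(>|t|)"]
  list(slope = unname(coef(fit)["x"]), intercept = unname(coef(fit)[1]),
       r2 = r^2, p = p, n = length(x))
}
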