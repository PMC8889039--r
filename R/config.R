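# YAML configuration: a single file carrying the model, contact, controller,
# reference and exoskeleton sections, with package defaults for anything
# omitted.

#' Read / write a simulation configuration
#'
#' The configuration file has YAML semantics with sections `model`
#' (body_mass, height, belt_speed, gravity, added_mass, mtp_stiffness,
#' mtp_damping), `contact` (the [default_contact_params()] fields),
#' `gains` (hip/knee/ankle kp/ki/kd, hat_upright, integrator_limit),
#' `reference` (cycle_duration, speed, n_cycles, n_harmonics) and `exo`
#' (stiffness, engage_phase, disengage_phase, enabled, geometry).  Omitted
#' entries take package defaults.
#'
#' @param path file path.
#' @return `read_config` returns a list with elements `config`
#'   (`model_config`), `contact`, `gains`, `reference_args`, `exo`,
#'   `geometry`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  m <- raw$model %||% list()
  config <- do.call(default_model_config, m[names(m) %in%
    names(formals(default_model_config))])
  contact <- do.call(default_contact_params, (raw$contact %||% list())[
    names(raw$contact %||% list()) %in% names(formals(default_contact_params))])
  gr <- raw$gains %||% list()
  gains_args <- list()
  for (j in c("hip", "knee", "ankle", "hat_upright"))
    if (!is.null(gr[[j]])) gains_args[[j]] <- unlist(gr[[j]])
  if (!is.null(gr$integrator_limit)) gains_args$integrator_limit <- gr$integrator_limit
  gains <- do.call(default_gains, gains_args)
  ra <- raw$reference %||% list()
  ex <- raw$exo
  exo <- NULL; geometry <- exo_geometry()
  if (!is.null(ex)) {
    exo <- exo_params(ex$stiffness %||% 4.85, ex$engage_phase %||% 29,
                      ex$disengage_phase %||% 53,
                      enabled = ex$enabled %||% TRUE)
    ge <- ex$geometry %||% list()
    geometry <- exo_geometry(
      anchor_position = unlist(ge$anchor_position %||% c(1.0, 0.05)),
      spool_axis_local = unlist(ge$spool_axis_local %||% c(-0.065, -0.045)),
      shank_attachment_local = unlist(ge$shank_attachment_local %||% c(-0.065, -0.16)),
      spool_ratio = ge$spool_ratio %||% 5)
  }
  list(config = config, contact = contact, gains = gains,
       reference_args = ra, exo = exo, geometry = geometry)
}

#' @rdname read_config
#' @param config a `model_config`.
#' @param contact a `contact_params`.
#' @param gains a `controller_gains`.
#' @param exo an `exo_params` or NULL.
#' @param geometry an `exo_geometry`.
#' @param reference_args list of [make_reference()] arguments.
#' @export
write_config <- function(path, config = default_model_config(),
                         contact = default_contact_params(),
                         gains = default_gains(), exo = NULL,
                         geometry = exo_geometry(),
                         reference_args = list(cycle_duration = 1.21,
                                               speed = 1.18, n_cycles = 4)) {
  out <- list(
    model = list(body_mass = config$body_mass, height = config$height,
                 belt_speed = config$belt_speed, gravity = config$gravity,
                 added_mass = as.list(config$added_mass),
                 mtp_stiffness = config$mtp_stiffness,
                 mtp_damping = config$mtp_damping),
    contact = unclass(contact),
    gains = list(hip = as.list(gains$hip), knee = as.list(gains$knee),
                 ankle = as.list(gains$ankle),
                 hat_upright = as.list(gains$hat_upright),
                 integrator_limit = gains$integrator_limit),
    reference = reference_args)
  if (!is.null(exo))
    out$exo <- c(unclass(exo), list(geometry = unclass(geometry)))
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
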