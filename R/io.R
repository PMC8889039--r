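# Simulation result writer: tidy delimited time series + JSON events sidecar.

#' Write a simulation result
#'
#' Writes the simulated time series as a tidy tab-separated table (one row
#' per sample: time, stride phase, per-joint angles/torques/powers, ground
#' reaction forces, tendon force) and the event log as a JSON sidecar
#' (`<path>.events.json`) that also records the condition metadata and any
#' energy dissipated at brake disengagements.
#'
#' @param sim a `walker_sim`.
#' @param path output path of the series table.
#' @param thin keep every `thin`-th sample.
#' @return `path`, invisibly.
#' @export
write_sim_result <- function(sim, path, thin = 1) {
  d <- sim$data[seq(1, nrow(sim$data), by = thin), ]
  keep <- c("time", "phase", coordinate_names(),
            paste0("tau_", joint_coord_names()),
            paste0("power_", joint_coord_names()),
            "grf_x_r", "grf_y_r", "grf_x_l", "grf_y_l",
            "tendon_force", "assist_torque", "elongation")
  write.table(d[, keep], path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(
    condition = if (is.null(sim$exo)) "NO-EXO"
                else if (!sim$exo$enabled) "NO-POWER" else "ACTIVE",
    exo = if (!is.null(sim$exo)) unclass(sim$exo),
    body_mass = sim$body_mass,
    cycle_duration = sim$cycle_duration,
    n_cycles = sim$n_cycles,
    fell = sim$fell,
    dissipated_energy_J = sim$dissipated_energy,
    events = sim$events
  )
  jsonlite::write_json(meta, paste0(path, ".events.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
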