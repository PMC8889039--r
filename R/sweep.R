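# Parameter sweep over tendon stiffness and brake timings.

#' Parameter sweep grid
#'
#' Default values are the study grid: 8 elastic tendon stiffness values
#' (N/m/kg), 7 brake engagement timings and 11 brake disengagement timings
#' (% of stride).  One value from each column forms a parameter triplet; all
#' triplets are tested.
#'
#' @param stiffness_values,engage_values,disengage_values numeric vectors.
#' @return list of class `sweep_grid`.
#' @export
sweep_grid <- function(stiffness_values = c(0.91, 1.52, 2.12, 2.73, 3.79,
                                            4.85, 6.97, 9.09),
                       engage_values = c(20, 23, 26, 29, 32, 35, 38),
                       disengage_values = c(44, 47, 50, 51, 52, 53, 54, 55,
                                            56, 59, 62)) {
  stopifnot(all(stiffness_values > 0),
            all(engage_values >= 0), all(disengage_values < 100))
  structure(list(stiffness_values = stiffness_values,
                 engage_values = engage_values,
                 disengage_values = disengage_values), class = "sweep_grid")
}

#' Enumerate all parameter triplets of a grid
#'
#' @param grid a `sweep_grid`.
#' @return `data.frame` with one row per triplet (columns `stiffness`,
#'   `engage`, `disengage`), the Cartesian product of the grid columns.
#' @export
enumerate_triplets <- function(grid = sweep_grid()) {
  out <- expand.grid(stiffness = grid$stiffness_values,
                     engage = grid$engage_values,
                     disengage = grid$disengage_values,
                     KEEP.OUT.ATTRS = FALSE)
  ok <- out$engage < out$disengage
  if (!all(ok)) out <- out[ok, ]
  rownames(out) <- NULL
  out
}

#' Run the parameter sweep
#'
#' Simulates every triplet of the grid and computes the push-off work
#' metrics against a NO-EXO baseline.  With `optimize = TRUE` each triplet
#' is solved `repeats` times by the genetic algorithm (seeds `1:repeats`)
#' and the representative solution selected; otherwise a single
#' tracking-only simulation per triplet is used.  Completed triplets are
#' checkpointed to `checkpoint_dir` (one file per triplet) and skipped on
#' re-runs, so an interrupted sweep is resumable.  Per-triplet failures are
#' recorded, not fatal.
#'
#' @param grid a `sweep_grid`.
#' @param model a `walker_model` built with `exo_mass = TRUE`.
#' @param baseline NO-EXO representative `walker_sim`.
#' @param reference the NO-EXO `gait_reference`.
#' @param optimize run the GA refinement per triplet.
#' @param repeats GA repetitions per triplet (with `optimize`).
#' @param settings a [ga_settings()] list.
#' @param geometry an `exo_geometry`.
#' @param checkpoint_dir optional directory for resumable records.
#' @param n_cycles simulated cycles.
#' @param window push-off phase window (%).
#' @param ... passed to [simulate_walking()].
#' @return `data.frame` of class `sweep_records`: one row per triplet with
#'   work metrics, reduction % and disengagement group.
#' @export
run_sweep <- function(grid, model, baseline, reference,
                      optimize = FALSE, repeats = 4,
                      settings = ga_settings(), geometry = exo_geometry(),
                      checkpoint_dir = NULL, n_cycles = 4,
                      window = c(40, 60), ...) {
  trip <- enumerate_triplets(grid)
  p_base <- ankle_power_cycle(baseline, cycle = min(3, baseline$n_cycles))
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  rows <- vector("list", nrow(trip))
  for (i in seq_len(nrow(trip))) {
    tr <- trip[i, ]
    tag <- sprintf("k%.2f_e%g_d%g", tr$stiffness, tr$engage, tr$disengage)
    ck <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, paste0(tag, ".tsv")) else NULL
    if (!is.null(ck) && file.exists(ck)) {
      rows[[i]] <- read.delim(ck)
      next
    }
    rec <- tryCatch({
      par <- exo_params(tr$stiffness, tr$engage, tr$disengage)
      sim <- if (optimize) {
        sols <- lapply(seq_len(repeats), function(s) {
          ga <- ga_optimize(model, par, reference, baseline,
                            settings = settings, seed = s,
                            geometry = geometry, ...)
          simulate_walking(model, ga$reference, exo = par,
                           geometry = geometry, n_cycles = n_cycles, ...)
        })
        select_representative(sols)
      } else {
        simulate_walking(model, reference, exo = par, geometry = geometry,
                         n_cycles = n_cycles, ...)
      }
      cyc <- max(1, min(3, floor(sim$t_end / sim$cycle_duration)))
      sav <- ankle_work_savings(ankle_power_cycle(sim, cycle = cyc), p_base,
                                window, sim$cycle_duration)
      data.frame(stiffness = tr$stiffness, engage = tr$engage,
                 disengage = tr$disengage,
                 positive_ankle_work = sav$active_work,
                 baseline_work = sav$baseline_work,
                 reduction_pct = sav$reduction_pct,
                 group = classify_disengagement(tr$disengage),
                 fell = sim$fell, error = NA_character_)
    }, error = function(e) {
      data.frame(stiffness = tr$stiffness, engage = tr$engage,
                 disengage = tr$disengage,
                 positive_ankle_work = NA_real_, baseline_work = NA_real_,
                 reduction_pct = NA_real_,
                 group = classify_disengagement(tr$disengage),
                 fell = NA, error = conditionMessage(e))
    })
    if (!is.null(ck)) write.table(rec, ck, sep = "\t", row.names = FALSE,
                                  quote = FALSE)
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_records", class(out))
  out
}
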