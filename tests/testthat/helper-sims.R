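# Shared fixtures: simulations are expensive, so the study conditions are
# simulated once per test session and cached.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .sim_cache)) assign(key, force(expr), .sim_cache)
  get(key, .sim_cache)
}

study_config <- function() cached("config", default_model_config())
study_model <- function() cached("model0", build_model(study_config()))
study_model_exo <- function() cached("model1",
                                     build_model(study_config(), exo_mass = TRUE))
study_reference <- function() cached("ref", make_reference(config = study_config()))

baseline_sim <- function() cached("base",
  simulate_walking(study_model(), study_reference()))

baseline_power <- function() cached("p0", ankle_power_cycle(baseline_sim()))

active_sim <- function() cached("active",
  simulate_walking(study_model_exo(), study_reference(),
                   exo = exo_params(4.85, 29, 53)))

exo_condition_sim <- function(stiffness, engage, disengage) {
  key <- sprintf("exo_%g_%g_%g", stiffness, engage, disengage)
  cached(key, simulate_walking(study_model_exo(), study_reference(),
                               exo = exo_params(stiffness, engage, disengage)))
}

condition_reduction <- function(stiffness, engage, disengage) {
  sim <- exo_condition_sim(stiffness, engage, disengage)
  if (sim$fell) return(NA_real_)
  ankle_work_savings(ankle_power_cycle(sim), baseline_power())$reduction_pct
}

# standing state: all joints at the zero (standing) pose
standing_state <- function(height = NULL) {
  y <- numeric(30)
  y[2] <- if (is.null(height)) study_model()$standing_hip_height else height
  y
}
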