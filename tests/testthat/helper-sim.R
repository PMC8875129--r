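# Shared fixtures: all test data is generated in code.

default_schedule <- function() sampling_schedule()

# Per-well pipeline: measured concentrations -> Papp
well_papp <- function(w, window = NULL) {
  dq <- cumulative_amounts(w$concs, vr = w$vr, vs = w$vs)
  fit <- transport_rate(dq, w$times, window = window)
  papp(fit$rate, w$area, w$c0)
}

# Simulate one bidirectional condition and return its group summary row
condition_summary <- function(params, c0, n_wells, seed,
                              schedule = default_schedule(), ...) {
  ds <- simulate_condition(params, schedule, c0_list = c0,
                           n_wells = n_wells, seed = seed, ...)
  summarize_groups(analyze_wells(ds$wells))
}

# Event-by-event mass bookkeeping: the independent oracle for the
# sampling-dilution correction. Walks the sampling protocol forward,
# tracking the mass carried away by each aliquot.
bookkeeping_dq <- function(concs, vr, vs) {
  withdrawn <- 0
  out <- numeric(length(concs))
  for (n in seq_along(concs)) {
    out[n] <- concs[n] * vr + withdrawn     # receiver mass + prior aliquots
    withdrawn <- withdrawn + concs[n] * vs  # this sample leaves the system
  }
  out
}

# Simulator parameter sets reused across files
passive_params <- function(p = 1.5e-6, noise_cv = 0, ...)
  transport_sim_params(p_passive = p, noise_cv = noise_cv, ...)

efflux_params <- function(inhibition = 0, noise_cv = 0)
  transport_sim_params(p_passive = 5e-6, vmax = 3.125e-4, km = 25,
                       inhibition = inhibition, noise_cv = noise_cv)
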