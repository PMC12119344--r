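# Transfer-function fits are the expensive shared resource of the suite:
# each synapse condition is fitted once per session and memoised here.
.tf_cache <- new.env(parent = emptyenv())

cached_fits <- function(name) {
  if (!exists(name, envir = .tf_cache)) {
    syn <- switch(name,
                  base = synapse_params(),                 # wake / NREM
                  prop = synapse_params(tau_i = 7),        # propofol-like
                  keta = synapse_params(tau_e = 3.75),     # ketamine-like
                  ti6  = synapse_params(tau_i = 6),
                  stop("unknown fit condition: ", name))
    assign(name,
           list(e = fit_transfer_function(neuron_params("RS"), syn, seed = 11),
                i = fit_transfer_function(neuron_params("FS"), syn, seed = 511),
                syn = syn),
           envir = .tf_cache)
  }
  get(name, envir = .tf_cache)
}

# The whole-brain study configuration used by the macroscale analyses:
# 20-region synthetic parcellation, sparse structured coupling, global
# coupling calibrated so the wake preset is a stable asynchronous state
# while slow-wave presets show coordinated low-frequency bursting.
study_connectome <- function() synthetic_connectome(20, density = 0.15,
                                                    seed = 42, G = 0.3)

study_hub <- function(con) which.max(colSums(con$weights))

preset_fits <- function(preset_name) {
  cached_fits(switch(preset_name,
                     wake = "base", NREM = "base",
                     propofol = "prop", ketamine = "keta"))
}
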