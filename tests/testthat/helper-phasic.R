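# shared fixtures: small-but-representative parameter sets
epsv_params <- function(...) {
  fn_params(eps_mode = "voltage_dependent", ...)
}

epsc_params <- function(...) {
  fn_params(eps_mode = "constant", ...)
}

# total spike count of a simulation
n_spikes <- function(sim) {
  sum(vapply(sim$trains, function(tr) length(tr$times), 1L))
}

# barrier heights that realize a target hazard value at D = 1
dU_for_hazard <- function(H, gamma = 5, beta = 3, p_exp = 1.5) {
  (log(gamma / H) / beta)^(1 / p_exp)
}
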