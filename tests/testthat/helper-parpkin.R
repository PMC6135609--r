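# shared fixtures: everything is generated in code, scaled down from the
# full acquisition (500 log-spaced points) to keep the suite quick

wt_params <- function() preset("WT")$params

fast_inst <- function(t_end, n_points = 120, seed = 1L, noise_sd = 0.0133) {
  instrument_spec(t_end = t_end, n_points = n_points, seed = seed,
                  noise_sd = noise_sd)
}

# small noiseless ternary dissociation series (4 competitor concs)
noiseless_dissoc <- function(params = wt_params(), n_points = 80,
                             concs = c(120, 500, 1500, 4000)) {
  generate_dissociation_series(
    params, concs, scheme = "ternary",
    instrument = fast_inst(5, n_points = n_points, noise_sd = 0))
}

noiseless_assoc <- function(params = rate_params(k1 = 3.1, k_m1 = 5),
                            n_points = 80) {
  generate_association_series(
    params, c(60, 106, 188, 250),
    instrument = fast_inst(0.025, n_points = n_points, noise_sd = 0))
}
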