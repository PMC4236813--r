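# Shared fixtures: wild-type truth parameters and small dataset builders.

wt_params <- function() psd_params()

wt_truth <- c(k_degENDO = 0.0028, k_leak = 0.01513, k_dark = 0.59,
              k_degLOV = 0.048)

# noiseless single-replicate three-condition dataset at the truth
noiseless_dataset <- function(params = wt_params()) {
  generate_chase_dataset(params, n_reps = 1, cv = 0, seed = 1)
}

# priors centred on the generating truth (recovery-study configuration)
truth_priors <- function() {
  list(k_degENDO = c(0.0028, 0.00028), k_degLOV = c(0.048, 0.0048))
}

# generic numeric eigenvalue oracle for the slow decay rate
slow_rate_eigen <- function(params, k_hnu) {
  ev <- eigen(chase_matrix(params, k_hnu), only.values = TRUE)$values
  min(abs(ev))
}
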