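# Shared fixtures: the canonical fibroblast anisotropy parameter and the
# cyclic-stretch settings used across experiment replications.

ALPHA_FIX <- 0.794
KS_FIX <- 0.7

hayakawa_params <- function() {
  energy_params(r = 0.4, eps = 0.2, k_s = KS_FIX, alpha = ALPHA_FIX)
}

faust_params <- function(eps = 0.049) {
  energy_params(r = 0.15, eps = eps, k_s = KS_FIX, alpha = ALPHA_FIX)
}

# random stiffness-based parameter sets (k_perp != 1 so alpha exists)
random_stiffness_params <- function(n_sets, seed = 1234) {
  set.seed(seed)
  lapply(seq_len(n_sets), function(k) {
    k_perp <- runif(1, 0.05, 0.95)
    energy_params(r = runif(1, 0, 3), eps = runif(1, 0.02, 0.3),
                  k_s = runif(1, 0.1, 2), k_perp = k_perp)
  })
}
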