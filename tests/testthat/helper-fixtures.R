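# Shared fixtures for the test suite. Everything is built in code; the
# reference membranes below reappear across files.

rel_err <- function(a, b) abs(a - b) / abs(b)

# silicone-like homogeneous membrane (68 um)
sil_mem <- function(K = 1, D = 1e-6) membrane_spec(L = 68e-4, K = K, D = D)

# skin-like bilayer with a rate-limiting stratum corneum
sc_dominant_bl <- function() {
  bilayer_spec(L_sc = 15e-4, L_ved = 485e-4, K_sc = 50, D_sc = 1e-9,
               K_ved = 2, D_ved = 1e-7)
}

# noise-free model-generated timecourse
tc_from_model <- function(mem, donor, times_s, label = "model") {
  permeation_timecourse(times_s, cumulative_amount(mem, donor, times_s),
                        donor, label = label)
}

# random positive bilayer within a few decades, for property sweeps
random_bilayer <- function() {
  bilayer_spec(L_sc = runif(1, 5e-4, 30e-4), L_ved = runif(1, 100e-4, 800e-4),
               K_sc = 10^runif(1, -1, 2), K_ved = 10^runif(1, -1, 1),
               D_sc = 10^runif(1, -10, -8), D_ved = 10^runif(1, -8, -6))
}
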