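# Shared fixtures: canonical states, parameter sets, and norms.

zero_bio_init <- function(aba = 0) {
  c(C_ABA = aba, mRNA = 0, Protein = 0, Complex = 0, I_biolum = 0)
}

# biosensor set with only ABA production/degradation active
prod_deg_only <- function(k_prod, k_deg) {
  biosensor_params(k_prod = k_prod, k_deg = k_deg, kon = 0, koff = 0,
                   k_trans = 0, k_tran_deg = 0, k_tran_syn = 0,
                   k_deg_prot = 0, k_response = 0)
}

# pure first-order decay of free ABA (no expression, no binding via
# empty protein pool, no light)
decay_only <- function(k_deg) {
  biosensor_params(k_deg = k_deg, k_trans = 0, k_response = 0)
}

# sup-norm relative disagreement between two trajectories on a shared grid
rel_sup_err <- function(a, b) {
  max(abs(a$states - b$states)) / max(abs(b$states))
}

worked_biosensor_params <- function() {
  suppressWarnings(biosensor_params(
    k_prod = 0.1, k_deg = 0.05, kon = 0.1, koff = 0.001, k_trans = 0.2,
    k_tran_deg = 0.1, k_tran_syn = 0.3, k_deg_prot = 0.02, K_half = 1,
    n = 1, k_response = 10))
}

worked_biosensor_state <- function() {
  c(C_ABA = 1, mRNA = 0, Protein = 2, Complex = 0.5, I_biolum = 0)
}
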