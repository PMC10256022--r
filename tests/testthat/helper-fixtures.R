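# Shared fixture builders: everything is generated in code at test time.

# small simulated scenario, whitened, with truth attached
make_scenario <- function(N, K, Ns, T = 20L * N * K, seed = 1L,
                          mu_lo = 0.5, mu_hi = 0.8, beta = 0.5) {
  cfg <- sim_config(N, K, Ns, n_samples = T, mu_lo = mu_lo, mu_hi = mu_hi,
                    beta = beta, seed = seed)
  sim <- generate_ground_truth(cfg)
  sim$whitened <- whiten_stack(sim$data, order = N)
  sim
}

# quick optimizer settings used across tests (defaults are for production)
fast_settings <- function(max_iter = 64L, tol = 1e-5, seed = NULL) {
  ivag_settings(max_iter = max_iter, tol = tol, seed = seed)
}

# joint ISI of a demixing set against a scenario's ground truth
scenario_isi <- function(W, sim) {
  joint_isi(mix_demix_products(W, sim$truth, sim$whitened))
}

# literal term-by-term transcription of the normalized ISI formula,
# kept as an independent oracle for the vectorized implementation
isi_oracle <- function(G) {
  N <- nrow(G)
  A <- abs(G)
  total <- 0
  for (n in seq_len(N)) {
    mx <- max(A[n, ])
    acc <- 0
    for (m in seq_len(N)) acc <- acc + A[n, m] / mx
    total <- total + acc - 1
  }
  for (m in seq_len(N)) {
    mx <- max(A[, m])
    acc <- 0
    for (n in seq_len(N)) acc <- acc + A[n, m] / mx
    total <- total + acc - 1
  }
  total / (2 * N * (N - 1))
}
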