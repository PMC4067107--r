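# study-condition shortcuts used across the suite
tmv_truth <- function() c(E1 = 0.032, E2 = 0.0213, eta = 12.4)

# random physically valid series solids for property sweeps
random_series_solids <- function(n, seed = 421) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      zener_series(
        E1 = 10^stats::runif(1, -3, 1),
        E2 = 10^stats::runif(1, -3, 1),
        eta = 10^stats::runif(1, -1, 3),
        v1 = stats::runif(1, 0.05, 0.45),
        v2 = stats::runif(1, 0.05, 0.45)
      )
    })
  })
}

# isotropic plane-stress-like contact stiffness E/(1-v^2) from (G, K):
# independent route used to check the relaxed-limit identity
contact_stiffness_from_gk <- function(G, K) {
  E <- 9 * K * G / (3 * K + G)
  v <- (3 * K - 2 * G) / (2 * (3 * K + G))
  E / (1 - v^2)
}
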