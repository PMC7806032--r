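# Independent oracles used across tests: plain-R state-space simulation and
# Markov parameters computed by direct matrix powers, kept separate from the
# package's Rcpp recursion and fitting code paths.

simulate_ss_r <- function(A, B, C, D, u, x0 = NULL) {
  u <- as.matrix(u)
  n <- nrow(A)
  N <- nrow(u)
  p <- nrow(C)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  y <- matrix(0, N, p)
  for (k in seq_len(N)) {
    y[k, ] <- C %*% x + D %*% u[k, ]
    x <- A %*% x + B %*% u[k, ]
  }
  y
}

markov_direct <- function(A, B, C, D, n_terms = 20) {
  out <- vector("list", n_terms)
  out[[1]] <- D
  Ak <- diag(nrow(A))
  for (k in seq_len(n_terms - 1)) {
    out[[k + 1]] <- C %*% Ak %*% B
    Ak <- Ak %*% A
  }
  out
}

# random stable discrete system with spectral radius in [0.4, 0.9]
make_stable_ss <- function(n, m, p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  rho <- runif(1, 0.4, 0.9)
  A <- A * rho / max(Mod(eigen(A, only.values = TRUE)$values))
  list(A = A, B = matrix(rnorm(n * m), n, m),
       C = matrix(rnorm(p * n), p, n), D = matrix(rnorm(p * m), p, m))
}

# worst-case distance between two eigenvalue multisets
eig_set_error <- function(lam_hat, lam_true) {
  max(vapply(lam_true, function(l) min(Mod(lam_hat - l)), numeric(1)),
      vapply(lam_hat, function(l) min(Mod(lam_true - l)), numeric(1)))
}

max_markov_rel_err <- function(M_hat, M_true) {
  scale <- max(abs(unlist(M_true)))
  max(mapply(function(a, b) max(abs(a - b)), M_hat, M_true)) / scale
}

# short synthetic trial shared by several tests
smoke_recording <- function(n_moves = 60, radius_m = 0.01, neck = "low",
                            seed = 42, noise_sd = 0.05) {
  run_trial(radius_m = radius_m, neck_preset = neck, n_moves = n_moves,
            seed = seed, noise_sd = noise_sd)
}
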