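# Independent brute-force oracles used to cross-check the fast paths.

# Local field as the literal double sum over couplings,
# h_i = sum_{j != i} (1/N) sum_mu xi_i^mu xi_j^mu sigma_j + kappa eta_i
naive_local_field <- function(sigma, xi, i, kappa = 0, eta = NULL) {
  N <- nrow(xi)
  acc <- 0
  for (j in seq_len(N)) {
    if (j == i) next
    acc <- acc + sum(xi[i, ] * xi[j, ]) * sigma[j]
  }
  acc / N + if (is.null(eta)) 0 else kappa * eta[i]
}

# Energy as the literal pair sum
naive_energy <- function(sigma, xi, kappa = 0, eta = NULL) {
  N <- nrow(xi)
  acc <- 0
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      acc <- acc - sum(xi[i, ] * xi[j, ]) * sigma[i] * sigma[j] / N
    }
  }
  if (!is.null(eta)) acc <- acc - kappa * sum(eta * sigma)
  acc
}

# Diluted local field as the literal masked double sum
naive_diluted_field <- function(sigma, xi, mask, d, i, kappa = 0,
                                eta = NULL) {
  N <- nrow(xi)
  acc <- 0
  for (j in seq_len(N)) {
    if (j == i) next
    acc <- acc + mask[i, j] * sum(xi[i, ] * xi[j, ]) * sigma[j]
  }
  acc / (N * (1 - d)) + if (is.null(eta)) 0 else kappa * eta[i]
}

# Zero-temperature condensed-overlap equation solved by a root finder
# independent of the damped fixed-point iteration: for each candidate m,
# r is obtained by direct iteration of r = 1/(1-C)^2 at that fixed m, and
# the residual of the m-equation is handed to uniroot.
# bracket restricted to the stable retrieval root (the middle, unstable
# root of the m-equation lies below ~0.9 at small alpha)
oracle_mrho_T0 <- function(alpha, kappa, lower = 0.9, upper = 1 - 1e-12) {
  erf <- function(x) 2 * pnorm(sqrt(2) * x) - 1
  r_at_m <- function(m) {
    r <- 1
    for (it in 1:20000) {
      C <- sqrt(2 / (pi * alpha * r)) * exp(-(m + kappa)^2 / (2 * alpha * r))
      if (!is.finite(C) || C >= 1) return(NA_real_)
      rn <- 1 / (1 - C)^2
      if (abs(rn - r) < 1e-13) return(rn)
      r <- (r + rn) / 2
    }
    r
  }
  g <- function(m) {
    r <- r_at_m(m)
    if (is.na(r)) return(NA_real_)
    m - erf((m + kappa) / sqrt(2 * alpha * r))
  }
  uniroot(g, c(lower, upper), tol = 1e-12)$root
}
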