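# Replica-symmetric mean-field solvers for the Hebbian network in a
# persistent external field.
#
# Zero-temperature order parameters: condensed overlap m, noise strength r
# (with the auxiliary quantity C, r = 1/(1-C)^2), and the stimulus /
# orthogonal overlaps.  Finite temperature adds the Edwards-Anderson
# parameter q, with the Gaussian integrals evaluated by Gauss-Hermite
# quadrature.

erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

new_mf_solution <- function(m_rho, q, r, C, m_perp, m_stim, u, converged,
                            branch, iterations, residual, params) {
  structure(list(m_rho = m_rho, q = q, r = r, C = C, m_perp = m_perp,
                 m_stim = m_stim, u = u, converged = converged,
                 branch = branch, iterations = iterations,
                 residual = residual, params = params),
            class = "mf_solution")
}

#' @export
print.mf_solution <- function(x, ...) {
  cat(sprintf(
    "<mf_solution> branch = %s (%s)\n  m_rho = %.6g, q = %.6g, r = %.6g, m_perp = %.6g, u = %.6g\n",
    x$branch, if (x$converged) "converged" else "NOT converged",
    x$m_rho, x$q, x$r, x$m_perp, x$u))
  invisible(x)
}

# stationarity right-hand sides at T = 0
mf_rhs_T0 <- function(m, r, alpha, kappa, gamma) {
  s <- sqrt(2 * alpha * r)
  m_new <- gamma * erf((m + kappa) / s) + (1 - gamma) * erf((m - kappa) / s)
  C <- sqrt(2 / (pi * alpha * r)) *
    (gamma * exp(-(m + kappa)^2 / (2 * alpha * r)) +
       (1 - gamma) * exp(-(m - kappa)^2 / (2 * alpha * r)))
  list(m = m_new, C = C)
}

# stimulus-sign overlap <eta sigma> of a condensed T = 0 solution
mf_m_stim_T0 <- function(m, r, alpha, kappa, gamma) {
  s <- sqrt(2 * alpha * r)
  gamma * erf((m + kappa) / s) - (1 - gamma) * erf((m - kappa) / s)
}

#' Solve the zero-temperature saddle-point equations
#'
#' Damped fixed-point iteration of the coupled equations for the condensed
#' overlap `m_rho` and the noise parameter `r = 1/(1 - C)^2` at given load
#' `alpha`, field intensity `kappa`, and stimulus agreement `gamma`. Two
#' canonical initializations discover the branches: `"retrieval"` starts
#' from `(m_rho = 1, r = 1)`; `"zero"` starts from `m_rho = 0` with `r`
#' pre-solved self-consistently at `m_rho = 0`. If the auxiliary quantity
#' `C` reaches 1 during the iteration, `r` diverges and the branch is
#' declared nonexistent (the returned solution is flagged not converged).
#'
#' Branch labels of the converged solution: `"retrieval"` when
#' `m_rho > 0.5`; `"field-aligned"` when `kappa > 0` drags a small but
#' nonzero `m_rho` (for `gamma > 1/2` the stimulus always induces some
#' alignment); `"zero"` otherwise.
#'
#' @param alpha Load p/N (> 0).
#' @param kappa Field intensity (>= 0).
#' @param gamma Stimulus agreement probability in `[1/2, 1]`.
#' @param init `"retrieval"` or `"zero"`.
#' @param tol Residual tolerance (default 1e-10).
#' @param damping Update damping in (0, 1]; the new iterate is
#'   `(1 - damping) * old + damping * rhs`.
#' @param max_iter Iteration cap.
#' @return An `mf_solution` with fields `m_rho`, `q` (1 at T = 0), `r`,
#'   `C`, `m_perp` (orthogonal-stimulus overlap at the same `alpha`,
#'   `kappa`), `m_stim` (overlap with the correlated stimulus), `u`
#'   (internal energy per neuron), `converged`, `branch`, `iterations`,
#'   `residual`.
#' @examples
#' mf_solve_T0(0.05, 0, 1, init = "retrieval")$m_rho  # deep retrieval
#' @export
mf_solve_T0 <- function(alpha, kappa, gamma = 1,
                        init = c("retrieval", "zero"),
                        tol = 1e-10, damping = 0.5, max_iter = 1e5) {
  if (alpha <= 0) stop("`alpha` must be positive")
  if (kappa < 0) stop("`kappa` must be non-negative")
  if (gamma < 0.5 || gamma > 1) stop("`gamma` must be in [1/2, 1]")
  init <- match.arg(init)
  params <- list(alpha = alpha, kappa = kappa, gamma = gamma, beta = Inf)

  if (init == "retrieval") {
    m <- 1; r <- 1
  } else {
    m <- 0
    r <- mf_solve_r0(alpha, kappa)
    if (is.na(r)) r <- 1
  }

  converged <- FALSE
  exists <- TRUE
  iter <- 0L
  res <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    rhs <- mf_rhs_T0(m, r, alpha, kappa, gamma)
    if (!is.finite(rhs$C) || rhs$C >= 1) { exists <- FALSE; break }
    r_new <- 1 / (1 - rhs$C)^2
    res <- max(abs(rhs$m - m), abs(r_new - r))
    m <- (1 - damping) * m + damping * rhs$m
    r <- (1 - damping) * r + damping * r_new
    if (res < tol) { converged <- TRUE; break }
  }
  if (!exists) {
    return(new_mf_solution(NA_real_, 1, NA_real_, NA_real_, NA_real_,
                           NA_real_, NA_real_, FALSE, "nonexistent",
                           iter, res, params))
  }
  rhs <- mf_rhs_T0(m, r, alpha, kappa, gamma)
  m_stim <- mf_m_stim_T0(m, r, alpha, kappa, gamma)
  orth <- mf_solve_orthogonal_T0(alpha, kappa, tol = tol)
  branch <- if (abs(m) > 0.5) "retrieval"
  else if (kappa > 0 && abs(m) > 1e-8) "field-aligned"
  else "zero"
  u <- 0.5 * alpha * (1 - r) - 0.5 * m^2 - kappa * m_stim
  new_mf_solution(m, 1, r, rhs$C, orth$m_perp, m_stim, u, converged,
                  branch, iter, res, params)
}

# r at m = 0 (the C-form there is gamma-independent).  In terms of
# x = sqrt(r) >= 1 the fixed point r = 1/(1-C)^2 reads
# x - sqrt(2/(pi alpha)) exp(-kappa^2/(2 alpha x^2)) - 1 = 0, which always
# has a root (the left side is negative at x = 1 and grows like x).
mf_solve_r0 <- function(alpha, kappa, tol = 1e-14) {
  c0 <- sqrt(2 / (pi * alpha))
  f <- function(x) x - c0 * exp(-kappa^2 / (2 * alpha * x^2)) - 1
  upper <- 2 + c0
  while (f(upper) < 0) upper <- upper * 2
  x <- stats::uniroot(f, c(1, upper), tol = tol)$root
  x^2
}

#' Zero-temperature solution under an orthogonal stimulus
#'
#' With a stimulus orthogonal to every stored memory there is no condensed
#' pattern (`m_rho = 0` exactly); the noise parameter solves
#' `r = 1/(1 - C)^2` with `C` evaluated at `m_rho = 0`, and the stimulus
#' overlap is `m_perp = erf(kappa / sqrt(2 alpha r))`.
#'
#' @inheritParams mf_solve_T0
#' @return An `mf_solution` with `branch = "orthogonal"`.
#' @export
mf_solve_orthogonal_T0 <- function(alpha, kappa, tol = 1e-10) {
  if (alpha <= 0) stop("`alpha` must be positive")
  if (kappa < 0) stop("`kappa` must be non-negative")
  r <- mf_solve_r0(alpha, kappa, tol = min(tol, 1e-12))
  params <- list(alpha = alpha, kappa = kappa, gamma = 0.5, beta = Inf)
  if (is.na(r)) {
    return(new_mf_solution(0, 1, NA_real_, NA_real_, NA_real_, NA_real_,
                           NA_real_, FALSE, "nonexistent", NA_integer_,
                           Inf, params))
  }
  C <- 1 - 1 / sqrt(r)
  mp <- mf_m_perp_T0(kappa, alpha, r)
  u <- 0.5 * alpha * (1 - r) - kappa * mp
  new_mf_solution(0, 1, r, C, mp, mp, u, TRUE, "orthogonal", NA_integer_,
                  0, params)
}

#' Orthogonal-stimulus overlap at zero temperature
#'
#' `m_perp = erf(kappa / sqrt(2 alpha r))`, with `r` taken from a
#' converged orthogonal-stimulus solve at the same `alpha` and `kappa`.
#'
#' @param kappa Field intensity.
#' @param alpha Load.
#' @param r Noise parameter of the orthogonal branch.
#' @return Numeric scalar in `[0, 1]` for `kappa >= 0`.
#' @export
mf_m_perp_T0 <- function(kappa, alpha, r) {
  erf(kappa / sqrt(2 * alpha * r))
}

#' Internal energy per neuron at zero temperature
#'
#' `u = alpha (1 - r) / 2 - m_rho^2 / 2 - kappa * m_stim`, where `m_stim`
#' is the overlap between the configuration and the applied stimulus signs
#' (equal to `m_rho` for a perfectly correlated stimulus, and to `m_perp`
#' on the orthogonal branch). Used to select between coexisting branches.
#'
#' @param sol A converged `mf_solution` at T = 0.
#' @return Numeric scalar.
#' @export
internal_energy_T0 <- function(sol) {
  stopifnot(inherits(sol, "mf_solution"))
  0.5 * sol$params$alpha * (1 - sol$r) - 0.5 * sol$m_rho^2 -
    sol$params$kappa * sol$m_stim
}

#' Maxwell branch selection
#'
#' Among converged solutions at the same control parameters, returns the
#' one with the lowest internal energy; ties break toward the larger
#' condensed overlap. The full candidate list is attached as attribute
#' `"candidates"`.
#'
#' @param solutions List of `mf_solution` objects.
#' @return The selected `mf_solution`.
#' @export
maxwell_select <- function(solutions) {
  if (inherits(solutions, "mf_solution")) solutions <- list(solutions)
  ok <- Filter(function(s) isTRUE(s$converged), solutions)
  if (length(ok) == 0) stop("no converged solution to select from")
  u <- vapply(ok, `[[`, numeric(1), "u")
  m <- vapply(ok, `[[`, numeric(1), "m_rho")
  sel <- ok[[order(u, -m)[1]]]
  attr(sel, "candidates") <- ok
  sel
}

# Quadrature engine for the finite-temperature Gaussian averages.
#
# For one field shift b it returns
#   M(b) = Int Dz tanh(beta (a z + b))
#   K(b) = beta Int Dz sech^2(beta (a z + b))       [K = beta (1 - q)]
# When a*beta is small the integrands are smooth on the scale of the
# Gauss-Hermite nodes and plain quadrature is accurate.  At low
# temperature, however, the tanh kink and the sech^2 spike have width
# 1/(a beta) in z and fall between nodes, so the boundary layer is
# resolved explicitly by substituting u = beta (a z + b):
#   M(b) = erf(b/(sqrt(2) a))
#          + (1/(a beta)) Int du [tanh u - sign u] phi((u/beta - b)/a)
#   K(b) = (1/a) Int du sech^2(u) phi((u/beta - b)/a)
# with the u integrals on a fixed Gauss-Legendre rule (both kernels decay
# like exp(-2|u|)).  The crossover at a*beta = 2 keeps both regimes well
# inside their resolution limits; in the beta -> Inf limit K(b) reduces
# to the zero-temperature expression sqrt(2/(pi a^2)) exp(-b^2/(2 a^2)).
mf_quad_rules <- function(gh_order) {
  gh <- pracma::gaussHermite(gh_order)
  gl <- pracma::gaussLegendre(400, -25, 25)
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi), u = gl$x, wu = gl$w)
}

mf_branch_MK <- function(a, b, beta, qr) {
  if (a * beta <= 2) {
    arg <- beta * (a * qr$z + b)
    t <- tanh(arg)
    M <- sum(qr$w * t)
    K <- beta * sum(qr$w * (1 - t^2))
  } else {
    phi <- stats::dnorm((qr$u / beta - b) / a)
    M <- erf(b / (sqrt(2) * a)) +
      sum(qr$wu * (tanh(qr$u) - sign(qr$u)) * phi) / (a * beta)
    K <- sum(qr$wu * phi / cosh(qr$u)^2) / a
  }
  c(M = M, K = K)
}

#' Solve the finite-temperature saddle-point equations
#'
#' Damped fixed-point iteration of the coupled equations for the
#' condensed overlap `m_rho`, the Edwards-Anderson parameter `q`, and the
#' noise strength `r = q / (1 - beta (1 - q))^2` at inverse temperature
#' `beta`. The Gaussian averages are evaluated by Gauss-Hermite
#' quadrature, with the thermal boundary layer (width `1/beta`, which
#' falls between quadrature nodes at low temperature) integrated on a
#' dedicated rule; the stimulus-sign average uses the weights
#' `(gamma, 1 - gamma)`. As `beta` grows the solution approaches the
#' zero-temperature one of [mf_solve_T0()].
#'
#' @inheritParams mf_solve_T0
#' @param beta Inverse temperature (> 0, finite).
#' @param gh_order Gauss-Hermite order (default 101; doubling it changes
#'   a converged solution by less than 1e-9).
#' @return An `mf_solution`; `u` is reported only at T = 0 and is `NA`
#'   here.
#' @export
mf_solve_finiteT <- function(alpha, kappa, gamma = 1, beta,
                             init = c("retrieval", "zero"),
                             tol = 1e-10, damping = 0.5, max_iter = 1e5,
                             gh_order = 101) {
  if (alpha <= 0) stop("`alpha` must be positive")
  if (kappa < 0) stop("`kappa` must be non-negative")
  if (gamma < 0.5 || gamma > 1) stop("`gamma` must be in [1/2, 1]")
  if (!is.finite(beta) || beta <= 0)
    stop("`beta` must be positive and finite (use mf_solve_T0 for T = 0)")
  init <- match.arg(init)
  qr <- mf_quad_rules(gh_order)
  params <- list(alpha = alpha, kappa = kappa, gamma = gamma, beta = beta)

  both <- function(m, r) {
    a <- sqrt(alpha * r)
    p1 <- mf_branch_MK(a, m + kappa, beta, qr)
    p2 <- if (gamma < 1) mf_branch_MK(a, m - kappa, beta, qr) else c(0, 0)
    list(m = gamma * p1[1] + (1 - gamma) * p2[1],
         K = gamma * p1[2] + (1 - gamma) * p2[2],
         m_stim = gamma * p1[1] - (1 - gamma) * p2[1])
  }

  m <- if (init == "retrieval") 1 else 0
  q <- 0.5
  r <- 1

  converged <- FALSE
  exists <- TRUE
  iter <- 0L
  res <- Inf
  out <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    out <- both(m, r)
    K <- out$K
    if (!is.finite(K)) { exists <- FALSE; break }
    q_new <- min(max(1 - K / beta, 0), 1)
    if (abs(1 - K) < 1e-14) { exists <- FALSE; break }
    r_new <- min(q_new / (1 - K)^2, 1e8)   # cap transient blow-ups
    res <- max(abs(out$m - m), abs(q_new - q), abs(r_new - r))
    m <- (1 - damping) * m + damping * out$m
    q <- (1 - damping) * q + damping * q_new
    r <- (1 - damping) * r + damping * r_new
    if (res < tol) { converged <- TRUE; break }
  }
  if (!exists) {
    return(new_mf_solution(NA_real_, NA_real_, NA_real_, NA_real_,
                           NA_real_, NA_real_, NA_real_, FALSE,
                           "nonexistent", iter, res, params))
  }
  mp <- mf_m_perp_finiteT(alpha, kappa, beta, tol, damping, max_iter, qr)
  branch <- if (abs(m) > 0.5) "retrieval"
  else if (kappa > 0 && abs(m) > 1e-8) "field-aligned"
  else "zero"
  new_mf_solution(m, q, r, NA_real_, mp, out$m_stim, NA_real_, converged,
                  branch, iter, res, params)
}

# orthogonal stimulus at finite T: no condensed pattern, the eta average
# symmetrizes to a single branch at shift kappa
mf_m_perp_finiteT <- function(alpha, kappa, beta, tol, damping, max_iter,
                              qr) {
  q <- 0.5
  r <- 1
  M <- NA_real_
  for (iter in seq_len(max_iter)) {
    a <- sqrt(alpha * r)
    mk <- mf_branch_MK(a, kappa, beta, qr)
    M <- mk[1]
    q_new <- min(max(1 - mk[2] / beta, 0), 1)
    if (abs(1 - mk[2]) < 1e-14) break
    r_new <- min(q_new / (1 - mk[2])^2, 1e8)
    if (max(abs(q_new - q), abs(r_new - r)) < tol) break
    q <- (1 - damping) * q + damping * q_new
    r <- (1 - damping) * r + damping * r_new
  }
  M
}

#' Critical storage capacity
#'
#' Bisects on the load `alpha` for the largest value at which the
#' zero-temperature retrieval branch still exists (converged solution with
#' `m_rho > 0.5` from the retrieval initialization). At `kappa = 0`,
#' `gamma = 1` this reproduces the classic capacity of the Hebbian
#' network, 0.14 to two decimals.
#'
#' @param kappa Field intensity (default 0).
#' @param gamma Stimulus agreement (default 1).
#' @param lower,upper Bisection bracket on alpha.
#' @param tol Bisection tolerance on alpha (default 1e-3).
#' @return The capacity estimate (numeric scalar).
#' @examples
#' round(critical_capacity(), 2)  # 0.14
#' @export
critical_capacity <- function(kappa = 0, gamma = 1, lower = 0.01,
                              upper = 1, tol = 1e-3) {
  has_retrieval <- function(alpha) {
    s <- mf_solve_T0(alpha, kappa, gamma, init = "retrieval")
    isTRUE(s$converged) && !is.na(s$m_rho) && s$m_rho > 0.5
  }
  if (!has_retrieval(lower))
    stop("no retrieval branch at `lower`; widen the bracket")
  while (has_retrieval(upper)) upper <- upper * 2
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has_retrieval(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Analytic estimate of the calibrated field intensity
#'
#' The crosstalk noise on a neuron aligned with the stimulated memory has
#' variance `alpha / (1 - d)` (with `d` the fraction of removed directed
#' synapses; `d = 0` is the undiluted network), so the field intensity
#' that cancels it is its width, `kappa_c = sqrt(alpha / (1 - d))`. The
#' simulated `kappa_c` sits below this estimate, by about 10% undiluted
#' and slightly more than 20% at strong dilution.
#'
#' @param alpha Load.
#' @param d Dilution fraction in `[0, 1)`.
#' @return `sqrt(alpha / (1 - d))`.
#' @export
kc_theory <- function(alpha, d = 0) {
  if (any(d < 0 | d >= 1)) stop("`d` must be in [0, 1)")
  sqrt(alpha / (1 - d))
}
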