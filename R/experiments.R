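# Experiment drivers: kappa scans with disorder averaging, empirical noise
# calibration, time-switched stimuli, and theory/simulation comparisons.

# master seed -> independent per-realization seeds (32-bit safe)
spawn_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Scan the stimulus intensity and locate kappa_c
#'
#' For each `kappa` on the grid and each disorder realization, two
#' independent relaxations are run from random initial configurations:
#' one under a stimulus correlated (agreement `gamma`) with stored pattern
#' 1 (the condensed pattern), measuring its overlap `m_rho` (and the
#' overlaps of any correlated companion patterns), and one under a
#' stimulus orthogonal to every stored memory, measuring `m_perp`. The
#' overlap gap `Delta m(kappa) = |mean(m_rho) - mean(m_perp)|` is computed
#' from the ensemble means, and the calibrated intensity `kappa_c` is the
#' grid point maximizing it (smallest such point on an exact tie).
#'
#' Within a realization the pattern set, the two stimulus sign vectors and
#' the dilution mask (if any) are drawn once and shared across the kappa
#' grid; initial configurations are redrawn per run.
#'
#' @param N Number of neurons.
#' @param alpha Load; `p = round(alpha * N)` patterns are stored.
#' @param gamma Stimulus agreement probability in `[1/2, 1]`.
#' @param kappa_grid Strictly increasing vector of field intensities.
#' @param realizations Number of disorder realizations per grid point.
#' @param sweeps Sweep budget per relaxation.
#' @param seed Master seed; spawns one reproducible stream per
#'   realization.
#' @param correlation_spec Optional numeric vector of agreement fractions
#'   `b`; each adds one stored pattern correlated with pattern 1, whose
#'   overlap is also measured.
#' @param d Optional dilution fraction in `[0, 1)`; when supplied the
#'   couplings are asymmetrically diluted.
#' @param order,tie Update-order and tie-break policies, as in
#'   [run_dynamics()].
#' @return A tibble of class `kappa_scan` with one row per grid point:
#'   `kappa`, `m_rho`, `m_rho_se`, `m_perp`, `m_perp_se`, `delta_m`, and
#'   one `m_theta<k>`/`m_theta<k>_se` pair per correlated companion.
#'   Attributes: `kappa_c`, `max_delta_m`, `config`.
#' @examples
#' \donttest{
#' sc <- kappa_scan(N = 500, alpha = 1, gamma = 1,
#'                  kappa_grid = seq(0.5, 1.5, 0.25),
#'                  realizations = 5, seed = 1)
#' attr(sc, "kappa_c")
#' }
#' @export
kappa_scan <- function(N = 2000, alpha = 1, gamma = 1,
                       kappa_grid = seq(0, 2, by = 0.05),
                       realizations = 20, sweeps = 100, seed = NULL,
                       correlation_spec = NULL, d = NULL,
                       order = "cyclic", tie = "keep") {
  if (any(diff(kappa_grid) <= 0))
    stop("`kappa_grid` must be strictly increasing")
  if (realizations < 1) stop("`realizations` must be >= 1")
  if (gamma < 0.5 || gamma > 1) stop("`gamma` must be in [1/2, 1]")
  if (!is.null(d) && (d < 0 || d >= 1)) stop("`d` must be in [0, 1)")
  p <- round(alpha * N)
  if (p < 1) stop("`alpha * N` must round to at least one pattern")
  ncorr <- length(correlation_spec)
  nk <- length(kappa_grid)
  seeds <- spawn_seeds(seed, realizations)

  m_rho <- matrix(NA_real_, realizations, nk)
  m_orth <- matrix(NA_real_, realizations, nk)
  m_theta <- if (ncorr > 0)
    array(NA_real_, c(realizations, nk, ncorr)) else NULL

  for (rr in seq_len(realizations)) {
    set.seed(seeds[rr])
    ps <- generate_patterns(N, p, correlation_spec = correlation_spec)
    eta_rho <- make_stimulus(ps$xi[, 1], gamma, kappa = 0, target_index = 1L)
    eta_orth <- make_orthogonal_stimulus(ps, kappa = 0)
    coupl <- if (is.null(d)) couplings() else
      couplings("hebb-diluted", d = d, mask = dilution_mask(N, d))
    for (ik in seq_len(nk)) {
      kap <- kappa_grid[ik]
      st1 <- random_state(ps)
      r1 <- run_dynamics(st1, ps, coupl,
                         new_stimulus(eta_rho$eta, kap, gamma, 1L),
                         sweeps = sweeps, order = order, tie = tie,
                         watch = integer(0))
      m_rho[rr, ik] <- r1$state$m[1]
      if (ncorr > 0)
        m_theta[rr, ik, ] <- r1$state$m[1 + seq_len(ncorr)]
      st2 <- random_state(ps)
      r2 <- run_dynamics(st2, ps, coupl,
                         new_stimulus(eta_orth$eta, kap, 0.5, "orthogonal"),
                         sweeps = sweeps, order = order, tie = tie,
                         watch = integer(0))
      m_orth[rr, ik] <- m_perp(r2$state, eta_orth)
    }
  }

  se <- function(x) stats::sd(x) / sqrt(length(x))
  mr_mean <- colMeans(m_rho); mr_se <- apply(m_rho, 2, se)
  mo_mean <- colMeans(m_orth); mo_se <- apply(m_orth, 2, se)
  out <- tibble::tibble(kappa = kappa_grid, m_rho = mr_mean,
                        m_rho_se = mr_se, m_perp = mo_mean,
                        m_perp_se = mo_se)
  out$delta_m <- delta_m(out$m_rho, out$m_perp)
  if (ncorr > 0) {
    for (k in seq_len(ncorr)) {
      mt <- matrix(m_theta[, , k], realizations, nk)
      out[[paste0("m_theta", k)]] <- colMeans(mt)
      out[[paste0("m_theta", k, "_se")]] <- apply(mt, 2, se)
    }
  }
  imax <- which.max(out$delta_m)  # first index on a flat plateau
  config <- list(N = N, alpha = alpha, p = p, gamma = gamma,
                 kappa_grid = kappa_grid, realizations = realizations,
                 sweeps = sweeps, seed = seed,
                 correlation_spec = correlation_spec, d = d,
                 order = order, tie = tie)
  structure(out,
            class = c("kappa_scan", class(out)),
            kappa_c = kappa_grid[imax],
            max_delta_m = out$delta_m[imax],
            config = config)
}

#' Kappa scan with correlated companion patterns
#'
#' Thin wrapper around [kappa_scan()] requiring a `correlation_spec`; the
#' companion overlaps `m_theta` saturate at `2b - 1` for large `kappa`.
#'
#' @inheritParams kappa_scan
#' @return A `kappa_scan` tibble (see [kappa_scan()]).
#' @export
correlated_scan <- function(N = 2000, alpha = 1, gamma = 1,
                            kappa_grid = seq(0, 1.5, by = 0.05),
                            realizations = 20, sweeps = 100, seed = NULL,
                            correlation_spec = 0.8, ...) {
  if (length(correlation_spec) < 1)
    stop("`correlation_spec` must list at least one b value")
  kappa_scan(N = N, alpha = alpha, gamma = gamma, kappa_grid = kappa_grid,
             realizations = realizations, sweeps = sweeps, seed = seed,
             correlation_spec = correlation_spec, ...)
}

#' Kappa scan with asymmetrically diluted couplings
#'
#' Thin wrapper around [kappa_scan()] with a dilution fraction `d`; the
#' calibrated intensity grows with dilution roughly as
#' `sqrt(alpha / (1 - d))` (see [kc_theory()]).
#'
#' @inheritParams kappa_scan
#' @return A `kappa_scan` tibble.
#' @export
dilution_scan <- function(N = 1000, alpha = 0.5, gamma = 1,
                          kappa_grid = seq(0, 2, by = 0.1),
                          realizations = 10, sweeps = 100, seed = NULL,
                          d = 0.5, ...) {
  kappa_scan(N = N, alpha = alpha, gamma = gamma, kappa_grid = kappa_grid,
             realizations = realizations, sweeps = sweeps, seed = seed,
             d = d, ...)
}

#' Empirical crosstalk-noise statistics
#'
#' Sets the configuration and the stimulus equal to stored pattern 1 and
#' evaluates, at every site, the crosstalk field contributed by the other
#' `p - 1` memories (through the masked, renormalized couplings when
#' `d > 0`). Across sites and realizations this noise has mean ~ 0 and
#' variance ~ `alpha / (1 - d)`, the calibration underlying
#' [kc_theory()].
#'
#' @param N Number of neurons.
#' @param p Number of stored patterns (>= 2).
#' @param realizations Disorder realizations to pool.
#' @param seed Master seed.
#' @param d Dilution fraction in `[0, 1)` (default 0: full couplings).
#' @return One-row tibble: `mean`, `variance`, `n` (pooled sample size),
#'   `N`, `p`, `alpha`, `d`.
#' @export
noise_variance_empirical <- function(N, p, realizations = 5, seed = NULL,
                                     d = 0) {
  if (p < 2) stop("`p` must be at least 2")
  if (d < 0 || d >= 1) stop("`d` must be in [0, 1)")
  seeds <- spawn_seeds(seed, realizations)
  noise <- numeric(0)
  for (rr in seq_len(realizations)) {
    set.seed(seeds[rr])
    xi <- matrix(sample(c(-1L, 1L), N * p, replace = TRUE), N, p)
    if (d == 0) {
      # noise_i = (1/N) [ sum_{mu>1} xi_i^mu s_mu - (p-1) xi_i^1 ],
      # s_mu = sum_j xi_j^mu xi_j^1  (self term j = i removed exactly)
      s <- as.vector(crossprod(xi, xi[, 1]))
      h <- (as.vector(xi[, -1, drop = FALSE] %*% s[-1]) -
              (p - 1) * xi[, 1]) / N
    } else {
      mask <- dilution_mask(N, d)
      A <- xi * xi[, 1]                  # A_{j mu} = xi_j^mu xi_j^1
      M <- mask %*% A                    # row i: sum_j C_ij A_{j mu}
      h <- rowSums(xi[, -1, drop = FALSE] * M[, -1, drop = FALSE]) /
        (N * (1 - d))
    }
    noise <- c(noise, h)
  }
  tibble::tibble(mean = mean(noise), variance = stats::var(noise),
                 n = length(noise), N = N, p = p, alpha = p / N, d = d)
}

#' Time course under a switching stimulus
#'
#' Runs the three-phase protocol: no stimulus until `t0`, then a stimulus
#' with agreement `gamma1` on stored pattern 1 (rho) until `t1`, then a
#' stimulus with agreement `gamma2` on stored pattern 2 (nu). Overlaps
#' with both patterns are recorded every sweep. Times are in single-neuron
#' updates; defaults mirror the reference protocol proportionally
#' (stimulus onset after 5 sweeps, switch after 10, horizon 15).
#'
#' @param N Number of neurons.
#' @param alpha Load.
#' @param kappa Field intensity applied from `t0` on.
#' @param t0,t1 Stimulus onset and switch times (single-neuron updates),
#'   `0 < t0 < t1`.
#' @param gamma1,gamma2 Agreement probabilities of the two stimuli.
#' @param seed Seed for the disorder and initial state.
#' @param sweeps Total sweep budget (series length).
#' @return A tibble of class `time_course`: `sweep`, `t`, `m_rho`, `m_nu`,
#'   `flips`; attribute `config`.
#' @export
time_course <- function(N = 2000, alpha = 0.8, kappa = 0.9, t0 = 5 * N,
                        t1 = 10 * N, gamma1 = 0.8, gamma2 = 1.0,
                        seed = NULL, sweeps = 15) {
  if (!(t0 > 0 && t1 > t0)) stop("need 0 < t0 < t1")
  if (t1 >= sweeps * N)
    stop("`t1` must fall inside the sweep budget")
  if (!is.null(seed)) set.seed(seed)
  p <- round(alpha * N)
  if (p < 2) stop("need at least two stored patterns")
  ps <- generate_patterns(N, p)
  sch <- stimulus_schedule(
    list(null_stimulus(N),
         make_stimulus(ps$xi[, 1], gamma1, kappa, target_index = 1L),
         make_stimulus(ps$xi[, 2], gamma2, kappa, target_index = 2L)),
    t_start = c(0, t0, t1))
  st <- random_state(ps)
  run <- run_dynamics(st, ps, couplings(), sch, sweeps = sweeps,
                      watch = c(1L, 2L), early_stop = FALSE)
  out <- tibble::tibble(sweep = run$trajectory$sweep,
                        t = run$trajectory$t,
                        m_rho = run$trajectory$m1,
                        m_nu = run$trajectory$m2,
                        flips = run$trajectory$flips)
  structure(out, class = c("time_course", class(out)),
            config = list(N = N, alpha = alpha, kappa = kappa, t0 = t0,
                          t1 = t1, gamma1 = gamma1, gamma2 = gamma2,
                          seed = seed, sweeps = sweeps))
}

#' Compare mean-field theory with simulation along a kappa grid
#'
#' Runs a simulation scan and, at each grid point, solves the
#' zero-temperature saddle-point equations (retrieval and zero
#' initializations, Maxwell-selected) for the condensed overlap and the
#' orthogonal branch for `m_perp`. Reports both sets of overlaps and
#' their maximum absolute discrepancy, which shrinks as `N` grows and
#' vanishes in the strong-field limit.
#'
#' @inheritParams kappa_scan
#' @return A tibble of class `theory_vs_sim`: `kappa`, `m_rho_sim`,
#'   `m_perp_sim`, `m_rho_theory`, `m_perp_theory`, `delta_m_sim`,
#'   `delta_m_theory`; attribute `max_discrepancy`.
#' @export
theory_vs_simulation <- function(alpha = 1, gamma = 1,
                                 kappa_grid = seq(0.5, 1.5, by = 0.1),
                                 N = 2000, realizations = 10,
                                 seed = NULL, sweeps = 100) {
  sim <- kappa_scan(N = N, alpha = alpha, gamma = gamma,
                    kappa_grid = kappa_grid, realizations = realizations,
                    sweeps = sweeps, seed = seed)
  th <- purrr::map_dfr(kappa_grid, function(kap) {
    sols <- list(mf_solve_T0(alpha, kap, gamma, init = "retrieval"),
                 mf_solve_T0(alpha, kap, gamma, init = "zero"))
    sols <- Filter(function(s) isTRUE(s$converged), sols)
    mr <- if (length(sols) > 0) maxwell_select(sols)$m_rho else NA_real_
    orth <- mf_solve_orthogonal_T0(alpha, kap)
    tibble::tibble(kappa = kap, m_rho_theory = mr,
                   m_perp_theory = orth$m_perp)
  })
  out <- dplyr::left_join(
    dplyr::select(tibble::as_tibble(sim), "kappa",
                  m_rho_sim = "m_rho", m_perp_sim = "m_perp"),
    th, by = "kappa")
  out$delta_m_sim <- delta_m(out$m_rho_sim, out$m_perp_sim)
  out$delta_m_theory <- delta_m(out$m_rho_theory, out$m_perp_theory)
  disc <- max(abs(out$m_rho_sim - out$m_rho_theory),
              abs(out$m_perp_sim - out$m_perp_theory), na.rm = TRUE)
  structure(out, class = c("theory_vs_sim", class(out)),
            max_discrepancy = disc)
}
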