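#' Coupling configuration
#'
#' Full Hebbian couplings `J_ij = (1/N) sum_mu xi_i^mu xi_j^mu` (i != j,
#' symmetric), or their asymmetrically diluted form
#' `J_ij = C_ij / (N (1 - d)) sum_mu xi_i^mu xi_j^mu`, where the binary
#' mask entries `C_ij` are drawn independently of `C_ji`, so dilution
#' destroys the coupling symmetry and with it the energy function.
#'
#' @param mode `"hebb-full"` or `"hebb-diluted"`.
#' @param d Dilution fraction in `[0, 1)` (diluted mode).
#' @param mask N x N binary matrix from [dilution_mask()] (diluted mode).
#' @return A `coupling_config` object.
#' @export
couplings <- function(mode = c("hebb-full", "hebb-diluted"), d = 0,
                      mask = NULL) {
  mode <- match.arg(mode)
  if (mode == "hebb-diluted") {
    if (is.null(mask)) stop("diluted mode requires a `mask`")
    if (d < 0 || d >= 1) stop("`d` must be in [0, 1)")
    if (any(diag(mask) != 0)) stop("mask diagonal must be zero")
  } else {
    d <- 0; mask <- NULL
  }
  structure(list(mode = mode, d = d, mask = mask),
            class = "coupling_config")
}

#' Asymmetric dilution mask
#'
#' Off-diagonal entries are i.i.d. Bernoulli(1 - d) indicators of synapse
#' survival; `C_ij` and `C_ji` are drawn independently, so a fraction of
#' about `2 d (1 - d)` of neuron pairs is connected in one direction only.
#' The diagonal is zero.
#'
#' @param N Number of neurons.
#' @param d Fraction of removed directed synapses, in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return N x N integer 0/1 matrix with zero diagonal.
#' @export
dilution_mask <- function(N, d, seed = NULL) {
  if (length(d) != 1L || !is.finite(d) || d < 0 || d >= 1)
    stop("`d` must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  C <- matrix(rbinom(N * N, 1L, 1 - d), N, N)
  diag(C) <- 0L
  storage.mode(C) <- "integer"
  C
}

#' Network state
#'
#' Bundles the neuron configuration with its elapsed update count and the
#' cached overlap vector `m_mu = (1/N) sum_i xi_i^mu sigma_i`, kept exactly
#' consistent with `sigma` by all update operations.
#'
#' @param sigma Sign vector of length N.
#' @param patterns A `pattern_set`.
#' @param t Elapsed single-neuron updates.
#' @return A `network_state` object with fields `sigma`, `t`, `m`.
#' @export
network_state <- function(sigma, patterns, t = 0) {
  stopifnot(inherits(patterns, "pattern_set"))
  sigma <- as.integer(sigma)
  if (length(sigma) != patterns$N) stop("length(sigma) != N")
  if (!all(abs(sigma) == 1L)) stop("sigma entries must be +1 or -1")
  structure(list(sigma = sigma, t = t,
                 m = as.vector(crossprod(patterns$xi, sigma)) / patterns$N),
            class = "network_state")
}

#' Random initial network state
#'
#' @param patterns A `pattern_set`.
#' @param seed Optional integer seed.
#' @return A `network_state` with i.i.d. +1/-1 neurons.
#' @export
random_state <- function(patterns, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  network_state(sample(c(-1L, 1L), patterns$N, replace = TRUE), patterns)
}

#' @export
print.network_state <- function(x, ...) {
  cat("<network_state> N =", length(x$sigma), ", t =", x$t, "\n")
  invisible(x)
}

#' Local field on one neuron
#'
#' The post-synaptic field `h_i = sum_{j != i} J_ij sigma_j + kappa eta_i`.
#' In full Hebbian mode it is evaluated through the cached overlaps,
#' `h_i = sum_mu xi_i^mu m_mu - p sigma_i / N + kappa eta_i`, which equals
#' the self-term-excluded double sum exactly; in diluted mode the masked
#' sum is evaluated directly.
#'
#' @param state A `network_state`.
#' @param patterns A `pattern_set`.
#' @param coupl A `coupling_config` (default full Hebbian).
#' @param stimulus A `stimulus` (or `NULL` for no field).
#' @param i Neuron index.
#' @return The field value (numeric scalar).
#' @export
local_field <- function(state, patterns, coupl = couplings(),
                        stimulus = NULL, i = 1L) {
  if (i < 1 || i > patterns$N) stop("neuron index out of range")
  ext <- if (is.null(stimulus)) 0 else stimulus$kappa * stimulus$eta[i]
  if (coupl$mode == "hebb-full") {
    Nm <- round(state$m * patterns$N)        # exact integer overlaps
    (sum(patterns$xi[i, ] * Nm) - patterns$p * state$sigma[i]) /
      patterns$N + ext
  } else {
    ai <- as.vector(patterns$xi %*% patterns$xi[i, ])  # sum_mu xi_i xi_j
    sum(coupl$mask[i, ] * ai * state$sigma) /
      (patterns$N * (1 - coupl$d)) + ext
  }
}

#' Single sequential zero-temperature update
#'
#' Sets `sigma_i <- sign(h_i)`; an exactly zero field leaves the neuron
#' unchanged under the default tie rule (`"keep"`), or sets it to +1 under
#' `"plus"`. The overlap cache is updated incrementally and the update
#' counter advances by one.
#'
#' @inheritParams local_field
#' @param tie `"keep"` (default) or `"plus"`.
#' @return The updated `network_state`.
#' @export
update_neuron <- function(state, patterns, coupl = couplings(),
                          stimulus = NULL, i = 1L, tie = c("keep", "plus")) {
  tie <- match.arg(tie)
  h <- local_field(state, patterns, coupl, stimulus, i)
  new <- if (h > 0) 1L else if (h < 0) -1L else
    if (tie == "keep") state$sigma[i] else 1L
  if (new != state$sigma[i]) {
    state$m <- state$m + 2 * new * patterns$xi[i, ] / patterns$N
    state$sigma[i] <- new
  }
  state$t <- state$t + 1
  state
}

#' Run zero-temperature sequential dynamics
#'
#' Performs `sweeps` passes of N single-neuron updates each, querying the
#' stimulus schedule at every update time. Neurons are visited in fixed
#' cyclic order `1..N` by default, or in a fresh random permutation each
#' sweep. With symmetric (full Hebbian) couplings and a constant stimulus
#' this dynamics never increases the energy, so it terminates at a
#' single-flip-stable state; a sweep with zero flips is then a fixed point
#' and, when `early_stop = TRUE` and the schedule has reached its final
#' segment, the run stops there. In diluted (asymmetric) mode no fixed
#' point is guaranteed and the budget is normally exhausted.
#'
#' @param state Initial `network_state`.
#' @param patterns A `pattern_set`.
#' @param coupl A `coupling_config`.
#' @param schedule A `stimulus` or `stimulus_schedule`.
#' @param sweeps Sweep budget (each sweep = N updates); default 100,
#'   matching the relaxation protocol `t* = 100 N`.
#' @param order `"cyclic"` or `"random"` (new permutation per sweep, drawn
#'   from the current RNG state).
#' @param tie Zero-field tie rule, `"keep"` or `"plus"`.
#' @param watch Integer indices of patterns whose overlaps are recorded
#'   every sweep (default: pattern 1).
#' @param record_energy Record the energy per sweep (full mode only).
#' @param early_stop Stop on a zero-flip sweep once the stimulus is
#'   constant for the remaining horizon.
#' @return A list of class `sdnn_run` with elements `state` (final
#'   `network_state`), `trajectory` (tibble: `sweep`, `t`, `flips`,
#'   `m_eta`, one `m<k>` column per watched pattern, optional `energy`),
#'   `converged` (last sweep had zero flips), `flips_last_sweep`, and
#'   `sweeps_done`.
#' @export
run_dynamics <- function(state, patterns, coupl = couplings(), schedule,
                         sweeps = 100, order = c("cyclic", "random"),
                         tie = c("keep", "plus"), watch = 1L,
                         record_energy = FALSE, early_stop = TRUE) {
  order <- match.arg(order)
  tie <- match.arg(tie)
  if (sweeps < 1) stop("`sweeps` must be >= 1")
  schedule <- as_schedule(schedule)
  sa <- schedule_args(schedule)
  N <- patterns$N
  watch <- as.integer(watch)
  if (patterns$p > 0 && any(watch < 1 | watch > patterns$p))
    stop("`watch` indices out of range")
  ord <- if (order == "cyclic") {
    matrix(integer(0), N, 0)
  } else {
    vapply(seq_len(sweeps), function(s) sample.int(N), integer(N))
  }
  if (record_energy && coupl$mode != "hebb-full")
    stop("energy is defined only for symmetric undiluted couplings")

  res <- if (coupl$mode == "hebb-full") {
    cpp_run_full(patterns$xi, state$sigma, sa$eta, sa$start, sa$kappa,
                 as.integer(sweeps), watch, record_energy,
                 as.integer(tie == "plus"), ord, early_stop,
                 as.numeric(state$t))
  } else {
    cpp_run_diluted(patterns$xi, state$sigma, coupl$mask, coupl$d,
                    sa$eta, sa$start, sa$kappa, as.integer(sweeps), watch,
                    as.integer(tie == "plus"), ord, early_stop,
                    as.numeric(state$t))
  }

  ns <- res$sweeps_done
  traj <- tibble::tibble(sweep = res$traj$sweep, t = res$traj$t,
                         flips = as.integer(res$traj$flips),
                         m_eta = res$traj$m_eta)
  if (length(watch) > 0) {
    mw <- matrix(res$traj$m_watch, nrow = ns, ncol = length(watch),
                 byrow = TRUE)
    colnames(mw) <- paste0("m", watch)
    traj <- dplyr::bind_cols(traj, tibble::as_tibble(mw))
  }
  if (record_energy) traj$energy <- res$traj$energy

  final <- structure(list(sigma = res$sigma, t = res$t, m = res$m),
                     class = "network_state")
  structure(list(state = final, trajectory = traj,
                 converged = isTRUE(res$converged),
                 flips_last_sweep = res$flips_last,
                 sweeps_done = ns),
            class = "sdnn_run")
}

#' @export
print.sdnn_run <- function(x, ...) {
  cat("<sdnn_run>", x$sweeps_done, "sweep(s),",
      if (x$converged) "reached a fixed point" else "budget exhausted",
      sprintf("(%d flips in last sweep)\n", x$flips_last_sweep))
  invisible(x)
}

#' Energy of a configuration
#'
#' `H = - sum_(i,j) J_ij sigma_i sigma_j - kappa sum_i eta_i sigma_i`,
#' the pair sum running over distinct neuron pairs. Defined only for the
#' symmetric undiluted couplings; calling it in diluted mode is an error
#' because asymmetric synapses admit no energy function.
#'
#' @inheritParams local_field
#' @return The total energy (numeric scalar).
#' @export
energy <- function(state, patterns, stimulus = NULL, coupl = couplings()) {
  if (coupl$mode != "hebb-full")
    stop("no energy function exists for asymmetric diluted couplings")
  N <- patterns$N
  pair <- -(N * sum(state$m^2) - patterns$p) / 2
  ext <- if (is.null(stimulus)) 0 else
    stimulus$kappa * sum(stimulus$eta * state$sigma)
  pair - ext
}

#' Overlaps with the stored patterns
#'
#' `m_mu = (1/N) sum_i xi_i^mu sigma_i`, recomputed from the configuration.
#'
#' @param state A `network_state`.
#' @param patterns A `pattern_set`.
#' @return Numeric vector of length p.
#' @export
overlaps <- function(state, patterns) {
  as.vector(crossprod(patterns$xi, state$sigma)) / patterns$N
}

#' Overlap with a stimulus sign vector
#'
#' `m_perp = (1/N) sum_i eta_i sigma_i`; with an orthogonal stimulus this
#' is the false-recognition overlap.
#'
#' @param state A `network_state`.
#' @param stimulus A `stimulus`.
#' @return Numeric scalar.
#' @export
m_perp <- function(state, stimulus) {
  mean(stimulus$eta * state$sigma)
}

#' Overlap gap
#'
#' `Delta m = |m_rho - m_perp|`, the difference between the overlap reached
#' under a memory-correlated stimulus and under an orthogonal one; its
#' maximum over kappa locates the calibrated field intensity kappa_c.
#'
#' @param mrho Condensed-pattern overlap (may be ensemble-averaged).
#' @param mperp Orthogonal-stimulus overlap (same averaging).
#' @return `abs(mrho - mperp)`.
#' @export
delta_m <- function(mrho, mperp) abs(mrho - mperp)
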