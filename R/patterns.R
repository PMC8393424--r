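#' Generate a set of stored memory patterns
#'
#' Draws `p` binary patterns of length `N`, each entry +1 or -1 with equal
#' probability, independently across sites and patterns. These are the
#' quenched memories wired into the Hebbian couplings; for finite `N` their
#' pairwise overlaps fluctuate at order \eqn{1/\sqrt{N}} ("orthogonal on
#' average").
#'
#' Patterns listed in `correlation_spec` are constructed to agree with the
#' first (target) pattern on an exact fraction `b` of sites, giving an
#' empirical overlap of exactly `2*round(b*N)/N - 1`; see
#' [make_correlated()]. The realized fraction `round(b*N)/N` is recorded in
#' the `correlated_groups` table.
#'
#' @param N Number of neurons (positive integer).
#' @param p Number of stored patterns (non-negative integer).
#' @param seed Optional integer seed; when supplied the RNG state is set
#'   before drawing so the pattern set is reproducible.
#' @param correlation_spec Optional numeric vector of agreement fractions
#'   `b` in `[0, 1]`. For each value, one of the patterns (slots
#'   `2, 3, ...`) is rebuilt to be correlated with pattern 1. Requires
#'   `p >= length(correlation_spec) + 1`.
#' @return An object of class `pattern_set`: a list with elements `xi`
#'   (N x p integer matrix of signs), `N`, `p`, `alpha = p/N`, and
#'   `correlated_groups` (tibble with columns `base`, `member`, `b`,
#'   `b_realized`, `overlap`).
#' @examples
#' ps <- generate_patterns(100, 10, seed = 1)
#' crossprod(ps$xi[, 1], ps$xi[, 2]) / ps$N  # O(1/sqrt(N)) overlap
#' @export
generate_patterns <- function(N, p, seed = NULL, correlation_spec = NULL) {
  if (length(N) != 1L || !is.finite(N) || N < 1 || N != round(N))
    stop("`N` must be a positive integer")
  if (length(p) != 1L || !is.finite(p) || p < 0 || p != round(p))
    stop("`p` must be a non-negative integer")
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(N); p <- as.integer(p)
  xi <- matrix(sample(c(-1L, 1L), N * p, replace = TRUE), nrow = N, ncol = p)

  groups <- tibble::tibble(base = integer(), member = integer(),
                           b = numeric(), b_realized = numeric(),
                           overlap = numeric())
  if (!is.null(correlation_spec) && length(correlation_spec) > 0) {
    if (p < length(correlation_spec) + 1L)
      stop("need at least length(correlation_spec) + 1 patterns")
    for (k in seq_along(correlation_spec)) {
      b <- correlation_spec[k]
      xi[, k + 1L] <- make_correlated(xi[, 1L], b)
      kN <- round(b * N)
      groups <- dplyr::bind_rows(groups, tibble::tibble(
        base = 1L, member = k + 1L, b = b, b_realized = kN / N,
        overlap = (2 * kN - N) / N))
    }
  }
  structure(list(xi = xi, N = N, p = p, alpha = p / N,
                 correlated_groups = groups),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("<pattern_set> N =", x$N, ", p =", x$p,
      sprintf(", alpha = %.4g", x$alpha), "\n")
  if (nrow(x$correlated_groups) > 0) {
    cat("correlated patterns:\n")
    print(x$correlated_groups)
  }
  invisible(x)
}

#' Build a pattern correlated with a given one by an exact site fraction
#'
#' Returns a sign vector agreeing with `base` on exactly `round(b * N)`
#' uniformly chosen sites and negated on the rest, so the empirical overlap
#' with `base` is exactly `(2 * round(b * N) - N) / N` (equal to `2b - 1`
#' whenever `b * N` is an integer). `b = 1` copies the pattern, `b = 0`
#' anti-correlates it.
#'
#' @param base Sign vector (+1/-1) of length N.
#' @param b Agreement fraction in `[0, 1]`. Non-integer `b * N` is rounded
#'   to the nearest site count.
#' @param seed Optional integer seed for the choice of disagreeing sites.
#' @return An integer sign vector of length N.
#' @export
make_correlated <- function(base, b, seed = NULL) {
  if (length(b) != 1L || !is.finite(b) || b < 0 || b > 1)
    stop("`b` must be a single value in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  N <- length(base)
  k <- round(b * N)
  out <- as.integer(base)
  if (k < N) {
    flip <- sample.int(N, N - k)
    out[flip] <- -out[flip]
  }
  out
}

new_stimulus <- function(eta, kappa, gamma, target) {
  structure(list(eta = as.integer(eta), kappa = kappa, gamma = gamma,
                 target = target),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat("<stimulus> N =", length(x$eta), ", kappa =", x$kappa,
      ", gamma =", x$gamma, ", target =", format(x$target), "\n")
  invisible(x)
}

#' Construct an external stimulus correlated with a stored pattern
#'
#' Each stimulus sign independently equals the corresponding site of
#' `target` with probability `gamma`, and its negation otherwise
#' (per-site Bernoulli corruption). The expected overlap between stimulus
#' and target is `2*gamma - 1`; `gamma = 1` reproduces the pattern exactly
#' and `gamma = 1/2` yields a stimulus independent of it.
#'
#' @param target Sign vector of the memory the stimulus points at.
#' @param gamma Per-site agreement probability in `[1/2, 1]`.
#' @param kappa Field intensity (non-negative).
#' @param seed Optional integer seed.
#' @param target_index Optional integer index of the target memory,
#'   recorded for bookkeeping.
#' @return A `stimulus` object: list with `eta` (sign vector), `kappa`,
#'   `gamma`, `target` (index or `NA`).
#' @export
make_stimulus <- function(target, gamma, kappa, seed = NULL,
                          target_index = NA_integer_) {
  if (length(gamma) != 1L || !is.finite(gamma) || gamma < 0.5 || gamma > 1)
    stop("`gamma` must be in [1/2, 1]")
  if (length(kappa) != 1L || !is.finite(kappa) || kappa < 0)
    stop("`kappa` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  N <- length(target)
  flip <- sample(c(1L, -1L), N, replace = TRUE, prob = c(gamma, 1 - gamma))
  new_stimulus(as.integer(target) * flip, kappa, gamma, target_index)
}

#' Construct a stimulus orthogonal (on average) to all stored patterns
#'
#' Draws the stimulus signs i.i.d. +1/-1 with equal probability,
#' independently of every stored memory, so its overlap with each of them
#' is of order \eqn{1/\sqrt{N}}. This is the false-recognition baseline
#' used to measure the orthogonal overlap.
#'
#' @param x A `pattern_set`, or a plain integer giving N.
#' @param kappa Field intensity (non-negative).
#' @param seed Optional integer seed.
#' @return A `stimulus` object with `target = "orthogonal"` and
#'   `gamma = 1/2`.
#' @export
make_orthogonal_stimulus <- function(x, kappa, seed = NULL) {
  N <- if (inherits(x, "pattern_set")) x$N else as.integer(x)
  if (length(kappa) != 1L || !is.finite(kappa) || kappa < 0)
    stop("`kappa` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  eta <- sample(c(-1L, 1L), N, replace = TRUE)
  new_stimulus(eta, kappa, 1 / 2, "orthogonal")
}

#' A stimulus carrying no field
#'
#' Convenience constructor for schedule segments in which no external
#' pattern is presented (`kappa = 0`); the sign vector is irrelevant and
#' set to all +1.
#'
#' @param N Number of neurons.
#' @return A `stimulus` with `kappa = 0`.
#' @export
null_stimulus <- function(N) {
  new_stimulus(rep(1L, N), 0, 1 / 2, NA_integer_)
}

#' Piecewise-constant stimulus schedule
#'
#' Describes a stimulus that changes abruptly at given times, measured in
#' single-neuron updates (one sweep = N updates). Segment `k` applies from
#' `t_start[k]` (inclusive) until the next segment begins; the last segment
#' extends indefinitely. The first segment must start at `t = 0` and the
#' start times must be strictly increasing.
#'
#' @param stimuli List of `stimulus` objects, one per segment.
#' @param t_start Numeric vector of segment start times (same length).
#' @return A `stimulus_schedule` object.
#' @examples
#' ps <- generate_patterns(50, 5, seed = 1)
#' sch <- stimulus_schedule(
#'   list(null_stimulus(50),
#'        make_stimulus(ps$xi[, 1], 0.8, 0.9, target_index = 1L),
#'        make_stimulus(ps$xi[, 2], 1.0, 0.9, target_index = 2L)),
#'   t_start = c(0, 250, 500))
#' stimulus_at(sch, 100)$kappa  # 0: no stimulus yet
#' @export
stimulus_schedule <- function(stimuli, t_start = 0) {
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  if (length(stimuli) == 0) stop("schedule must contain at least one segment")
  if (!all(vapply(stimuli, inherits, logical(1), "stimulus")))
    stop("`stimuli` must be a list of stimulus objects")
  if (length(t_start) != length(stimuli))
    stop("`t_start` must have one entry per segment")
  if (t_start[1] != 0) stop("first segment must start at t = 0")
  if (length(t_start) > 1 && any(diff(t_start) <= 0))
    stop("`t_start` must be strictly increasing")
  Ns <- vapply(stimuli, function(s) length(s$eta), integer(1))
  if (length(unique(Ns)) != 1L) stop("all segments must have the same N")
  structure(list(stimuli = stimuli, t_start = as.numeric(t_start)),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat("<stimulus_schedule>", length(x$stimuli), "segment(s)\n")
  for (k in seq_along(x$stimuli))
    cat(sprintf("  t >= %g: kappa = %g, gamma = %g, target = %s\n",
                x$t_start[k], x$stimuli[[k]]$kappa, x$stimuli[[k]]$gamma,
                format(x$stimuli[[k]]$target)))
  invisible(x)
}

#' Query the stimulus active at a given time
#'
#' @param schedule A `stimulus_schedule`.
#' @param t Time in single-neuron updates (non-negative).
#' @return The `stimulus` of the last segment with `t_start <= t`.
#' @export
stimulus_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  if (length(t) != 1L || !is.finite(t) || t < 0) stop("`t` must be >= 0")
  schedule$stimuli[[max(which(schedule$t_start <= t))]]
}

as_schedule <- function(x) {
  if (inherits(x, "stimulus_schedule")) x
  else if (inherits(x, "stimulus")) stimulus_schedule(list(x), 0)
  else stop("expected a stimulus or stimulus_schedule")
}

# schedule -> arguments of the compiled runners
schedule_args <- function(schedule) {
  S <- length(schedule$stimuli)
  N <- length(schedule$stimuli[[1]]$eta)
  eta <- matrix(0, N, S)
  for (k in seq_len(S)) eta[, k] <- schedule$stimuli[[k]]$eta
  list(eta = eta, start = schedule$t_start,
       kappa = vapply(schedule$stimuli, `[[`, numeric(1), "kappa"))
}
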