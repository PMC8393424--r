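#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mean-field solution
#'
#' @param x An `mf_solution`.
#' @param ... Unused.
#' @return A long tibble with columns `term` and `value` covering the
#'   order parameters.
#' @export
tidy.mf_solution <- function(x, ...) {
  tibble::tibble(
    term = c("m_rho", "q", "r", "C", "m_perp", "m_stim", "u"),
    value = c(x$m_rho, x$q, x$r, x$C, x$m_perp, x$m_stim, x$u))
}

#' One-row summary of a mean-field solution
#'
#' @param x An `mf_solution`.
#' @param ... Unused.
#' @return A one-row tibble with the order parameters, the control
#'   parameters, the branch label and convergence diagnostics.
#' @export
glance.mf_solution <- function(x, ...) {
  tibble::tibble(
    alpha = x$params$alpha, kappa = x$params$kappa,
    gamma = x$params$gamma, beta = x$params$beta,
    m_rho = x$m_rho, q = x$q, r = x$r, m_perp = x$m_perp, u = x$u,
    branch = x$branch, converged = x$converged,
    iterations = x$iterations, residual = x$residual)
}

#' One-row summary of a kappa scan
#'
#' @param x A `kappa_scan` tibble.
#' @param ... Unused.
#' @return A one-row tibble with `kappa_c`, `max_delta_m` and the scan
#'   configuration.
#' @export
glance.kappa_scan <- function(x, ...) {
  cf <- attr(x, "config")
  tibble::tibble(kappa_c = attr(x, "kappa_c"),
                 max_delta_m = attr(x, "max_delta_m"),
                 N = cf$N, alpha = cf$alpha, gamma = cf$gamma,
                 realizations = cf$realizations,
                 d = if (is.null(cf$d)) 0 else cf$d)
}

#' Plot a kappa scan
#'
#' Overlap curves `m_rho(kappa)`, `m_perp(kappa)` and the gap
#' `Delta m(kappa)`, with the calibrated `kappa_c` marked.
#'
#' @param object A `kappa_scan` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kappa_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "kappa", "m_rho", "m_perp",
                  "delta_m"),
    cols = c("m_rho", "m_perp", "delta_m"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kappa, y = .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = attr(object, "kappa_c"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = expression(kappa), y = "overlap",
                  colour = NULL,
                  title = sprintf("kappa_c = %.3g",
                                  attr(object, "kappa_c"))) +
    ggplot2::theme_minimal()
}

#' Plot a time course
#'
#' Per-sweep overlaps with the two scheduled memories, with the stimulus
#' onset and switch times marked.
#'
#' @param object A `time_course` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.time_course <- function(object, ...) {
  cf <- attr(object, "config")
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "t", "m_rho", "m_nu"),
    cols = c("m_rho", "m_nu"), names_to = "memory", values_to = "overlap")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$overlap,
                                   colour = .data$memory)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(cf$t0, cf$t1), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "t (single-neuron updates)", y = "overlap",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
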