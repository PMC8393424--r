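test_that("zero-temperature solutions satisfy their defining equations", {
  grid <- expand.grid(alpha = c(0.05, 0.5, 1, 4),
                      kappa = c(0, 0.5, 1.5),
                      gamma = c(1, 0.9))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    for (init in c("retrieval", "zero")) {
      s <- mf_solve_T0(g$alpha, g$kappa, g$gamma, init = init)
      if (!s$converged) next
      # re-substitution residuals
      erf <- function(x) 2 * pnorm(sqrt(2) * x) - 1
      sden <- sqrt(2 * g$alpha * s$r)
      m_rhs <- g$gamma * erf((s$m_rho + g$kappa) / sden) +
        (1 - g$gamma) * erf((s$m_rho - g$kappa) / sden)
      expect_lt(abs(s$m_rho - m_rhs), 1e-9)
      expect_lt(abs(s$r - 1 / (1 - s$C)^2), 1e-8)
      expect_true(s$C < 1)
      expect_true(abs(s$m_rho) <= 1 && s$r >= 0)
    }
  }
})

test_that("gamma = 1/2 admits the zero solution and gamma = 1 matches the root oracle", {
  s <- mf_solve_T0(0.5, 0.7, gamma = 0.5, init = "zero")
  expect_true(s$converged)
  expect_lt(abs(s$m_rho), 1e-8)

  # independent uniroot-based solution of the retrieval equation
  for (alpha in c(0.05, 0.1)) {
    s <- mf_solve_T0(alpha, 0, 1, init = "retrieval")
    expect_lt(abs(s$m_rho - oracle_mrho_T0(alpha, 0)), 1e-3)
  }
  # deep retrieval limit: alpha -> 0 sends m_rho -> 1
  expect_gt(mf_solve_T0(0.001, 0, 1, init = "retrieval")$m_rho, 0.999)
})

test_that("retrieval branch disappears at the classic capacity", {
  s <- mf_solve_T0(0.2, 0, 1, init = "retrieval")
  expect_false(isTRUE(s$converged) && !is.na(s$m_rho) && s$m_rho > 0.5)
  expect_equal(round(critical_capacity(), 2), 0.14)
  # a field extends the capacity
  expect_gt(critical_capacity(kappa = 0.3), critical_capacity())
})

test_that("orthogonal branch gives erf overlap, increasing in kappa", {
  o0 <- mf_solve_orthogonal_T0(1, 0)
  expect_equal(o0$m_perp, 0)
  expect_equal(mf_m_perp_T0(1e6, 1, o0$r), 1, tolerance = 1e-8)
  # closed form at kappa = sqrt(2 alpha r)
  r <- mf_solve_orthogonal_T0(0.5, 1)$r
  expect_equal(mf_m_perp_T0(sqrt(2 * 0.5 * r), 0.5, r),
               2 * pnorm(sqrt(2)) - 1, tolerance = 1e-12)

  kgrid <- seq(0.1, 2, by = 0.1)
  mp <- vapply(kgrid, function(k) mf_solve_orthogonal_T0(1, k)$m_perp,
               numeric(1))
  expect_true(all(diff(mp) > 0))
})

test_that("strong fields saturate the overlaps", {
  for (alpha in c(0.5, 1)) {
    for (gamma in c(1, 0.9)) {
      kap <- 3 * sqrt(alpha)
      sols <- list(mf_solve_T0(alpha, kap, gamma, init = "retrieval"),
                   mf_solve_T0(alpha, kap, gamma, init = "zero"))
      sols <- Filter(function(s) s$converged, sols)
      sel <- maxwell_select(sols)
      expect_gte(sel$m_rho, 2 * gamma - 1 - 0.01)
      expect_gte(mf_solve_orthogonal_T0(alpha, kap)$m_perp, 0.99)
    }
  }
})

test_that("internal energy and Maxwell selection behave as expected", {
  # perfect-retrieval limit: m = 1, r = 1, kappa = 0 gives u = -1/2
  s <- mf_solve_T0(1e-4, 0, 1, init = "retrieval")
  expect_equal(internal_energy_T0(s), -0.5, tolerance = 1e-3)
  # null solution at kappa = 0: m = 0, m_stim = 0
  z <- mf_solve_T0(0.5, 0, 1, init = "zero")
  expect_equal(z$u, 0.5 * 0.5 * (1 - z$r))

  # selection: lower u wins; candidates retained.  At alpha = 0.03 the
  # retrieval state is the global minimum; by alpha = 0.1 it is only
  # metastable and the disordered branch wins the energy comparison.
  both <- list(mf_solve_T0(0.03, 0, 1, init = "retrieval"),
               mf_solve_T0(0.03, 0, 1, init = "zero"))
  sel <- maxwell_select(both)
  expect_equal(sel$branch, "retrieval")
  both_hi <- list(mf_solve_T0(0.1, 0, 1, init = "retrieval"),
                  mf_solve_T0(0.1, 0, 1, init = "zero"))
  expect_equal(maxwell_select(both_hi)$branch, "zero")
  expect_length(attr(sel, "candidates"), 2)
  expect_error(maxwell_select(list()), "no converged")
})

test_that("finite-temperature solver approaches the zero-temperature one", {
  # beta -> 0: paramagnet
  s_hot <- mf_solve_finiteT(0.5, 0.5, 1, beta = 0.01, init = "retrieval")
  # paramagnetic response to the field: m ~ beta kappa / (1 - beta)
  expect_lt(abs(s_hot$m_rho - 0.01 * 0.5 / (1 - 0.01)), 1e-3)
  expect_lt(s_hot$q, 1e-3)

  for (case in list(c(0.05, 0, 1), c(0.5, 1, 1), c(1, 1, 0.9))) {
    sT <- mf_solve_finiteT(case[1], case[2], case[3], beta = 100,
                           init = "retrieval")
    s0 <- mf_solve_T0(case[1], case[2], case[3], init = "retrieval")
    if (sT$converged && s0$converged) {
      expect_lt(abs(sT$m_rho - s0$m_rho), 1e-2)
      expect_lt(abs(sT$m_perp - s0$m_perp), 2e-2)
    }
    # the r identity is a restatement of the fixed point
    expect_lt(abs(sT$r * (1 - 100 + 100 * sT$q)^2 - sT$q), 1e-8)
  }

  # quadrature self-check: doubling the order barely moves the answer
  a <- mf_solve_finiteT(0.5, 0.5, 1, beta = 20, gh_order = 101)
  b <- mf_solve_finiteT(0.5, 0.5, 1, beta = 20, gh_order = 201)
  expect_lt(abs(a$m_rho - b$m_rho), 1e-9)
})

test_that("analytic kappa_c scales as the noise width", {
  expect_equal(kc_theory(1, 0), 1)
  expect_equal(kc_theory(0.49), 0.7)
  expect_equal(kc_theory(0.5, 0.7), sqrt(0.5 / 0.3))
  expect_error(kc_theory(1, 1), "\\[0, 1\\)")
})

test_that("tidiers summarize solutions", {
  s <- mf_solve_T0(0.1, 0.2, 1, init = "retrieval")
  td <- tidy(s)
  expect_identical(td$term[1], "m_rho")
  expect_equal(td$value[1], s$m_rho)
  gl <- glance(s)
  expect_equal(gl$alpha, 0.1)
  expect_true(gl$converged)
})
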