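# Independent oracles used across tests.

# Equilibrium occupancy of the linear R <-> O <-> D scheme obtained by
# solving the rate-balance linear system directly (independent of the
# package's closed forms). Rates mirror the simulator's construction.
eq_occupancy_linear_solve <- function(l_gamma, q, rate_scale = 1,
                                      desens_rate = 1) {
  k_ro <- rate_scale / l_gamma   # R -> O
  k_or <- rate_scale             # O -> R
  if (is.infinite(q)) {
    # desensitized branch unreachable: two-state equilibrium, D pinned at 0
    A <- rbind(c(-k_ro, k_or, 0), c(0, 0, 1), c(1, 1, 1))
    b <- c(0, 0, 1)
  } else {
    k_od <- desens_rate
    k_do <- desens_rate * q
    A <- rbind(c(-k_ro, k_or, 0),
               c(k_ro, -(k_or + k_od), k_do),
               c(1, 1, 1))
    b <- c(0, 0, 1)
  }
  stats::setNames(as.numeric(solve(A, b)),
                  c("p_resting", "p_open", "p_desensitized"))
}

# Hand-rolled Hill curve for generating fixtures independent of the fitter.
hill_curve <- function(conc, ec50, n, emax) {
  100 + (emax - 100) * conc^n / (conc^n + ec50^n)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <= rel_tol * abs(expected)),
              label = sprintf("relative error %.3g vs tolerance %.3g",
                              max(abs(actual - expected) / abs(expected)),
                              rel_tol))
}
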