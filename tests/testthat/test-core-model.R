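params_gaba <- gating_parameters(L = 1, K_C = 78.5e-6, K_O = 120e-9, N = 2L)

test_that("gamma factor matches hand arithmetic and boundary behavior", {
  expect_equal(gamma_factor(0, params_gaba), 1)
  # ((1 + 1000/78.5) / (1 + 1000/0.12))^2 on the literature K_d values
  expect_equal(gamma_factor(1e-3, params_gaba),
               ((1 + 1000 / 78.5) / (1 + 1000 / 0.12))^2, tolerance = 1e-12)
  expect_equal(gamma_factor(1e-3, params_gaba), 2.72e-6, tolerance = 2e-3)
  # saturating agonist approaches (K_O/K_C)^N
  expect_equal(gamma_factor(1, params_gaba),
               (params_gaba$K_O / params_gaba$K_C)^2, tolerance = 1e-3)
  expect_error(gamma_factor(-1e-9, params_gaba), "concentration")
})

test_that("gamma is strictly decreasing in agonist concentration", {
  x <- 10^seq(-10, -2, length.out = 60)
  g <- gamma_factor(x, params_gaba)
  expect_true(all(diff(g) < 0))
  expect_true(all(g > (params_gaba$K_O / params_gaba$K_C)^2 & g <= 1))
})

test_that("peak and steady-state open probabilities follow the closed forms", {
  expect_equal(popen_peak(0), 1)
  expect_equal(popen_peak(1), 0.5)
  expect_equal(popen_peak(lgamma_from_peak(0.71)), 0.71, tolerance = 1e-12)
  expect_error(popen_peak(-0.1), "l_gamma")
  # q -> Inf collapses the steady state onto the peak
  expect_equal(popen_steady_state(1, Inf), 0.5)
  expect_equal(popen_steady_state(0, 1), 0.5)
  expect_equal(popen_steady_state(0.4085, 0.1459), 0.121, tolerance = 2e-3)
  expect_error(popen_steady_state(1, 0), "Q")
  expect_error(popen_steady_state(1, -2), "Q")
})

test_that("desensitized occupancy matches the printed worked example", {
  lg <- lgamma_from_peak(0.71)
  q <- q_from_steady_state(0.121, lg)
  qs <- q_from_steady_state(0.077, lg)
  # agreement at the printed precision (exact arithmetic gives 0.8296/0.8916)
  expect_equal(p_desensitized(lg, q), 0.829, tolerance = 1e-3)
  expect_equal(p_desensitized(lg, qs), 0.892, tolerance = 1e-3)
  expect_equal(p_desensitized(1, Inf), 0)
})

test_that("peak inversion recovers L*Gamma from printed peaks", {
  expect_equal(lgamma_from_peak(1), 0)
  expect_equal(lgamma_from_peak(0.71), 1 / 0.71 - 1)
  expect_equal(lgamma_from_peak(0.012), 1 / 0.012 - 1)
  expect_error(lgamma_from_peak(0), "0, 1")
  expect_error(lgamma_from_peak(1.2), "0, 1")
})

test_that("Q estimation inverts the steady-state closed form", {
  lg <- lgamma_from_peak(0.71)
  expect_equal(q_from_steady_state(0.121, lg), 0.1459, tolerance = 1e-3)
  expect_equal(q_from_steady_state(0.077, lg), 0.0864, tolerance = 1e-3)
  # steady state equal to the peak: no desensitization sentinel
  expect_identical(q_from_steady_state(1 / (1 + lg), lg), Inf)
  expect_error(q_from_steady_state(0.8, lg), "inconsistent")
})

test_that("Q/steady-state round trip holds to 1e-9 over a log grid", {
  for (lg in 10^seq(-3, 3, length.out = 13)) {
    for (q in 10^seq(-3, 3, length.out = 13)) {
      p <- popen_steady_state(lg, q)
      expect_equal(q_from_steady_state(p, lg, tol = 1e-12), q, tolerance = 1e-9)
    }
  }
})

test_that("occupancy vectors conserve probability and obey the Q ratio", {
  grid <- expand.grid(peak = c(0.012, 0.1, 0.3, 0.71, 0.95),
                      frac = c(0.05, 0.3, 0.9, 1))
  for (i in seq_len(nrow(grid))) {
    m <- measured_response(grid$peak[i], grid$peak[i] * grid$frac[i])
    occ <- occupancy_from_measurements(m)
    expect_lt(abs(sum(occ) - 1), 1e-12)
    q <- attr(occ, "q")
    if (is.finite(q))
      expect_equal(occ[["p_desensitized"]] / occ[["p_open"]], 1 / q,
                   tolerance = 1e-9)
    else
      expect_equal(occ[["p_desensitized"]], 0, tolerance = 1e-9)
  }
})

test_that("closed forms agree with a direct linear-system equilibrium solve", {
  for (lg in c(0.01, 0.4085, 5, 200)) {
    for (q in c(0.05, 0.1459, 1, 50, Inf)) {
      ref <- eq_occupancy_linear_solve(lg, q)
      expect_equal(popen_steady_state(lg, q), ref[["p_open"]],
                   tolerance = 1e-9)
      expect_equal(p_desensitized(lg, q), ref[["p_desensitized"]],
                   tolerance = 1e-9)
    }
  }
})

test_that("monotonicity: peak decreasing in L*Gamma, steady state increasing in Q", {
  lg <- 10^seq(-3, 3, length.out = 40)
  expect_true(all(diff(popen_peak(lg)) < 0))
  q <- 10^seq(-3, 3, length.out = 40)
  expect_true(all(diff(popen_steady_state(0.4, q)) > 0))
})

test_that("measured-response occupancy matches the printed worked example", {
  occ <- occupancy_from_measurements(measured_response(0.71, 0.121))
  expect_equal(occ[["p_open"]], 0.121)
  expect_equal(occ[["p_desensitized"]], 0.829, tolerance = 1e-3)
  expect_equal(occ[["p_resting"]], 0.049, tolerance = 2e-2)
  occ_s <- occupancy_from_measurements(measured_response(0.71, 0.077))
  expect_equal(occ_s[["p_desensitized"]], 0.892, tolerance = 1e-3)
})

test_that("transferred Q predicts low-agonist occupancy", {
  lg071 <- lgamma_from_peak(0.71)
  q <- q_from_steady_state(0.121, lg071)
  occ <- predict_low_agonist(q, 0.012)
  expect_equal(occ[["p_open"]], 0.0111, tolerance = 2e-2)
  expect_lt(abs(sum(occ) - 1), 1e-12)
  # no desensitization: occupancy splits between resting and open at the peak
  occ_inf <- predict_low_agonist(Inf, 0.3)
  expect_equal(occ_inf[["p_desensitized"]], 0)
  expect_equal(occ_inf[["p_open"]], 0.3)
  occ_sym <- predict_low_agonist(1, 1)
  expect_equal(as.numeric(occ_sym), c(0, 0.5, 0.5))
})

test_that("high-affinity fraction and binding fold change match the worked sums", {
  occ_c <- occupancy_from_measurements(measured_response(0.71, 0.121))
  occ_s <- occupancy_from_measurements(measured_response(0.71, 0.077))
  expect_equal(round(high_affinity_fraction(occ_c), 2), 0.95)
  expect_equal(round(high_affinity_fraction(occ_s), 2), 0.97)
  expect_equal(binding_fold_change(occ_c, occ_s), 0.969 / 0.95,
               tolerance = 2e-3)
  expect_equal(binding_fold_change(occ_c, occ_c), 1)
  all_rest <- state_occupancy(1, 0, 0)
  expect_equal(high_affinity_fraction(all_rest), 0)
  expect_error(binding_fold_change(all_rest, occ_c), "undefined")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(gating_parameters(L = -1, K_C = 1e-5, K_O = 1e-7), "L")
  expect_error(gating_parameters(L = 1, K_C = 1e-7, K_O = 1e-5), "K_C")
  expect_error(gating_parameters(L = 1, K_C = 1e-5, K_O = 1e-7, Q = 0), "Q")
  expect_error(state_occupancy(0.5, 0.5, 0.5), "sum")
  expect_error(measured_response(0.5, 0.6), "inconsistent")
})
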