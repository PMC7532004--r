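test_that("neutral or absent ligand leaves the gating parameters unchanged", {
  p <- rod_study_parameters()
  kk150 <- ligand_profile_preset("KK150")
  p2 <- apply_ligand(p, kk150, 10e-6)
  expect_equal(p2$L, p$L)
  expect_equal(p2$Q, p$Q)
  p3 <- apply_ligand(p, ligand_profile_preset("3b5aP"), 0)
  expect_equal(p3$Q, p$Q)
})

test_that("a saturating single-site desensitizer multiplies Q by its efficacy", {
  p <- rod_study_parameters()
  prof <- ligand_profile("toy", list(
    beta_intra = list(K = 1e-7, l_factor = 1, q_factor = 0.59)))
  p2 <- apply_ligand(p, prof, 1)  # 1 M >> K: full occupancy
  expect_equal(p2$Q / p$Q, 0.59, tolerance = 1e-6)
  expect_equal(p2$L, p$L)
})

test_that("the epi-allopregnanolone preset reproduces the measured Q shift at 3 uM", {
  p <- rod_study_parameters()
  p2 <- apply_ligand(p, ligand_profile_preset("3b5aP"), 3e-6)
  lg <- lgamma_from_peak(0.71)
  q_star <- q_from_steady_state(0.077, lg)
  expect_equal(p2$Q, q_star, tolerance = 5e-3)
  expect_equal(p2$L, p$L)  # no activation sites
})

test_that("simulated responses are deterministic and collapse to closed form at zero noise", {
  a <- simulate_responses(sd_peak = 0, sd_ss = 0, seed = 7,
                          profile = ligand_profile_preset("3b5aP"))
  truth <- attr(a, "truth")
  expect_equal(unique(a$p_open_peak[a$condition == "control"]),
               truth$p_open_peak)
  expect_equal(unique(a$p_open_steady_state[a$condition == "control"]),
               truth$p_open_steady_state)
  expect_equal(unique(a$p_open_steady_state[a$condition == "3b5aP"]),
               truth$p_open_steady_state_ligand)
  b1 <- simulate_responses(seed = 42)
  b2 <- simulate_responses(seed = 42)
  expect_identical(b1, b2)
  b3 <- simulate_responses(seed = 43)
  expect_false(identical(b1, b3))
})

test_that("peak scatter reproduces the reported between-cell spread", {
  means <- vapply(1:40, function(s) {
    d <- simulate_responses(n_control = 16L, sd_peak = 0.25, sd_ss = 0.033,
                            seed = s)
    mean(d$p_open_peak)
  }, numeric(1))
  # sample means stay within ~3 SEM of the generating peak; truncation to
  # (0, 1] biases the mean slightly low, hence the one-sided slack
  expect_lt(abs(mean(means) - 0.71), 3 * 0.25 / sqrt(16))
  expect_true(all(means > 0 & means <= 1))
})

test_that("simulated trace relaxes to the closed-form equilibrium within 1e-6", {
  params <- rod_study_parameters()
  sched <- data.frame(t_start = 0, t_end = 200, agonist_conc = 1e-3)
  tr <- simulate_trace(params, sched, rate_scale = 10, desens_rate = 0.5,
                       dt = 0.02)
  occ_end <- attr(tr, "occupancy_final")
  lg <- params$L * gamma_factor(1e-3, params)
  expect_equal(occ_end[["p_open"]], popen_steady_state(lg, params$Q),
               tolerance = 1e-6)
  expect_equal(occ_end[["p_desensitized"]], p_desensitized(lg, params$Q),
               tolerance = 1e-6)
  expect_lt(abs(sum(occ_end) - 1), 1e-9)
})

test_that("without desensitization the trace reaches L*Gamma = 1 equilibrium with no sag", {
  p <- gating_parameters(L = 1, K_C = 1e-4, K_O = 1e-6, Q = Inf)
  x <- 1  # saturating: Gamma ~ (K_O/K_C)^2 = 1e-4, so L*Gamma ~ 1e-4
  # choose agonist so L*Gamma(x) = 1: Gamma = 1 at x = 0 only; use L instead
  p$L <- 1 / gamma_factor(1e-5, p)
  sched <- data.frame(t_start = 0, t_end = 20, agonist_conc = 1e-5)
  tr <- simulate_trace(p, sched, rate_scale = 5, dt = 0.01)
  po <- attr(tr, "p_open")
  expect_equal(po[length(po)], 0.5, tolerance = 1e-6)
  expect_lte(max(po), 0.5 + 1e-9)  # monotone rise, no sag
})

test_that("washout returns the current to baseline", {
  params <- rod_study_parameters()
  sched <- data.frame(t_start = c(0, 30, 30.0001),
                      t_end = c(30, 30.0001, 120),
                      agonist_conc = c(1e-3, 0, 0))
  sched <- sched[c(1, 3), ]
  tr <- simulate_trace(params, sched, dt = 0.02)
  late <- tr$current_nA[tr$time_s > 110]
  expect_lt(max(abs(late)), 1e-2)  # < 0.01% of the full-scale current
})

test_that("an undersampling dt is rejected", {
  params <- rod_study_parameters()
  sched <- data.frame(t_start = 0, t_end = 10, agonist_conc = 1e-3)
  expect_error(simulate_trace(params, sched, rate_scale = 100, dt = 0.5),
               "too coarse")
})

test_that("zero-noise isotherm tables round-trip through the fitter exactly", {
  tab <- simulate_binding("isotherm", occ = state_occupancy(0, 0, 1),
                          noise_cv = 0, replicates = 2L, seed = 3)
  sp <- specific_binding(tab$total_cpm, tab$nonspecific_cpm)
  f <- fit_isotherm(tab$ligand_conc_nM, sp$specific_cpm)
  truth <- attr(tab, "truth")
  expect_rel_equal(f$estimates$K_d, truth$K_d * 1e9, 1e-6)
  expect_rel_equal(f$estimates$B_max, truth$B_max, 1e-6)
})

test_that("a neutral ligand sweep produces a flat 100% modulation curve", {
  tab <- simulate_binding("modulation",
                          profile = ligand_profile_preset("KK150"),
                          noise_pct = 0, replicates = 1L, seed = 1)
  expect_equal(tab$percent_of_control, rep(100, nrow(tab)), tolerance = 1e-9)
})

test_that("a desensitizing sweep yields enhancement with EC50 near the site constant", {
  tab <- simulate_binding("modulation",
                          profile = ligand_profile_preset("3b5aP"),
                          noise_pct = 0, replicates = 1L, seed = 1)
  f <- fit_hill_modulation(tab$modulator_conc_uM, tab$percent_of_control)
  expect_true(f$converged)
  expect_gt(f$estimates$E_max, 100)
})

test_that("a weak-efficacy sweep's fitted EC50 tracks the occupancy constant within 25%", {
  # gentle per-site efficacy keeps the allosteric EC50 shift small, so the
  # fitted midpoint reports the binding-site occupancy constant
  prof <- ligand_profile("weak_pam", list(
    intersubunit = list(K = 0.3e-6, l_factor = 0.85, q_factor = 1)))
  tab <- simulate_binding("modulation", profile = prof, noise_pct = 0,
                          replicates = 1L, seed = 1)
  f <- fit_hill_modulation(tab$modulator_conc_uM, tab$percent_of_control)
  expect_true(f$converged)
  expect_gt(f$estimates$E_max, 100)
  expect_lt(abs(f$estimates$EC50 - 0.3) / 0.3, 0.25)
})

test_that("time-course tables are deterministic given the seed", {
  t1 <- simulate_binding("timecourse", noise_pct = 2, seed = 11)
  t2 <- simulate_binding("timecourse", noise_pct = 2, seed = 11)
  expect_identical(t1, t2)
  t0 <- simulate_binding("timecourse", noise_pct = 0, seed = 11,
                         replicates = 1L)
  f <- fit_mono_exponential(t0$time_min, t0$percent_of_control)
  expect_rel_equal(f$estimates$tau, 3.97, 1e-4)
})
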