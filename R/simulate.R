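#' Reference gating parameters of the study conditions
#'
#' Gating parameters reproducing the measured alpha1beta3 responses. L is
#' agonist-independent and is set so the peak open probability at 1 mM GABA
#' is 0.71; Q is set so the steady-state open probability there is 0.121.
#' For GABA the agonist affinities are the literature estimates (K_C = 78.5
#' uM resting, K_O = 120 nM open, N = 2). For muscimol the resting affinity
#' is taken equal to GABA's and the open-state affinity is solved from the
#' measured peak open probability of 0.012 at 20 nM muscimol (giving K_O of
#' about 0.48 nM, the sub-nanomolar affinity expected of the high-affinity
#' radioligand).
#'
#' @param agonist \code{"GABA"} or \code{"muscimol"}.
#' @return A [gating_parameters()] object.
#' @export
rod_study_parameters <- function(agonist = c("GABA", "muscimol")) {
  agonist <- match.arg(agonist)
  p <- gating_parameters(L = 1, K_C = 78.5e-6, K_O = 120e-9, N = 2L, Q = Inf)
  lg <- lgamma_from_peak(0.71)
  p$L <- lg / gamma_factor(1e-3, p)
  p$Q <- q_from_steady_state(0.121, lg)
  if (agonist == "muscimol") {
    # solve K_O from peak P_open = 0.012 at 20 nM muscimol
    x <- 20e-9
    gamma_target <- lgamma_from_peak(0.012) / p$L
    p$K_O <- x / ((1 + x / p$K_C) / gamma_target^(1 / p$N) - 1)
  }
  p
}

#' State affinities matched to a gating parameterization
#'
#' Builds a [state_affinities()] whose resting K_d is the parameters' K_C
#' and whose open and desensitized K_d both equal K_O — the equal-affinity
#' assumption under which Q is transferable.
#'
#' @param params a [gating_parameters()].
#' @return A [state_affinities()].
#' @export
matched_affinities <- function(params) {
  stopifnot(inherits(params, "gating_parameters"))
  state_affinities(resting = params$K_C, open = params$K_O,
                   desensitized = params$K_O)
}

rtruncnorm01 <- function(n, mean, sd, lower = 0, upper = 1) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > lower && v <= upper) break
    }
    out[i] <- v
  }
  out
}

#' Simulate paired peak / steady-state open-probability measurements
#'
#' Draws per-cell peak and steady-state open probabilities around the ROD
#' closed-form values, with truncated-normal between-cell scatter on (0, 1].
#' When a ligand profile is supplied, each cell yields a paired
#' control/ligand pair (the paired design of the desensitization
#' experiments: each cell serves as its own control), with the ligand acting
#' through [apply_ligand()].
#'
#' @param params a [gating_parameters()]; defaults to the study conditions
#'   ([rod_study_parameters()]).
#' @param agonist_conc agonist concentration, molar (default 1 mM GABA).
#' @param n_control,n_ligand cells per condition (defaults 7 and 5, the
#'   study's steady-state group sizes).
#' @param sd_peak between-cell SD of the peak open probability (default
#'   0.25, the reported scatter around 0.71).
#' @param sd_ss between-cell SD of the steady-state open probability
#'   (default 0.033, the reported scatter around 0.121).
#' @param profile optional [ligand_profile()] for the ligand condition.
#' @param ligand_conc ligand concentration, molar (default 3 uM).
#' @param seed integer seed fixing all draws.
#' @return A data frame with columns \code{cell}, \code{condition},
#'   \code{agonist_conc}, \code{p_open_peak}, \code{p_open_steady_state};
#'   attribute \code{truth} holds the generating closed-form values.
#' @export
simulate_responses <- function(params = rod_study_parameters(),
                               agonist_conc = 1e-3,
                               n_control = 7L, n_ligand = 5L,
                               sd_peak = 0.25, sd_ss = 0.033,
                               profile = NULL, ligand_conc = 3e-6,
                               seed = 1L) {
  stopifnot(inherits(params, "gating_parameters"))
  set.seed(seed)
  lg <- params$L * gamma_factor(agonist_conc, params)
  peak0 <- popen_peak(lg)
  ss0 <- popen_steady_state(lg, params$Q)
  draw <- function(n, condition, pars) {
    lg_c <- pars$L * gamma_factor(agonist_conc, pars)
    peak_mu <- popen_peak(lg_c)
    ss_mu <- popen_steady_state(lg_c, pars$Q)
    peak <- rtruncnorm01(n, peak_mu, sd_peak)
    ss <- vapply(peak, function(pk) rtruncnorm01(1, ss_mu, sd_ss,
                                                 upper = pk), numeric(1))
    data.frame(cell = seq_len(n), condition = condition,
               agonist_conc = agonist_conc, p_open_peak = peak,
               p_open_steady_state = ss)
  }
  out <- draw(n_control, "control", params)
  truth <- list(l_gamma = lg, p_open_peak = peak0,
                p_open_steady_state = ss0, q = params$Q)
  if (!is.null(profile)) {
    pars_l <- apply_ligand(params, profile, ligand_conc)
    dl <- draw(n_ligand, profile$name, pars_l)
    out <- rbind(out, dl)
    truth$q_ligand <- pars_l$Q
    truth$p_open_steady_state_ligand <-
      popen_steady_state(pars_l$L * gamma_factor(agonist_conc, pars_l),
                         pars_l$Q)
  }
  attr(out, "truth") <- truth
  out
}

#' Simulate a macroscopic current trace from three-state kinetics
#'
#' Integrates the linear Resting <-> Open <-> Desensitized scheme under a
#' piecewise-constant agonist schedule. Rate constants are constrained so
#' that the equilibria match the closed-form model: the open->resting rate is
#' \code{rate_scale}, resting->open is \code{rate_scale / (L*Gamma)},
#' open->desensitized is \code{desens_rate} and desensitized->open is
#' \code{Q * desens_rate}. Absolute rates are free parameters of the
#' generator (the closed-form analysis is equilibrium-only); the defaults
#' give second-scale relaxations typical of oocyte recordings. The current is
#' \code{-amplitude_nA * P_open(t)} sign-flipped to a positive magnitude.
#'
#' @param params a [gating_parameters()].
#' @param schedule data frame with columns \code{t_start}, \code{t_end}
#'   (seconds) and \code{agonist_conc} (molar), contiguous and increasing.
#' @param rate_scale open->resting rate, 1/s, > 0.
#' @param desens_rate open->desensitized rate, 1/s (ignored when Q is
#'   infinite).
#' @param dt output sampling interval, seconds; must resolve the fastest
#'   relaxation (dt < 1 / max rate) or an error is raised.
#' @param amplitude_nA current at P_open = 1, nA.
#' @return A [current_trace()] with attribute \code{p_open} (the open
#'   probability at each sample) and \code{occupancy_final}.
#' @export
simulate_trace <- function(params, schedule, rate_scale = 10,
                           desens_rate = 0.5, dt = 0.01,
                           amplitude_nA = 100) {
  stopifnot(inherits(params, "gating_parameters"),
            all(c("t_start", "t_end", "agonist_conc") %in% names(schedule)))
  if (rate_scale <= 0) stop("rate_scale must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  k_od <- if (is.infinite(params$Q)) 0 else desens_rate
  k_do <- if (is.infinite(params$Q)) 0 else desens_rate * params$Q
  lg_all <- params$L * gamma_factor(schedule$agonist_conc, params)
  max_rate <- max(rate_scale, rate_scale / pmax(lg_all, 1e-12), k_od, k_do)
  if (dt >= 1 / max_rate)
    stop(sprintf(
      "dt = %g s is too coarse for the fastest rate (%g /s); reduce dt below %g s",
      dt, max_rate, 1 / max_rate))
  state <- c(R = 1, O = 0, D = 0)
  times_all <- numeric(0)
  popen_all <- numeric(0)
  for (i in seq_len(nrow(schedule))) {
    lg <- lg_all[i]
    k_or <- rate_scale
    k_ro <- rate_scale / lg
    deriv <- function(t, y, parms) {
      dR <- -k_ro * y[1] + k_or * y[2]
      dO <- k_ro * y[1] - (k_or + k_od) * y[2] + k_do * y[3]
      dD <- k_od * y[2] - k_do * y[3]
      list(c(dR, dO, dD))
    }
    tt <- seq(schedule$t_start[i], schedule$t_end[i], by = dt)
    sol <- deSolve::lsoda(state, tt, deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    state <- sol[nrow(sol), c("R", "O", "D")]
    keep <- if (i == 1L) seq_len(nrow(sol)) else -1L
    times_all <- c(times_all, sol[keep, "time"])
    popen_all <- c(popen_all, sol[keep, "O"])
  }
  tr <- current_trace(times_all, -amplitude_nA * popen_all, sign = -1,
                      metadata = "simulated three-state trace")
  attr(tr, "p_open") <- popen_all
  attr(tr, "occupancy_final") <- state_occupancy(
    p_resting = unname(state["R"]), p_open = unname(state["O"]),
    p_desensitized = unname(state["D"]))
  tr
}

#' Simulate radioligand binding tables
#'
#' Generates the three binding-assay designs with the noise structure the
#' fitters assume:
#' \describe{
#'   \item{isotherm}{specific binding from
#'     [predict_fractional_binding()] times \code{B_max}, plus a linear
#'     nonspecific component; multiplicative counting noise of the given CV.}
#'   \item{modulation}{a modulator-concentration sweep: at each
#'     concentration the ligand profile modifies the gating parameters
#'     ([apply_ligand()]), the steady-state occupancy follows in closed form,
#'     and binding at \code{agonist_conc} radioligand is expressed as percent
#'     of the no-modulator control; additive noise in percent.}
#'   \item{timecourse}{mono-exponential approach from \code{B0} to
#'     \code{B_inf} with time constant \code{tau_min}; additive noise scaled
#'     like the reported SEMs.}
#' }
#'
#' @param kind one of \code{"isotherm"}, \code{"modulation"},
#'   \code{"timecourse"}.
#' @param params gating parameters (modulation kind).
#' @param profile ligand profile (modulation kind).
#' @param occ a [state_occupancy()] used for the isotherm expectation;
#'   default all-desensitized (a fully shifted receptor population).
#' @param aff a [state_affinities()]; when \code{NULL} (default) the
#'   modulation assay uses [matched_affinities()] of \code{params} (the
#'   radioligand is the agonist) and the other kinds use
#'   [state_affinities()] defaults.
#' @param concentrations radioligand (isotherm) or modulator (modulation)
#'   concentrations, molar.
#' @param agonist_conc fixed radioligand concentration for the modulation
#'   assay (default 3 nM muscimol).
#' @param B_max maximal specific binding, cpm.
#' @param nonspecific_slope_cpm_per_M slope of the linear nonspecific
#'   component, cpm per molar.
#' @param noise_cv multiplicative counting-noise CV (isotherm).
#' @param noise_pct additive noise SD, percent of control
#'   (modulation/timecourse).
#' @param times_min,tau_min,B0,B_inf time-course design and generating
#'   parameters (defaults: the assay's sampling grid; tau 3.97 min; 100 to
#'   200 percent of control).
#' @param replicates replicate count per design point.
#' @param seed integer seed.
#' @return A data frame in the matching assay schema, with attribute
#'   \code{truth} holding the generating parameters.
#' @export
simulate_binding <- function(kind = c("isotherm", "modulation", "timecourse"),
                             params = rod_study_parameters("muscimol"),
                             profile = ligand_profile_preset("3b5aP"),
                             occ = state_occupancy(0, 0, 1),
                             aff = NULL,
                             concentrations = NULL,
                             agonist_conc = 3e-9,
                             B_max = 2000,
                             nonspecific_slope_cpm_per_M = 2e8,
                             noise_cv = 0, noise_pct = 0,
                             times_min = c(1, 3, 10, 30, 60),
                             tau_min = 3.97, B0 = 100, B_inf = 200,
                             replicates = 3L, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (is.null(aff))
    aff <- if (kind == "modulation") matched_affinities(params)
           else state_affinities()
  if (kind == "isotherm") {
    if (is.null(concentrations))
      concentrations <- exp(seq(log(0.3e-9), log(1e-6), length.out = 8))
    grid <- expand.grid(replicate = seq_len(replicates),
                        ligand_conc = concentrations)
    spec <- B_max * predict_fractional_binding(occ, grid$ligand_conc, aff)
    nonspec <- nonspecific_slope_cpm_per_M * grid$ligand_conc
    noise <- function(mu) mu * (1 + stats::rnorm(length(mu), 0, noise_cv))
    out <- data.frame(ligand_conc_nM = grid$ligand_conc * 1e9,
                      total_cpm = noise(spec + nonspec),
                      nonspecific_cpm = noise(nonspec),
                      replicate = grid$replicate)
    # the expectation is a true single-site isotherm only when every occupied
    # state shares one K_d; report that K_d as truth, else NA
    kds <- c(aff$resting, aff$open, aff$desensitized)
    wts <- as.numeric(occ)
    active <- kds[wts > 1e-12]
    kd_eff <- if (length(unique(active)) == 1L) active[1L] else NA_real_
    attr(out, "truth") <- list(B_max = B_max, K_d = kd_eff, occ = occ)
    return(out)
  }
  if (kind == "modulation") {
    if (is.null(concentrations))
      concentrations <- exp(seq(log(3e-9), log(30e-6), length.out = 9))
    bind_at <- function(c_mod) {
      p <- apply_ligand(params, profile, c_mod)
      lg <- p$L * gamma_factor(agonist_conc, p)
      occ_c <- state_occupancy(
        p_resting = lg * popen_steady_state(lg, p$Q),
        p_open = popen_steady_state(lg, p$Q),
        p_desensitized = p_desensitized(lg, p$Q))
      predict_fractional_binding(occ_c, agonist_conc, aff)
    }
    control <- bind_at(0)
    grid <- expand.grid(replicate = seq_len(replicates),
                        modulator_conc = concentrations)
    pct <- vapply(grid$modulator_conc, function(cc) 100 * bind_at(cc) / control,
                  numeric(1))
    out <- data.frame(modulator_conc_uM = grid$modulator_conc * 1e6,
                      percent_of_control = pct +
                        stats::rnorm(nrow(grid), 0, noise_pct),
                      replicate = grid$replicate)
    attr(out, "truth") <- list(profile = profile, control_binding = control)
    return(out)
  }
  grid <- expand.grid(replicate = seq_len(replicates), time_min = times_min)
  mu <- B0 + (B_inf - B0) * (1 - exp(-grid$time_min / tau_min))
  out <- data.frame(time_min = grid$time_min,
                    percent_of_control = mu +
                      stats::rnorm(nrow(grid), 0, noise_pct),
                    replicate = grid$replicate)
  attr(out, "truth") <- list(tau = tau_min, B0 = B0, B_inf = B_inf)
  out
}
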