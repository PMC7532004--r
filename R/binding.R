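#' Specific binding from total and nonspecific counts
#'
#' Specific binding = total - nonspecific (nonspecific measured in the
#' presence of 1 mM GABA). Negative values are retained, not clipped, so that
#' replicate averages remain unbiased; a \code{negative} flag marks them for
#' QC.
#'
#' @param total_cpm,nonspecific_cpm scintillation counts, cpm, >= 0;
#'   vectorized.
#' @return A data frame with columns \code{specific_cpm} and \code{negative}.
#' @export
specific_binding <- function(total_cpm, nonspecific_cpm) {
  if (any(total_cpm < 0) || any(nonspecific_cpm < 0))
    stop("counts must be >= 0")
  s <- total_cpm - nonspecific_cpm
  data.frame(specific_cpm = s, negative = s < 0)
}

#' Convert counts to amount of ligand
#'
#' Standard scintillation-counting conversion: cpm / efficiency = dpm;
#' 1 Ci = 2.22e12 dpm; amount (fmol) = dpm / (2.22e12 * specific activity in
#' Ci/mmol) * 1e12.
#'
#' @param cpm counts per minute, >= 0.
#' @param specific_activity_Ci_per_mmol radioligand specific activity
#'   (e.g. 30 for [3H]muscimol at 30 Ci/mmol), > 0.
#' @param counting_efficiency fraction of decays counted, in (0, 1].
#' @return Amount in fmol.
#' @export
counts_to_amount <- function(cpm, specific_activity_Ci_per_mmol,
                             counting_efficiency = 1) {
  if (any(cpm < 0)) stop("cpm must be >= 0")
  if (specific_activity_Ci_per_mmol <= 0)
    stop("specific activity must be > 0")
  if (counting_efficiency <= 0 || counting_efficiency > 1)
    stop("counting efficiency must lie in (0, 1]")
  dpm <- cpm / counting_efficiency
  dpm / (2.22e12 * specific_activity_Ci_per_mmol) * 1e12
}

fit_failure <- function(kind, msg, residuals = NULL) {
  structure(list(kind = kind, converged = FALSE, message = msg,
                 residuals = residuals),
            class = c("rod_fit_failure", "rod_fit"))
}

fit_result <- function(kind, estimates, se, fit, data) {
  structure(list(kind = kind, converged = TRUE, estimates = estimates,
                 se = se, residuals = stats::residuals(fit),
                 rss = sum(stats::residuals(fit)^2), data = data,
                 model = fit),
            class = "rod_fit")
}

#' @export
print.rod_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat(sprintf("%s fit FAILED: %s\n", x$kind, x$message))
    return(invisible(x))
  }
  cat(sprintf("%s fit\n", x$kind))
  for (nm in names(x$estimates))
    cat(sprintf("  %-10s %#.4g (SE %#.3g)\n", nm, x$estimates[[nm]],
                x$se[[nm]]))
  cat(sprintf("  RSS %.4g over %d points\n", x$rss, length(x$residuals)))
  invisible(x)
}

#' Fit a single-site binding isotherm
#'
#' Least-squares fit of B(x) = B_max * x / (K_d + x) to specific binding
#' versus ligand concentration. Concentrations are handled on a log grid
#' internally for the coarse start-value search, which makes the fit
#' invariant under unit rescaling of concentration.
#'
#' @param concentration ligand concentrations (any consistent unit), > 0,
#'   at least 4 distinct values.
#' @param specific specific binding (cpm or fmol), same length.
#' @param weights optional weights (e.g. 1/SEM^2); default unweighted.
#' @return A \code{"rod_fit"} with estimates \code{K_d} (in the unit of
#'   \code{concentration}) and \code{B_max}, or a failure report.
#' @export
fit_isotherm <- function(concentration, specific, weights = NULL) {
  stopifnot(length(concentration) == length(specific))
  if (any(concentration <= 0)) stop("concentrations must be > 0")
  if (length(unique(concentration)) < 4L)
    stop("need >= 4 distinct concentrations spanning K_d")
  d <- data.frame(x = concentration, y = specific)
  w <- if (is.null(weights)) rep(1, nrow(d)) else weights
  # coarse grid in log space to seed the solver away from local minima
  kd_grid <- exp(seq(log(min(d$x)) - log(10), log(max(d$x)) + log(10),
                     length.out = 25))
  sse <- vapply(kd_grid, function(k) {
    bhat <- sum(w * d$y * d$x / (k + d$x)) / sum(w * (d$x / (k + d$x))^2)
    sum(w * (d$y - bhat * d$x / (k + d$x))^2)
  }, numeric(1))
  kd0 <- kd_grid[which.min(sse)]
  b0 <- sum(w * d$y * d$x / (kd0 + d$x)) / sum(w * (d$x / (kd0 + d$x))^2)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Bmax * x / (Kd + x), data = d, weights = w,
                      start = list(Bmax = b0, Kd = kd0),
                      lower = c(Bmax = 0, Kd = 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(fit_failure("isotherm", conditionMessage(fit)))
  est <- stats::coef(fit)
  if (est[["Kd"]] < min(d$x) / 100 || est[["Kd"]] > max(d$x) * 100)
    return(fit_failure("isotherm", sprintf(
      "fitted K_d (%g) falls outside the credible range [%g, %g]",
      est[["Kd"]], min(d$x) / 100, max(d$x) * 100),
      residuals = stats::residuals(fit)))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 2))
  fit_result("isotherm",
             list(K_d = unname(est[["Kd"]]), B_max = unname(est[["Bmax"]])),
             list(K_d = unname(se[["Kd"]]), B_max = unname(se[["Bmax"]])),
             fit, d)
}

#' Fit a Hill concentration-response curve for modulation of binding
#'
#' Fits E(c) = 100 + (E_max - 100) * c^n / (c^n + EC50^n) to
#' percent-of-control binding versus modulator concentration, with the
#' baseline anchored at exactly 100\% (the no-modulator control). Inhibition
#' (E_max < 100) is supported. When the fitted |E_max - 100| is smaller than
#' twice the residual standard deviation the result is flagged as a
#' no-effect degenerate report (\code{no_effect = TRUE}) since EC50 and the
#' slope are then unidentifiable.
#'
#' @param concentration modulator concentrations, > 0, >= 5 distinct values.
#' @param percent_of_control response as percent of no-modulator control
#'   (100 = no effect).
#' @param weights optional weights.
#' @param free_baseline if TRUE, the baseline is a free parameter instead of
#'   being anchored at 100.
#' @return A \code{"rod_fit"} with estimates \code{EC50}, \code{hill_slope},
#'   \code{E_max} (and \code{baseline} when free), or a failure report.
#' @export
fit_hill_modulation <- function(concentration, percent_of_control,
                                weights = NULL, free_baseline = FALSE) {
  stopifnot(length(concentration) == length(percent_of_control))
  if (any(concentration <= 0)) stop("concentrations must be > 0")
  if (length(unique(concentration)) < 5L)
    stop("need >= 5 distinct modulator concentrations")
  d <- data.frame(x = concentration, y = percent_of_control)
  w <- if (is.null(weights)) rep(1, nrow(d)) else weights
  emax0 <- d$y[which.max(abs(d$y - 100))]
  half <- (100 + emax0) / 2
  ec0 <- d$x[which.min(abs(d$y - half))]
  grid <- expand.grid(ec = exp(seq(log(min(d$x)), log(max(d$x)),
                                   length.out = 15)),
                      n = c(0.5, 1, 1.5, 2, 3))
  sse <- mapply(function(ec, n) {
    f <- d$x^n / (d$x^n + ec^n)
    em <- 100 + sum(w * (d$y - 100) * f) / max(sum(w * f^2), 1e-12)
    sum(w * (d$y - (100 + (em - 100) * f))^2)
  }, grid$ec, grid$n)
  best <- grid[which.min(sse), ]
  start <- list(Emax = emax0, EC50 = best$ec, n = best$n)
  form <- y ~ 100 + (Emax - 100) * x^n / (x^n + EC50^n)
  if (free_baseline) {
    form <- y ~ base + (Emax - base) * x^n / (x^n + EC50^n)
    start$base <- 100
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = d, weights = w, start = start,
                      lower = c(Emax = 0, EC50 = min(d$x) / 1e3, n = 0.05,
                                if (free_baseline) c(base = 0)),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 300, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(fit_failure("hill_modulation", conditionMessage(fit)))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(
                   rep(NA_real_, length(est)), names(est)))
  out <- fit_result("hill_modulation",
                    c(list(EC50 = unname(est[["EC50"]]),
                           hill_slope = unname(est[["n"]]),
                           E_max = unname(est[["Emax"]])),
                      if (free_baseline) list(baseline = unname(est[["base"]]))),
                    c(list(EC50 = unname(se[["EC50"]]),
                           hill_slope = unname(se[["n"]]),
                           E_max = unname(se[["Emax"]])),
                      if (free_baseline) list(baseline = unname(se[["base"]]))),
                    fit, d)
  resid_sd <- sqrt(out$rss / max(1, length(out$residuals) - length(est)))
  out$no_effect <- abs(out$estimates$E_max - 100) < 2 * max(resid_sd, 1e-12)
  out
}

#' Fit a mono-exponential binding time course
#'
#' Fits B(t) = B0 + (Binf - B0) * (1 - exp(-t/tau)) to binding versus time,
#' as used for the slow onset of neurosteroid enhancement of low-concentration
#' radioligand binding.
#'
#' @param time_min times (minutes), >= 4 points including near-plateau.
#' @param level binding level (percent of control or counts).
#' @param weights optional weights.
#' @return A \code{"rod_fit"} with estimates \code{tau} (minutes), \code{B0}
#'   (initial level) and \code{B_inf} (plateau), or a failure report.
#' @export
fit_mono_exponential <- function(time_min, level, weights = NULL) {
  stopifnot(length(time_min) == length(level))
  if (length(unique(time_min)) < 4L)
    stop("need >= 4 time points including near-plateau")
  if (any(time_min < 0)) stop("times must be >= 0")
  d <- data.frame(t = time_min, y = level)
  w <- if (is.null(weights)) rep(1, nrow(d)) else weights
  b0 <- d$y[which.min(d$t)]
  binf <- mean(d$y[d$t >= stats::quantile(d$t, 0.75)])
  tau0 <- max(d$t[which.min(abs((d$y - b0) - (1 - exp(-1)) * (binf - b0)))],
              min(d$t[d$t > 0]))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ B0 + (Binf - B0) * (1 - exp(-t / tau)), data = d,
                      weights = w,
                      start = list(B0 = b0, Binf = binf, tau = tau0),
                      lower = c(B0 = -Inf, Binf = -Inf, tau = 1e-9),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 300, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(fit_failure("mono_exponential", conditionMessage(fit)))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(
                   rep(NA_real_, length(est)), names(est)))
  fit_result("mono_exponential",
             list(tau = unname(est[["tau"]]), B0 = unname(est[["B0"]]),
                  B_inf = unname(est[["Binf"]])),
             list(tau = unname(se[["tau"]]), B0 = unname(se[["B0"]]),
                  B_inf = unname(se[["Binf"]])),
             fit, d)
}

#' Per-state agonist affinities
#'
#' Orthosteric agonist dissociation constants of the resting, open and
#' desensitized states. The resting K_d must be the weakest (largest); the
#' defaults are the literature GABA estimates for alpha1beta2gamma2 receptors
#' (78.5 uM resting, 120 nM open, 40 nM desensitized).
#'
#' @param resting,open,desensitized K_d per state, molar.
#' @return An object of class \code{"state_affinities"}.
#' @export
state_affinities <- function(resting = 78.5e-6, open = 120e-9,
                             desensitized = 40e-9) {
  if (any(c(resting, open, desensitized) <= 0)) stop("K_d values must be > 0")
  if (resting < open || resting < desensitized)
    stop("resting-state K_d must be the weakest (largest)")
  structure(list(resting = resting, open = open, desensitized = desensitized),
            class = "state_affinities")
}

#' Predict fractional radioligand binding from state occupancy
#'
#' Occupancy-weighted sum of single-site binding across states:
#' sum over states of p_state * x / (x + K_d,state). With equal open and
#' desensitized affinities and x well below those K_d values this reduces to
#' the high-affinity-fraction approximation of [high_affinity_fraction()].
#'
#' @param occ a [state_occupancy()].
#' @param x radioligand concentration, molar; vectorized.
#' @param aff a [state_affinities()].
#' @return Fraction of receptors binding ligand, in [0, 1].
#' @export
predict_fractional_binding <- function(occ, x, aff = state_affinities()) {
  stopifnot(inherits(occ, "state_occupancy"), inherits(aff, "state_affinities"))
  if (any(x < 0)) stop("ligand concentration must be >= 0")
  occ[["p_resting"]] * x / (x + aff$resting) +
    occ[["p_open"]] * x / (x + aff$open) +
    occ[["p_desensitized"]] * x / (x + aff$desensitized)
}
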