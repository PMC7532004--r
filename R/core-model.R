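#' Agonist-dependence factor of the ROD model
#'
#' Computes the factor Gamma = ((1 + x/K_C) / (1 + x/K_O))^N that scales the
#' resting/open equilibrium constant L with agonist concentration. Gamma is 1
#' with no agonist and decreases strictly toward (K_O/K_C)^N at saturating
#' agonist, because the open state binds agonist more tightly (K_O < K_C), so
#' agonist occupancy pulls the equilibrium toward open.
#'
#' @param x agonist concentration (molar), vectorized; must be >= 0.
#' @param params a [gating_parameters()] object.
#' @return Gamma, dimensionless, same length as \code{x}.
#' @examples
#' p <- gating_parameters(L = 1, K_C = 78.5e-6, K_O = 120e-9)
#' gamma_factor(1e-3, p)   # ~2.7e-6 at 1 mM GABA
#' @export
gamma_factor <- function(x, params) {
  stopifnot(inherits(params, "gating_parameters"))
  if (any(!is.finite(x)) || any(x < 0))
    stop("agonist concentration must be finite and >= 0")
  ((1 + x / params$K_C) / (1 + x / params$K_O))^params$N
}

#' Peak open probability from the composite gating constant
#'
#' At the peak of the response (before desensitization accrues) the ROD model
#' gives P_open = 1 / (1 + L*Gamma).
#'
#' @param l_gamma the product L*Gamma, dimensionless, >= 0; vectorized.
#' @return Peak open probability in (0, 1].
#' @export
popen_peak <- function(l_gamma) {
  if (any(!is.finite(l_gamma) & !is.infinite(l_gamma)) || any(l_gamma < 0))
    stop("l_gamma must be >= 0")
  1 / (1 + l_gamma)
}

#' Steady-state open probability
#'
#' With desensitization equilibrated, P_open = 1 / (1 + 1/Q + L*Gamma). As
#' Q -> Inf this reduces to the peak (two-state) expression.
#'
#' @inheritParams popen_peak
#' @param q open/desensitized equilibrium constant Q > 0 (Inf allowed).
#' @return Steady-state open probability, never above [popen_peak()].
#' @export
popen_steady_state <- function(l_gamma, q) {
  if (any(l_gamma < 0) || any(is.na(l_gamma))) stop("l_gamma must be >= 0")
  if (any(is.na(q)) || any(q <= 0)) stop("Q must be positive")
  1 / (1 + 1 / q + l_gamma)
}

#' Steady-state desensitized probability
#'
#' P_desensitized = 1 / (1 + Q + Q*L*Gamma), i.e. (1/Q) times the steady-state
#' open probability.
#'
#' @inheritParams popen_steady_state
#' @return Desensitized-state probability.
#' @export
p_desensitized <- function(l_gamma, q) {
  if (any(l_gamma < 0) || any(is.na(l_gamma))) stop("l_gamma must be >= 0")
  if (any(is.na(q)) || any(q <= 0)) stop("Q must be positive")
  ifelse(is.infinite(q), 0, 1 / (1 + q + q * l_gamma))
}

#' Invert the peak open probability for L*Gamma
#'
#' The composite constant is read directly off the measured peak:
#' L*Gamma = 1/P_peak - 1.
#'
#' @param p_peak measured peak open probability in (0, 1]; vectorized.
#' @return L*Gamma >= 0.
#' @export
lgamma_from_peak <- function(p_peak) {
  if (any(!is.finite(p_peak)) || any(p_peak <= 0) || any(p_peak > 1))
    stop("peak P_open must lie in (0, 1]")
  1 / p_peak - 1
}

#' Estimate Q from the steady-state open probability
#'
#' With L*Gamma fixed from the peak, Q = 1 / (1/P_ss - 1 - L*Gamma). A
#' steady-state measurement equal to the peak (within \code{tol} relative)
#' returns \code{Inf}: no desensitization. A steady state exceeding the peak
#' beyond tolerance is an inconsistent measurement and errors.
#'
#' @param p_ss measured steady-state open probability, > 0.
#' @param l_gamma L*Gamma from [lgamma_from_peak()].
#' @param tol relative tolerance for treating \code{p_ss} as equal to the
#'   peak (default 1e-6).
#' @return Q > 0, possibly \code{Inf}.
#' @export
q_from_steady_state <- function(p_ss, l_gamma, tol = 1e-6) {
  stopifnot(length(p_ss) == 1L, length(l_gamma) == 1L)
  if (!is.finite(p_ss) || p_ss <= 0) stop("steady-state P_open must be > 0")
  if (l_gamma < 0) stop("l_gamma must be >= 0")
  p_peak <- 1 / (1 + l_gamma)
  if (p_ss > p_peak * (1 + tol))
    stop(sprintf(
      "inconsistent measurement: steady-state P_open (%g) exceeds the peak implied by L*Gamma = %g (peak %g)",
      p_ss, l_gamma, p_peak))
  inv <- 1 / p_ss - 1 - l_gamma
  if (inv <= p_peak^-1 * tol) return(Inf)
  1 / inv
}

#' Full state occupancy from a measured response pair
#'
#' Composes the two inversions: L*Gamma from the peak, Q from the steady
#' state, then the steady-state occupancy vector. Algebraically
#' \code{p_open = p_ss}, \code{p_resting = L*Gamma * p_ss} and
#' \code{p_desensitized = 1 - (1 + L*Gamma) * p_ss}.
#'
#' @param m a [measured_response()] object.
#' @return A [state_occupancy()] with attributes \code{l_gamma} and \code{q}.
#' @examples
#' occupancy_from_measurements(measured_response(0.71, 0.121))
#' @export
occupancy_from_measurements <- function(m) {
  stopifnot(inherits(m, "measured_response"))
  lg <- lgamma_from_peak(m$p_open_peak)
  q <- q_from_steady_state(m$p_open_steady_state, lg)
  occ <- state_occupancy(p_resting = lg * m$p_open_steady_state,
                         p_open = m$p_open_steady_state,
                         p_desensitized = 1 - (1 + lg) * m$p_open_steady_state)
  attr(occ, "l_gamma") <- lg
  attr(occ, "q") <- q
  occ
}

#' Predict occupancy at a new (low) agonist concentration from a transferred Q
#'
#' Because agonist affinity is taken equal in the open and desensitized
#' states, Q (or the steroid-modified Q*) estimated at one agonist
#' concentration applies at any other. Supplying the measured peak open
#' probability at the new concentration fixes L*Gamma there, and the
#' steady-state occupancy follows in closed form.
#'
#' @param q transferred open/desensitized equilibrium constant (Q or Q*).
#' @param p_peak_low measured peak open probability at the new concentration.
#' @return A [state_occupancy()] with attributes \code{l_gamma} and \code{q}.
#' @export
predict_low_agonist <- function(q, p_peak_low) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0)
    stop("Q must be positive")
  lg <- lgamma_from_peak(p_peak_low)
  p_open <- popen_steady_state(lg, q)
  occ <- state_occupancy(p_resting = lg * p_open,
                         p_open = p_open,
                         p_desensitized = p_desensitized(lg, q))
  attr(occ, "l_gamma") <- lg
  attr(occ, "q") <- q
  occ
}

#' Occupancy of the high-affinity (open + desensitized) states
#'
#' Open and desensitized receptors bind orthosteric agonist with similar,
#' much higher affinity than resting receptors, so at low radioligand
#' concentration specific binding tracks P_open + P_desensitized.
#'
#' @param occ a [state_occupancy()].
#' @return P_open + P_desensitized.
#' @export
high_affinity_fraction <- function(occ) {
  stopifnot(inherits(occ, "state_occupancy"))
  unname(occ[["p_open"]] + occ[["p_desensitized"]])
}

#' Predicted fold change of low-concentration radioligand binding
#'
#' Ratio of high-affinity-state occupancies between a treated (e.g. steroid)
#' and a control condition; interpreted as the predicted fold change of
#' specific radioligand binding at ligand concentrations well below the
#' high-affinity K_d.
#'
#' @param occ_control,occ_treated [state_occupancy()] objects.
#' @return Dimensionless fold change.
#' @export
binding_fold_change <- function(occ_control, occ_treated) {
  f0 <- high_affinity_fraction(occ_control)
  f1 <- high_affinity_fraction(occ_treated)
  if (f0 <= 0)
    stop("control high-affinity fraction is zero: fold change undefined")
  f1 / f0
}
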