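#' Gating parameters of the three-state ROD model
#'
#' Bundles the equilibrium constants of the Resting-Open-Desensitized (ROD)
#' scheme: \code{L = Resting/Open} quantifies constitutive (agonist-free)
#' activity, \code{K_C} and \code{K_O} are the agonist dissociation constants
#' of the resting and open receptor, \code{N} is the number of agonist binding
#' sites, and \code{Q = Open/Desensitized} sets the steady-state balance
#' between open and desensitized receptors. Agonist binding is assumed to have
#' equal affinity in the open and desensitized states, so \code{Q} carries no
#' agonist-concentration dependence and can be transferred between agonist
#' concentrations.
#'
#' @param L positive dimensionless resting/open equilibrium constant.
#' @param K_C agonist dissociation constant of the resting state (molar).
#' @param K_O agonist dissociation constant of the open state (molar); must be
#'   smaller than \code{K_C} (the open receptor binds agonist more tightly).
#' @param N number of agonist binding sites (default 2, the two
#'   beta(+)/alpha(-) orthosteric interfaces of an alpha1beta3 receptor).
#' @param Q positive open/desensitized equilibrium constant; \code{Inf} means
#'   no desensitization.
#' @return An object of class \code{"gating_parameters"}.
#' @examples
#' gating_parameters(L = 1, K_C = 78.5e-6, K_O = 120e-9, Q = 0.146)
#' @export
gating_parameters <- function(L, K_C, K_O, N = 2L, Q = Inf) {
  stopifnot(is.numeric(L), length(L) == 1L,
            is.numeric(K_C), length(K_C) == 1L,
            is.numeric(K_O), length(K_O) == 1L,
            is.numeric(N), length(N) == 1L,
            is.numeric(Q), length(Q) == 1L)
  if (!is.finite(L) || L <= 0) stop("L must be a positive finite number")
  if (!is.finite(K_C) || K_C <= 0 || !is.finite(K_O) || K_O <= 0)
    stop("K_C and K_O must be positive finite concentrations")
  if (K_C <= K_O)
    stop("K_C must exceed K_O: the resting state binds agonist more weakly")
  if (N < 1 || N != round(N)) stop("N must be a positive integer")
  if (is.na(Q) || Q <= 0) stop("Q must be positive (Inf = no desensitization)")
  structure(list(L = L, K_C = K_C, K_O = K_O, N = as.integer(N), Q = Q),
            class = "gating_parameters")
}

#' @export
print.gating_parameters <- function(x, ...) {
  cat("ROD gating parameters\n")
  cat(sprintf("  L   = %g (resting/open)\n", x$L))
  cat(sprintf("  K_C = %g M, K_O = %g M, N = %d\n", x$K_C, x$K_O, x$N))
  cat(sprintf("  Q   = %g (open/desensitized)\n", x$Q))
  invisible(x)
}

#' State occupancy of the ROD model
#'
#' Probabilities of the resting, open and desensitized states. The three
#' entries must sum to one; at steady state the desensitized/open ratio equals
#' \code{1/Q}.
#'
#' @param p_resting,p_open,p_desensitized state probabilities in [0, 1]
#'   summing to 1 (tolerance 1e-9 on construction).
#' @return An object of class \code{"state_occupancy"}: a named numeric vector.
#' @export
state_occupancy <- function(p_resting, p_open, p_desensitized) {
  p <- c(p_resting = p_resting, p_open = p_open,
         p_desensitized = p_desensitized)
  if (any(!is.finite(p)) || any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("state probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    stop(sprintf("state probabilities must sum to 1 (got %.12f)", sum(p)))
  structure(pmin(pmax(p, 0), 1), class = "state_occupancy")
}

#' @export
print.state_occupancy <- function(x, digits = 2, ...) {
  cat("ROD state occupancy\n")
  cat(sprintf("  resting      %.*f\n", digits, x[["p_resting"]]))
  cat(sprintf("  open         %.*f\n", digits, x[["p_open"]]))
  cat(sprintf("  desensitized %.*f\n", digits, x[["p_desensitized"]]))
  invisible(x)
}

#' A measured peak / steady-state response pair
#'
#' @param agonist_concentration agonist concentration (molar); may be NA when
#'   only the open probabilities are used (the occupancy inversion needs no
#'   concentration).
#' @param p_open_peak peak open probability in (0, 1].
#' @param p_open_steady_state steady-state open probability; must not exceed
#'   the peak.
#' @param condition_label free-text condition description.
#' @return An object of class \code{"measured_response"}.
#' @export
measured_response <- function(p_open_peak, p_open_steady_state,
                              agonist_concentration = NA_real_,
                              condition_label = "") {
  if (!is.finite(p_open_peak) || p_open_peak <= 0 || p_open_peak > 1)
    stop("p_open_peak must lie in (0, 1]")
  if (!is.finite(p_open_steady_state) || p_open_steady_state <= 0)
    stop("p_open_steady_state must be positive")
  if (p_open_steady_state > p_open_peak * (1 + 1e-9))
    stop(sprintf(
      "inconsistent measurement: steady-state P_open (%g) exceeds peak P_open (%g)",
      p_open_steady_state, p_open_peak))
  structure(list(agonist_concentration = agonist_concentration,
                 p_open_peak = p_open_peak,
                 p_open_steady_state = min(p_open_steady_state, p_open_peak),
                 condition_label = condition_label),
            class = "measured_response")
}
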