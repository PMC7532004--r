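#' Neurosteroid ligand effect profile
#'
#' Describes a neurosteroid (or analogue) acting through up to three
#' transmembrane binding sites of an alpha1beta3 receptor: the canonical
#' beta3(+)/alpha1(-) intersubunit site and the alpha1 and beta3 intrasubunit
#' sites. Each site has an occupancy constant (the concentration at which the
#' site is half occupied; \code{NA} = the ligand does not bind there) and two
#' multiplicative efficacies applied, when the site is occupied, to the
#' gating constants: \code{l_factor} on L (values < 1 promote channel
#' opening, i.e. activation) and \code{q_factor} on Q (values < 1 promote
#' desensitization). A factor of 1 is neutral; a ligand that binds everywhere
#' with all factors 1 occupies sites without functional effect (a competitive
#' antagonist of other neurosteroids).
#'
#' @param name ligand name.
#' @param sites a named list with entries \code{intersubunit},
#'   \code{alpha_intra}, \code{beta_intra}; each either \code{NULL}/absent
#'   (no binding) or a list with \code{K} (molar occupancy constant),
#'   \code{l_factor} and \code{q_factor}.
#' @return An object of class \code{"ligand_profile"}.
#' @seealso [ligand_profile_preset()] for the built-in ligands.
#' @export
ligand_profile <- function(name, sites) {
  known <- c("intersubunit", "alpha_intra", "beta_intra")
  if (length(setdiff(names(sites), known)))
    stop("unknown site name(s): ",
         paste(setdiff(names(sites), known), collapse = ", "))
  for (s in names(sites)) {
    site <- sites[[s]]
    if (is.null(site)) next
    if (!is.finite(site$K) || site$K <= 0)
      stop(sprintf("site %s: occupancy constant K must be > 0", s))
    site$l_factor <- if (is.null(site$l_factor)) 1 else site$l_factor
    site$q_factor <- if (is.null(site$q_factor)) 1 else site$q_factor
    if (site$l_factor <= 0 || site$q_factor <= 0)
      stop(sprintf("site %s: efficacy factors must be > 0", s))
    sites[[s]] <- site
  }
  structure(list(name = name, sites = sites), class = "ligand_profile")
}

#' @export
print.ligand_profile <- function(x, ...) {
  cat(sprintf("ligand profile: %s\n", x$name))
  for (s in names(x$sites)) {
    site <- x$sites[[s]]
    if (is.null(site)) next
    cat(sprintf("  %-12s K = %.3g M, L-factor %.3g, Q-factor %.3g\n",
                s, site$K, site$l_factor, site$q_factor))
  }
  invisible(x)
}

#' Built-in ligand profiles
#'
#' Parameterized profiles for the four ligands of the three-site,
#' state-dependent scheme:
#' \describe{
#'   \item{3a5aP}{allopregnanolone: binds all three sites; lowers L through
#'     the intersubunit and alpha1 intrasubunit sites (activation) and lowers
#'     Q through the beta3 intrasubunit site (desensitization).}
#'   \item{3b5aP}{epi-allopregnanolone: binds only the two intrasubunit
#'     sites, lowering Q (pure desensitizer / negative modulator). Its
#'     per-site Q-efficacy is calibrated so that 3 uM reproduces the measured
#'     Q -> Q* shift at 1 mM GABA (factor 0.592).}
#'   \item{KK148}{3-diazirinyl analogue: binds all three sites; neutral at
#'     the intersubunit site, lowers Q through both intrasubunit sites.}
#'   \item{KK150}{17-epimer of KK148: binds all three sites with neutral
#'     efficacy everywhere; occupies sites without functional effect.}
#' }
#' Occupancy constants follow the fitted modulation EC50s (0.24-0.25 uM for
#' the 3-OH steroids, ~2.4 uM for the diazirinyl analogues); activation
#' efficacies are qualitative.
#'
#' @param name one of \code{"3a5aP"}, \code{"3b5aP"}, \code{"KK148"},
#'   \code{"KK150"}.
#' @return A [ligand_profile()].
#' @export
ligand_profile_preset <- function(name = c("3a5aP", "3b5aP", "KK148",
                                           "KK150")) {
  name <- match.arg(name)
  switch(name,
    "3a5aP" = ligand_profile("3a5aP", list(
      intersubunit = list(K = 0.24e-6, l_factor = 0.05, q_factor = 1),
      alpha_intra = list(K = 0.24e-6, l_factor = 0.20, q_factor = 1),
      beta_intra = list(K = 2.4e-6, l_factor = 1, q_factor = 0.75))),
    "3b5aP" = ligand_profile("3b5aP", list(
      alpha_intra = list(K = 0.25e-6, l_factor = 1, q_factor = 0.7503),
      beta_intra = list(K = 0.25e-6, l_factor = 1, q_factor = 0.7503))),
    "KK148" = ligand_profile("KK148", list(
      intersubunit = list(K = 2.4e-6, l_factor = 1, q_factor = 1),
      alpha_intra = list(K = 2.4e-6, l_factor = 1, q_factor = 0.70),
      beta_intra = list(K = 2.4e-6, l_factor = 1, q_factor = 0.70))),
    "KK150" = ligand_profile("KK150", list(
      intersubunit = list(K = 2.4e-6, l_factor = 1, q_factor = 1),
      alpha_intra = list(K = 2.4e-6, l_factor = 1, q_factor = 1),
      beta_intra = list(K = 2.4e-6, l_factor = 1, q_factor = 1))))
}

#' Apply a ligand to the gating parameters
#'
#' Computes the gating parameters in the presence of a neurosteroid. Each
#' occupied site scales L and Q by a fractional-occupancy-weighted factor
#' \code{1 + (efficacy - 1) * occ}, with per-site occupancy
#' \code{occ = c / (c + K_site)}; factors combine multiplicatively across
#' sites. At zero ligand, or for a profile that is neutral everywhere, the
#' parameters are returned unchanged.
#'
#' @param params a [gating_parameters()].
#' @param profile a [ligand_profile()].
#' @param ligand_conc ligand concentration, molar, >= 0.
#' @return Modified [gating_parameters()].
#' @export
apply_ligand <- function(params, profile, ligand_conc) {
  stopifnot(inherits(params, "gating_parameters"),
            inherits(profile, "ligand_profile"))
  if (!is.finite(ligand_conc) || ligand_conc < 0)
    stop("ligand concentration must be >= 0")
  l_fac <- 1
  q_fac <- 1
  for (site in profile$sites) {
    if (is.null(site)) next
    occ <- ligand_conc / (ligand_conc + site$K)
    l_fac <- l_fac * (1 + (site$l_factor - 1) * occ)
    q_fac <- q_fac * (1 + (site$q_factor - 1) * occ)
  }
  out <- params
  out$L <- params$L * l_fac
  out$Q <- params$Q * q_fac
  out
}
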