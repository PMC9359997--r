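# Gibbs free-energy feasibility of candidate anaerobic conversions:
# dG = dG0' + R T ln Q over standard transformed formation energies (pH 7)
# and species activities. The shipped constants table is illustrative and
# editable; the module's contract is the calculation.

R_KJ <- 8.314e-3  # kJ/mol/K

#' Standard transformed formation energies
#'
#' Reads a constants table of per-species standard transformed Gibbs
#' energies of formation (kJ/mol, pH 7). The shipped table is an
#' illustrative Alberty-style set at 298.15 K and I = 0; supply your own
#' file for study-specific conditions.
#'
#' @param path TSV file with columns `species`, `dg0_prime`, `note`;
#'   default the table shipped with the package.
#' @return Named numeric vector of formation energies (kJ/mol).
#' @export
gibbs_constants <- function(path = system.file("extdata", "gibbs_dg0f.tsv",
                                               package = "acetotrace")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "dg0_prime") %in% names(tab)))
  stats::setNames(tab$dg0_prime, tab$species)
}

#' Describe a reaction for thermodynamic evaluation
#'
#' @param stoichiometry Named numeric vector, species to signed coefficient
#'   (products positive, substrates negative).
#' @param dg0f Named numeric vector of standard transformed formation
#'   energies (kJ/mol); default the shipped constants table.
#' @param activities Named numeric vector of dimensionless activities
#'   (concentration / 1 M, or partial pressure / 1 bar). Unlisted species
#'   default to 1; water is fixed at activity 1 by convention.
#' @param temperature Kelvin (default 310.15, i.e. 37 C).
#' @return Object of class `"reaction_thermo"`.
#' @examples
#' ethanol_to_acetate <- reaction_thermo(
#'   c(ethanol = -1, h2o = -1, acetate = 1, "h+" = 1, h2 = 2))
#' delta_g(ethanol_to_acetate)
#' @export
reaction_thermo <- function(stoichiometry, dg0f = gibbs_constants(),
                            activities = NULL, temperature = 310.15) {
  if (!is.numeric(stoichiometry) || is.null(names(stoichiometry)))
    stop("stoichiometry must be a named numeric vector")
  missing <- setdiff(names(stoichiometry), names(dg0f))
  if (length(missing))
    stop("no formation energy for species: ", paste(missing, collapse = ", "))
  act <- stats::setNames(rep(1, length(stoichiometry)), names(stoichiometry))
  if (!is.null(activities)) {
    unknown <- setdiff(names(activities), names(stoichiometry))
    if (length(unknown))
      stop("activities given for species not in the reaction: ",
           paste(unknown, collapse = ", "))
    if (any(activities <= 0)) stop("activities must be positive")
    act[names(activities)] <- activities
  }
  if ("h2o" %in% names(act)) act["h2o"] <- 1  # water activity fixed at 1
  if (temperature <= 0) stop("temperature must be positive (K)")
  structure(list(stoichiometry = stoichiometry,
                 dg0f = dg0f[names(stoichiometry)],
                 activities = act, temperature = temperature),
            class = "reaction_thermo")
}

#' @export
print.reaction_thermo <- function(x, ...) {
  st <- x$stoichiometry
  side <- function(sel) paste(
    ifelse(abs(st[sel]) == 1, names(st)[sel],
           paste(abs(st[sel]), names(st)[sel])), collapse = " + ")
  cat(side(st < 0), "->", side(st > 0), "\n")
  cat(sprintf("  T = %.2f K; dG0' = %.2f kJ/mol; dG = %.2f kJ/mol (%s)\n",
              x$temperature, delta_g0_prime(x), delta_g(x), feasibility(x)))
  invisible(x)
}

#' Standard transformed reaction Gibbs energy
#'
#' \eqn{\Delta G^{\circ\prime} = \sum_i \nu_i \Delta_f G^{\circ\prime}_i}.
#'
#' @param rxn A [reaction_thermo()].
#' @return kJ/mol.
#' @export
delta_g0_prime <- function(rxn) {
  stopifnot(inherits(rxn, "reaction_thermo"))
  sum(rxn$stoichiometry * rxn$dg0f)
}

#' Reaction Gibbs energy under given activities
#'
#' \eqn{\Delta G = \Delta G^{\circ\prime} + R T \ln Q} with
#' \eqn{Q = \prod_i a_i^{\nu_i}} and R = 8.314 J/mol/K.
#'
#' @inheritParams delta_g0_prime
#' @return kJ/mol.
#' @export
delta_g <- function(rxn) {
  stopifnot(inherits(rxn, "reaction_thermo"))
  lnQ <- sum(rxn$stoichiometry * log(rxn$activities))
  delta_g0_prime(rxn) + R_KJ * rxn$temperature * lnQ
}

#' Thermodynamic feasibility classification
#'
#' A conversion is `"favorable"` iff \eqn{\Delta G} is strictly below the
#' threshold (default 0); \eqn{\Delta G = 0} is equilibrium, not a driving
#' force, so the boundary classifies as `"unfavorable"`.
#'
#' @inheritParams delta_g0_prime
#' @param threshold kJ/mol (default 0).
#' @return `"favorable"` or `"unfavorable"`.
#' @examples
#' feasibility(reaction_thermo(c(ethanol = -1, h2o = -1, acetate = 1,
#'                               "h+" = 1, h2 = 2)))
#' @export
feasibility <- function(rxn, threshold = 0) {
  if (delta_g(rxn) < threshold) "favorable" else "unfavorable"
}

#' The anoxic ethanol-to-acetate example reaction
#'
#' Ethanol + H2O -> acetate + H+ + 2 H2, the hydrogen-producing anaerobic
#' oxidation whose feasibility depends on hydrogen partial pressure: at 1
#' bar H2 it is endergonic (unfavorable), and accumulating hydrogen only
#' drives it further uphill.
#'
#' @param h2_activity Hydrogen activity (partial pressure / 1 bar).
#' @param temperature Kelvin.
#' @param dg0f Constants table, see [gibbs_constants()].
#' @return A [reaction_thermo()].
#' @export
ethanol_oxidation_example <- function(h2_activity = 1, temperature = 310.15,
                                      dg0f = gibbs_constants()) {
  reaction_thermo(c(ethanol = -1, h2o = -1, acetate = 1, "h+" = 1, h2 = 2),
                  dg0f = dg0f, activities = c(h2 = h2_activity),
                  temperature = temperature)
}
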