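## Gibbs-energy machinery: formation energies at in-situ temperature,
## activity-corrected reaction energies, Heijnen dissipation energies and
## Kleerebezem lambda coupling factors.

#' Thermodynamic conditions
#'
#' Bundles the in-situ conditions under which reaction energies are
#' evaluated: temperature, pressure, salinity (used for the water activity),
#' ionic strength, and the ion-activity model.
#'
#' The default ionic strength is estimated from salinity as `I = 0.0199 * S`
#' (mol kg^-1), the standard seawater approximation (S = 35 gives I = 0.7).
#'
#' @param T_K temperature (K).
#' @param P_bar pressure (bar). Kept for interface completeness: the default
#'   energy model carries no pressure correction (documented approximation).
#' @param S salinity (per mille), used for the water activity
#'   `a_w = 1 - 0.000537 S`.
#' @param ionic_strength mol kg^-1; `NULL` estimates from salinity.
#' @param activity_model one of `"davies"`, `"unit"`, `"bdot"`.
#' @return an object of class `thermo_conditions`.
#' @export
thermo_conditions <- function(T_K, P_bar = 1, S = 35,
                              ionic_strength = NULL,
                              activity_model = c("davies", "unit", "bdot")) {
  activity_model <- match.arg(activity_model)
  if (T_K <= 0) stop("temperature must be positive (K)")
  if (P_bar <= 0) stop("pressure must be positive (bar)")
  if (is.null(ionic_strength)) ionic_strength <- 0.0199 * S
  if (ionic_strength < 0) stop("ionic strength must be >= 0")
  structure(list(T_K = T_K, P_bar = P_bar, S = S,
                 ionic_strength = ionic_strength,
                 activity_model = activity_model),
            class = "thermo_conditions")
}

#' Gibbs energy of formation at in-situ temperature
#'
#' Extrapolates the standard formation energy from the reference temperature
#' (298.15 K) using the Gibbs-Helmholtz relation with the constant-enthalpy
#' (Delta Cp = 0) approximation:
#' `dGf(T) = dGf(T0) * (T/T0) + dHf(T0) * (1 - T/T0)`.
#' Species without a tabulated enthalpy keep their reference-temperature
#' value. Pressure is not corrected by default (deep-sea pressure corrections
#' to reaction energies are small next to the dissipation energies involved
#' and are a documented approximation).
#'
#' @param species character vector of species names.
#' @param cond a [thermo_conditions()].
#' @param registry a [species_registry()].
#' @return numeric vector of formation energies (kJ mol^-1).
#' @export
gibbs_formation <- function(species, cond, registry) {
  stopifnot(inherits(cond, "thermo_conditions"))
  idx <- .reg_lookup(registry, species)
  G0 <- registry$dGf0[idx]
  H0 <- registry$dHf0[idx]
  if (anyNA(G0)) {
    stop("no formation energy tabulated for: ",
         paste(species[is.na(G0)], collapse = ", "))
  }
  tau <- cond$T_K / .const$Tref
  ifelse(is.na(H0), G0, G0 * tau + H0 * (1 - tau))
}

#' Activity set from concentrations
#'
#' Converts concentrations (mol m^-3) to molalities (1 m^3 ~ 1e3 kg solvent),
#' then applies the selected ion-activity model to charged aqueous species.
#' Neutral aqueous species get unit activity coefficients; solids have
#' activity 1; biomass activity is fixed at 1; the water activity follows the
#' salinity-linear form `a_w = 1 - 0.000537 S`.
#'
#' Activity coefficient models (A = 0.509 at 25 degC):
#' \itemize{
#'   \item Davies: `log10 g = -A z^2 (sqrt(I)/(1+sqrt(I)) - 0.3 I)`
#'   \item B-dot: `log10 g = -A z^2 sqrt(I)/(1 + sqrt(I)) + 0.041 I`
#'   \item unit: all coefficients 1 (for activity-independent tests)
#' }
#'
#' @param concentrations named numeric vector, mol m^-3.
#' @param cond a [thermo_conditions()].
#' @param registry a [species_registry()].
#' @return named numeric vector of activities (dimensionless).
#' @export
activity_set <- function(concentrations, cond, registry) {
  stopifnot(inherits(cond, "thermo_conditions"))
  if (any(concentrations < 0)) stop("negative concentration")
  idx <- .reg_lookup(registry, names(concentrations))
  phase <- registry$phase[idx]
  z <- registry$charge[idx]
  m <- concentrations * .MOLALITY_PER_MOLM3
  gamma <- rep(1, length(m))
  I <- cond$ionic_strength
  if (cond$activity_model != "unit" && I > 0) {
    sI <- sqrt(I)
    charged <- phase == "aqueous" & z != 0
    lg <- switch(cond$activity_model,
      davies = -.const$A_DH * z^2 * (sI / (1 + sI) - 0.3 * I),
      bdot   = -.const$A_DH * z^2 * sI / (1 + sI) + 0.041 * I
    )
    gamma[charged] <- 10^lg[charged]
  }
  a <- gamma * m
  a[phase %in% c("solid", "biomass")] <- 1
  aw <- if (cond$activity_model == "unit") 1 else 1 - 0.000537 * cond$S
  a[phase == "liquid"] <- aw
  names(a) <- names(concentrations)
  a
}

#' Reaction Gibbs energy with activity correction
#'
#' Assembles `dG = dG0(T) + R T ln Q` for a signed stoichiometry (products
#' positive). `dG0(T)` is the stoichiometric sum of formation energies at the
#' in-situ temperature; `ln Q` is the activity-weighted sum over the supplied
#' activities. Species absent from `activities` are taken at unit activity.
#'
#' @param stoich named numeric vector of stoichiometric coefficients.
#' @param cond a [thermo_conditions()].
#' @param registry a [species_registry()].
#' @param activities optional named numeric vector of activities.
#' @return energy in kJ per mole of reaction as written (i.e. per mole of the
#'   reference species the stoichiometry is normalized to).
#' @export
reaction_delta_g <- function(stoich, cond, registry, activities = NULL) {
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0) {
    warning("empty stoichiometry; returning 0")
    return(0)
  }
  dG0 <- sum(stoich * gibbs_formation(names(stoich), cond, registry))
  lnQ <- 0
  if (!is.null(activities)) {
    a <- activities[names(stoich)]
    a[is.na(a)] <- 1
    if (any(a <= 0)) stop("non-positive activity")
    lnQ <- sum(stoich * log(a))
  }
  dG0 + .const$R * cond$T_K * lnQ
}

#' Heijnen dissipation energy
#'
#' Empirical correlation for the Gibbs energy dissipated per mole of biomass
#' carbon synthesized, as a function of the carbon chain length `C` and the
#' degree of reduction `gamma` of the carbon source:
#' `200 + 18 (6 - C)^1.8 + exp{[(3.8 - gamma)^2]^0.16 * (3.6 + 0.4 C)}`
#' in kJ (molC biomass)^-1. For acetate (C = 2, gamma = 8) the correlation
#' gives 1477 kJ molC^-1.
#'
#' @param chain_length carbon chain length of the substrate (>= 1).
#' @param degree_reduction degree of reduction of the substrate.
#' @return dissipation energy, kJ (molC biomass)^-1.
#' @export
heijnen_dissipation <- function(chain_length, degree_reduction) {
  if (any(chain_length < 1)) stop("chain length must be >= 1")
  200 + 18 * (6 - chain_length)^1.8 +
    exp(((3.8 - degree_reduction)^2)^0.16 * (3.6 + 0.4 * chain_length))
}

#' Lambda coupling factor
#'
#' Number of catabolic turnovers needed per mole of biomass carbon so that
#' the energy gained by catabolism covers the anabolic energy plus the
#' dissipated energy of growth: `lambda = -(dG_ana + dG_diss)/dG_cat`.
#' Only exergonic catabolisms can fuel growth: a non-negative `dG_cat` flags
#' the guild inactive (`NA` returned; growth is forced to zero downstream).
#' A strongly exergonic anabolism cannot make lambda negative: the value is
#' clamped at zero.
#'
#' @param dG_ana anabolic reaction energy, kJ (molC biomass)^-1.
#' @param dG_cat catabolic reaction energy, kJ (mol donor)^-1.
#' @param dG_diss dissipation energy, kJ (molC biomass)^-1 (> 0).
#' @return mol donor per molC biomass, or `NA` when the catabolism is not
#'   exergonic.
#' @export
lambda_factor <- function(dG_ana, dG_cat, dG_diss) {
  if (any(dG_diss <= 0)) stop("dG_diss must be positive")
  lam <- pmax(0, -(dG_ana + dG_diss) / dG_cat)
  lam[dG_cat >= 0] <- NA_real_
  lam
}
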