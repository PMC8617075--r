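## The 18 metabolic guilds: catabolic reactions normalized to consume exactly
## one electron donor, anabolic reactions normalized to produce exactly one
## C-mole of biomass (CH1.8O0.5N0.2).
##
## Two anabolisms are corrected relative to their commonly printed forms,
## which do not close elementally: the Mn-oxidizer anabolism consumes
## 2.1 Mn2+ (not 1), and the nitritation anabolism gains 0.7 NO2- on the
## product side. Both corrections are covered by tests documenting the
## broken printed forms.

## shared anabolisms
.ana_HS <- c("HS-" = -2.1, "HCO3-" = -1, "NH4+" = -0.2, "H+" = -2.9,
             "S0" = 2.1, "H2O" = 2.5, biomass = 1)
.ana_H2 <- c("H2" = -2.1, "HCO3-" = -1, "NH4+" = -0.2, "H+" = -0.8,
             "H2O" = 2.5, biomass = 1)
.ana_CH4 <- c("CH4" = -0.525, "HCO3-" = -1, "NH4+" = -0.2, "H+" = -0.8,
              "CO2" = 0.525, "H2O" = 1.45, biomass = 1)
.ana_ace <- c(acetate = -0.525, "NH4+" = -0.2, "H+" = -0.275,
              "HCO3-" = 0.05, "H2O" = 0.4, biomass = 1)

.GUILD_TABLE <- list(
  list(name = "sulfide_oxidation", donor = "HS-", trophic = "chemolithoautotroph",
       cat = c("HS-" = -1, O2 = -0.5, "H+" = -1, S0 = 1, H2O = 1),
       ana = .ana_HS),
  list(name = "sulfur_oxidation", donor = "S0", trophic = "chemolithoautotroph",
       cat = c(S0 = -1, O2 = -1.5, H2O = -1, "SO4--" = 1, "H+" = 2),
       ana = c(S0 = -0.7, "HCO3-" = -1, "NH4+" = -0.2, H2O = -0.3,
               "SO4--" = 0.7, "H+" = 0.6, biomass = 1)),
  list(name = "thiosulfate_oxidation", donor = "S2O3--", trophic = "chemolithoautotroph",
       cat = c("S2O3--" = -1, O2 = -2, H2O = -1, "SO4--" = 2, "H+" = 2),
       ana = c("S2O3--" = -0.525, "HCO3-" = -1, "NH4+" = -0.2, H2O = -0.125,
               "SO4--" = 1.05, "H+" = 0.25, biomass = 1)),
  list(name = "methane_oxidation", donor = "CH4", trophic = "chemolithoautotroph",
       cat = c(CH4 = -1, O2 = -2, "HCO3-" = 1, "H+" = 1, H2O = 1),
       ana = .ana_CH4),
  list(name = "knallgas", donor = "H2", trophic = "chemolithoautotroph",
       cat = c(H2 = -1, O2 = -0.5, H2O = 1),
       ana = .ana_H2),
  list(name = "nitritation", donor = "NH4+", trophic = "chemolithoautotroph",
       cat = c("NH4+" = -1, O2 = -1.5, "NO2-" = 1, "H+" = 2, H2O = 1),
       ana = c("NH4+" = -0.9, "HCO3-" = -1, "H+" = 0.6, H2O = 1.1,
               "NO2-" = 0.7, biomass = 1)),
  list(name = "nitratation", donor = "NO2-", trophic = "chemolithoautotroph",
       cat = c("NO2-" = -1, O2 = -0.5, "NO3-" = 1),
       ana = c("NO2-" = -2.1, "HCO3-" = -1, "NH4+" = -0.2, "H+" = -0.8,
               "NO3-" = 2.1, H2O = 0.4, biomass = 1)),
  list(name = "iron_oxidation", donor = "Fe++", trophic = "chemolithoautotroph",
       cat = c("Fe++" = -1, O2 = -0.25, H2O = -1.5, FeOOH = 1, "H+" = 2),
       ana = c("Fe++" = -4.2, "HCO3-" = -1, "NH4+" = -0.2, "H+" = -5,
               "Fe+++" = 4.2, H2O = 2.5, biomass = 1)),
  list(name = "manganese_oxidation", donor = "Mn++", trophic = "chemolithoautotroph",
       cat = c("Mn++" = -1, O2 = -0.5, H2O = -1, MnO2 = 1, "H+" = 2),
       ana = c("Mn++" = -2.1, "HCO3-" = -1, "NH4+" = -0.2, H2O = -1.7,
               MnO2 = 2.1, "H+" = 3.4, biomass = 1)),
  list(name = "sulfide_denitrification", donor = "HS-", trophic = "chemolithoautotroph",
       cat = c("HS-" = -1, "H+" = -1.4, "NO3-" = -0.4, S0 = 1, H2O = 1.2,
               N2 = 0.2),
       ana = .ana_HS),
  list(name = "sulfide_DNRA", donor = "HS-", trophic = "chemolithoautotroph",
       cat = c("HS-" = -1, "H+" = -1.5, "NO3-" = -0.25, S0 = 1, H2O = 0.75,
               "NH4+" = 0.25),
       ana = .ana_HS),
  list(name = "hydrogen_denitrification", donor = "H2", trophic = "chemolithoautotroph",
       cat = c(H2 = -1, "H+" = -0.4, "NO3-" = -0.4, H2O = 1.2, N2 = 0.2),
       ana = .ana_H2),
  list(name = "hydrogen_DNRA", donor = "H2", trophic = "chemolithoautotroph",
       cat = c(H2 = -1, "H+" = -0.5, "NO3-" = -0.25, H2O = 0.75,
               "NH4+" = 0.25),
       ana = .ana_H2),
  list(name = "methanogenesis", donor = "H2", trophic = "chemolithoautotroph",
       cat = c(H2 = -1, "HCO3-" = -0.25, "H+" = -0.25, CH4 = 0.25,
               H2O = 0.75),
       ana = .ana_H2),
  list(name = "sulfate_reduction", donor = "H2", trophic = "chemolithoautotroph",
       cat = c(H2 = -1, "SO4--" = -0.25, "H+" = -0.25, "HS-" = 0.25,
               H2O = 1),
       ana = .ana_H2),
  list(name = "anaerobic_methane_oxidation", donor = "CH4", trophic = "chemolithoautotroph",
       cat = c(CH4 = -1, "SO4--" = -1, "HCO3-" = 1, "HS-" = 1, H2O = 1),
       ana = .ana_CH4),
  list(name = "aerobic_respiration", donor = "acetate", trophic = "chemoorganotroph",
       cat = c(acetate = -1, O2 = -2, "H+" = 1, "HCO3-" = 2),
       ana = .ana_ace),
  list(name = "denitrification", donor = "acetate", trophic = "chemoorganotroph",
       cat = c(acetate = -1, "NO3-" = -1.6, "H+" = -0.6, N2 = 0.8,
               "HCO3-" = 2, H2O = 0.8),
       ana = .ana_ace)
)

#' The 18 metabolic guild definitions
#'
#' Returns the guild set of the community model: for each guild a catabolic
#' stoichiometry (normalized to consume exactly one mole of electron donor),
#' an anabolic stoichiometry (normalized to produce exactly one C-mole of
#' biomass), the electron donor, the trophic class, and the dissipation
#' energy of growth.
#'
#' Dissipation energies default to 3500 kJ molC^-1 for the 16
#' chemolithoautotrophic guilds (average including reverse electron
#' transport) and to the empirical heterotrophic values (539 kJ molC^-1 for
#' aerobic acetate respiration, 557 for acetate denitrification).
#'
#' @param dG_diss_auto dissipation energy for lithoautotrophic guilds
#'   (kJ molC^-1).
#' @param dG_diss_het length-2 vector for the two heterotrophic guilds
#'   (aerobic respiration, denitrification).
#' @param dG_cat0_override optional named numeric vector giving a fixed
#'   standard-state catabolic reaction energy (kJ per mol donor) for
#'   selected guilds (e.g. `c(manganese_oxidation = -68)`); by default all
#'   energies are computed from the species registry.
#' @return list of 18 `guild_definition` objects.
#' @export
guild_definitions <- function(dG_diss_auto = 3500,
                              dG_diss_het = c(539, 557),
                              dG_cat0_override = NULL) {
  g <- .GUILD_TABLE
  het <- 0
  for (i in seq_along(g)) {
    if (g[[i]]$trophic == "chemoorganotroph") {
      het <- het + 1
      g[[i]]$dG_diss <- dG_diss_het[het]
    } else {
      g[[i]]$dG_diss <- dG_diss_auto
    }
    g[[i]]$dG_cat0_override <- NA_real_
    if (!is.null(dG_cat0_override) && g[[i]]$name %in% names(dG_cat0_override)) {
      g[[i]]$dG_cat0_override <- dG_cat0_override[[g[[i]]$name]]
    }
    class(g[[i]]) <- "guild_definition"
  }
  g
}

#' Validate and assemble stoichiometry matrices
#'
#' Builds the anabolic, catabolic and mortality stoichiometry matrices over
#' the full state (chemical species plus one biomass row per guild). Every
#' column is checked for elemental (C,H,O,N,S,Fe,Mn) and charge balance to
#' 1e-6 and for the normalization conventions (catabolic donor coefficient
#' -1, anabolic biomass coefficient +1).
#'
#' The mortality column recycles each C-mole of dead biomass as 40% labile
#' DOC (acetate carbon), 10% refractory DOC and 50% POC, releases biomass
#' nitrogen as NH4+ and closes hydrogen and oxygen on water.
#'
#' @param guilds output of [guild_definitions()].
#' @param registry a [species_registry()].
#' @param recycling carbon fractions of dead biomass routed to labile DOC,
#'   refractory DOC and POC (must sum to 1).
#' @return list with matrices `A_ana`, `A_cat`, `A_death`
#'   (`(n_species + n_guilds) x n_guilds`), the state names, and index
#'   helpers.
#' @export
build_matrices <- function(guilds, registry,
                           recycling = c(DOC_l = 0.4, DOC_r = 0.1, POC = 0.5)) {
  if (abs(sum(recycling) - 1) > 1e-12) stop("recycling fractions must sum to 1")
  species <- setdiff(registry$name, "biomass")
  ng <- length(guilds)
  gnames <- vapply(guilds, function(g) g$name, character(1))
  state <- c(species, paste0("X_", gnames))
  nsp <- length(species)

  place <- function(stoich, gi) {
    col <- numeric(nsp + ng)
    for (nm in names(stoich)) {
      if (nm == "biomass") col[nsp + gi] <- stoich[[nm]]
      else col[match(nm, species)] <- col[match(nm, species)] + stoich[[nm]]
    }
    col
  }

  ## mortality stoichiometry per C-mole of biomass; closure coefficients
  ## follow from the registry compositions (acetate carries 2 C)
  death_stoich <- c(acetate = recycling[["DOC_l"]] / 2,
                    DOC_r = recycling[["DOC_r"]],
                    POC = recycling[["POC"]],
                    "NH4+" = NA, "H2O" = NA, "H+" = NA, biomass = -1)
  ## solve N on NH4+, charge on H+, H on H2O
  comp <- function(nm, el) registry[nm, el]
  known <- death_stoich[!is.na(death_stoich)]
  nres <- -sum(known * vapply(names(known), comp, numeric(1), el = "N"))
  death_stoich[["NH4+"]] <- nres
  known <- death_stoich[!(names(death_stoich) %in% c("H2O", "H+"))]
  zres <- -sum(known * registry[names(known), "charge"])
  death_stoich[["H+"]] <- zres
  known <- death_stoich[names(death_stoich) != "H2O"]
  hres <- -sum(known * vapply(names(known), comp, numeric(1), el = "H"))
  death_stoich[["H2O"]] <- hres / 2

  A_ana <- A_cat <- A_death <- matrix(0, nsp + ng, ng,
                                      dimnames = list(state, gnames))
  for (gi in seq_len(ng)) {
    g <- guilds[[gi]]
    if (abs(g$cat[[g$donor]] + 1) > 1e-12) {
      stop("guild ", g$name, ": catabolic donor coefficient must be -1")
    }
    if (abs(g$ana[["biomass"]] - 1) > 1e-12) {
      stop("guild ", g$name, ": anabolic biomass coefficient must be +1")
    }
    for (kind in c("cat", "ana")) {
      res <- reaction_balance(g[[kind]], registry)
      bad <- names(res)[abs(res) > 1e-6]
      if (length(bad) > 0) {
        stop("guild ", g$name, " ", kind, "abolism unbalanced in: ",
             paste(bad, collapse = ", "))
      }
    }
    A_cat[, gi] <- place(g$cat, gi)
    A_ana[, gi] <- place(g$ana, gi)
    A_death[, gi] <- place(death_stoich, gi)
    res <- reaction_balance(death_stoich, registry)
    if (any(abs(res) > 1e-6)) {
      stop("mortality closure unbalanced in: ",
           paste(names(res)[abs(res) > 1e-6], collapse = ", "))
    }
  }
  list(A_ana = A_ana, A_cat = A_cat, A_death = A_death,
       state = state, species = species, n_species = nsp, n_guilds = ng,
       guild_names = gnames,
       organo = vapply(guilds, function(g) g$trophic == "chemoorganotroph",
                       logical(1)))
}
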