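## Species registry: thermodynamic constants and elemental composition for
## every chemical species the model can reference.

.ELEMENTS <- c("C", "H", "O", "N", "S", "Fe", "Mn")

#' Load a species registry
#'
#' Reads the table of chemical species used throughout the model: name, phase,
#' charge, elemental composition over C/H/O/N/S/Fe/Mn, and standard Gibbs
#' energy and enthalpy of formation at 25 degC, 1 bar (kJ mol^-1, aqueous
#' standard state for dissolved species). The package ships a default table
#' covering the 23 species of the community model plus the C-normalized
#' biomass molecule (CH1.8O0.5N0.2); users may supply a replacement table with
#' the same columns.
#'
#' The inert detrital pools (`DOC_r`, `POC`) carry a nominal composition used
#' only for elemental bookkeeping and have no formation energies (`NA`): they
#' never enter an energy calculation.
#'
#' @param path path to a CSV replacement table; `NULL` loads the embedded
#'   default.
#' @return a `data.frame` of class `species_registry`, one row per species.
#' @export
species_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_registry.csv", package = "plumeMTS")
  }
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "phase", "charge", .ELEMENTS, "dGf0", "dHf0")
  missing <- setdiff(needed, names(reg))
  if (length(missing) > 0) {
    stop("species registry is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(reg$name)) {
    stop("species registry names must be unique")
  }
  if (any(reg[, .ELEMENTS] < 0, na.rm = TRUE)) {
    stop("composition counts must be >= 0")
  }
  if (!all(reg$phase %in% c("aqueous", "solid", "liquid", "gas", "biomass"))) {
    stop("unknown phase in registry")
  }
  rownames(reg) <- reg$name
  class(reg) <- c("species_registry", "data.frame")
  reg
}

#' @keywords internal
.reg_lookup <- function(registry, species) {
  idx <- match(species, registry$name)
  if (anyNA(idx)) {
    stop("unknown species: ", paste(species[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Elemental and charge balance of a reaction
#'
#' Computes, for a signed stoichiometry (products positive, reactants
#' negative), the residual of every element and of charge. A balanced
#' reaction has all residuals equal to zero.
#'
#' @param stoich named numeric vector of stoichiometric coefficients.
#' @param registry a [species_registry()].
#' @return named numeric vector of residuals over C,H,O,N,S,Fe,Mn and charge.
#' @export
reaction_balance <- function(stoich, registry) {
  idx <- .reg_lookup(registry, names(stoich))
  comp <- as.matrix(registry[idx, .ELEMENTS, drop = FALSE])
  res <- drop(stoich %*% comp)
  c(res, charge = sum(stoich * registry$charge[idx]))
}
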