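## Synthetic vent sites: literature-plausible stand-ins for a per-site table
## of end-member chemistry and hydrodynamic source terms, so the whole
## pipeline is testable without any external download. Also the
## literature-override procedure for NBP substrate concentrations.

#' Deep-seawater background composition
#'
#' Fixed oxic deep-Atlantic-like background entrained into the plume:
#' oxygenated, nitrate-replete, with all hydrothermally sourced reduced
#' species at zero. The bulk refractory DOC pool carries ~40 uM-C while the
#' labile pool (acetate-carbon) is 0.1 uM-C — deep-ocean DOC is dominated by
#' refractory material, and the labile acetate pool that feeds
#' chemoorganotrophs sits at the nanomolar level that sustains the few
#' 1e-3 ugC L^-1 d^-1 of heterotrophic production observed in bathypelagic
#' water. The listed subset is not a full seawater speciation, so its charge
#' does not balance; activities, not charge closure, are what the model
#' consumes. Deterministic (no RNG).
#'
#' @return list: `conc` (named vector, mol m^-3; acetate in mol acetate,
#'   i.e. 2 C per mole), `T_C`, `S`, `rho` (potential density at 0 bar).
#' @export
seawater_background <- function() {
  conc <- c(
    "O2" = 0.25, "H+" = 1e-5, "H2O" = 55300,
    "HS-" = 0, "S0" = 0, "S2O3--" = 0, "SO4--" = 28,
    "CH4" = 0, "H2" = 0, "CO2" = 0.01, "HCO3-" = 2.2,
    "NH4+" = 5e-5, "NO2-" = 1e-5, "NO3-" = 0.021, "N2" = 0.59,
    "Fe++" = 0, "Fe+++" = 0, "FeOOH" = 0, "Mn++" = 0, "MnO2" = 0,
    "acetate" = 5e-5, "DOC_r" = 0.04, "POC" = 0.001
  )
  list(conc = conc, T_C = 2.5, S = 35,
       rho = seawater_density(2.5, 35))
}

#' Synthetic site template
#'
#' Min/max ranges for every sampled field of a black-smoker-type vent.
#' Ranges are literature-plausible stand-ins for real per-site compilations
#' (end-member temperatures of 300-400 degC, decimetre-scale orifices,
#' mol m^-3-level reduced chemistry), not values from any specific site.
#'
#' @param regime spreading regime label (metadata only).
#' @return object of class `site_template`: named list of `c(min, max)`
#'   ranges; concentration fields are sampled log-uniformly.
#' @export
site_template <- function(regime = c("slow", "intermediate", "fast")) {
  regime <- match.arg(regime)
  tpl <- list(
    T0_C = c(300, 400), u0 = c(0.1, 2), vent_diameter_m = c(0.05, 0.3),
    depth_m = c(1500, 4000), S0 = c(30, 42),
    N2_strat = c(1e-7, 1e-6),          # ambient stratification, s^-2
    "HS-" = c(1, 12), "H2" = c(0.01, 16), "CH4" = c(0.01, 2.5),
    "Fe++" = c(0.005, 25), "Mn++" = c(0.05, 2.5), "HCO3-" = c(2, 10),
    "NH4+" = c(0.001, 0.1), "acetate" = c(0.025, 0.25), "H+" = c(0.03, 1)
  )
  bad <- vapply(tpl, function(r) r[1] > r[2] || any(r <= 0), logical(1))
  if (any(bad)) stop("invalid template range: ", names(tpl)[bad][1])
  structure(c(tpl, list(regime = regime)), class = "site_template")
}

.LOG_FIELDS <- c("HS-", "H2", "CH4", "Fe++", "Mn++", "NH4+", "acetate",
                 "H+", "N2_strat")

#' Generate one synthetic vent site
#'
#' Draws every field of the template: uniformly for physical source terms,
#' log-uniformly for concentration-like fields spanning a decade or more.
#' Reproducible under a fixed seed (the caller's RNG state is preserved).
#'
#' @param template a [site_template()].
#' @param seed integer RNG seed.
#' @param name site name.
#' @return list of class `vent_site`: `name`, `source` ([vent_source()]),
#'   `ambient` ([ambient_column()]), `endmember` (named vector, mol m^-3),
#'   `T0_C`, `S0`.
#' @export
generate_site <- function(template, seed, name = paste0("site", seed)) {
  stopifnot(inherits(template, "site_template"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  draw <- function(nm) {
    r <- template[[nm]]
    if (nm %in% .LOG_FIELDS) exp(stats::runif(1, log(r[1]), log(r[2])))
    else stats::runif(1, r[1], r[2])
  }
  fields <- setdiff(names(template), "regime")
  v <- setNames(vapply(fields, draw, numeric(1)), fields)

  sw <- seawater_background()
  rho_site <- sw$rho
  dz_ref <- 500
  rho_ref <- rho_site - v[["N2_strat"]] * rho_site * dz_ref / .const$g
  conc_fields <- setdiff(.LOG_FIELDS, "N2_strat")
  endmember <- v[c(conc_fields, "HCO3-")]
  structure(list(
    name = name,
    source = vent_source(T0_C = v[["T0_C"]], S0 = v[["S0"]], u0 = v[["u0"]],
                         r0 = v[["vent_diameter_m"]] / 2,
                         depth = v[["depth_m"]]),
    ambient = ambient_column(rho_site, rho_ref, dz_ref,
                             T_sw = sw$T_C, S_sw = sw$S),
    endmember = endmember, T0_C = v[["T0_C"]], S0 = v[["S0"]]
  ), class = "vent_site")
}

#' Generate a site table
#'
#' @param n number of sites.
#' @param template a [site_template()].
#' @param seed base seed; site i uses `seed + i - 1`.
#' @return data.frame in the site-table CSV layout (one row per vent:
#'   physical columns, then one column per end-member species).
#' @export
generate_site_table <- function(n, template = site_template(), seed = 1) {
  rows <- lapply(seq_len(n), function(i) {
    s <- generate_site(template, seed + i - 1)
    .site_to_row(s)
  })
  do.call(rbind, rows)
}

#' @keywords internal
.site_to_row <- function(s) {
  phys <- data.frame(
    name = s$name, T0_C = s$source$T0_C, S0_psu = s$source$S0,
    u0_m_s = s$source$u0, vent_diameter_m = 2 * s$source$r0,
    depth_m = s$source$depth, rho_site = s$ambient$rho_site,
    rho_ref = s$ambient$rho_ref, dz_ref = s$ambient$dz_ref,
    stringsAsFactors = FALSE
  )
  chem <- as.data.frame(as.list(s$endmember), check.names = FALSE,
                        optional = TRUE)
  cbind(phys, chem)
}

#' Write / read a site table
#'
#' @param sites data.frame from [generate_site_table()] (or a list of
#'   `vent_site` objects).
#' @param path CSV path.
#' @return `read_site_table` returns a list of `vent_site` objects.
#' @export
write_site_table <- function(sites, path) {
  if (!is.data.frame(sites)) {
    sites <- do.call(rbind, lapply(sites, .site_to_row))
  }
  utils::write.csv(sites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  phys <- c("name", "T0_C", "S0_psu", "u0_m_s", "vent_diameter_m", "depth_m",
            "rho_site", "rho_ref", "dz_ref")
  missing <- setdiff(phys, names(df))
  if (length(missing) > 0) {
    stop("site table missing columns: ", paste(missing, collapse = ", "))
  }
  chem_cols <- setdiff(names(df), phys)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    structure(list(
      name = r$name,
      source = vent_source(r$T0_C, r$S0_psu, r$u0_m_s,
                           r$vent_diameter_m / 2, r$depth_m),
      ambient = ambient_column(r$rho_site, r$rho_ref, r$dz_ref),
      endmember = setNames(as.numeric(r[chem_cols]), chem_cols),
      T0_C = r$T0_C, S0 = r$S0_psu
    ), class = "vent_site")
  })
}

#' Override NBP substrate concentrations
#'
#' Replaces dilution-predicted non-buoyant-plume concentrations of selected
#' species with literature values (the procedure used to bound the error of
#' ignoring abiotic reactions in the rising plume: methane, hydrogen,
#' dissolved iron and manganese, total sulfide, ammonia, nitrate, nitrite
#' are the species typically overridden). The applied deltas are recorded
#' as an attribute.
#'
#' @param nbp named concentration vector (mol m^-3).
#' @param overrides named vector of replacement values; all names must
#'   exist in `nbp`.
#' @return updated vector with attribute `delta` (override minus previous).
#' @export
apply_overrides <- function(nbp, overrides) {
  if (length(overrides) == 0) {
    attr(nbp, "delta") <- setNames(numeric(0), character(0))
    return(nbp)
  }
  unknown <- setdiff(names(overrides), names(nbp))
  if (length(unknown) > 0) {
    stop("override of unknown species: ", paste(unknown, collapse = ", "))
  }
  delta <- overrides - nbp[names(overrides)]
  nbp[names(overrides)] <- overrides
  attr(nbp, "delta") <- delta
  nbp
}
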