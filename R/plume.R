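## 1-D Morton-Turner buoyant plume solver: neutral-buoyant-plume height,
## dilution factor, rise time, and in-plume T/S conditions.

#' Vent source description
#'
#' @param T0_C fluid exit temperature (degC).
#' @param S0 fluid salinity (per mille).
#' @param u0 exit velocity (m s^-1), > 0.
#' @param r0 vent radius (m), > 0.
#' @param depth depth below surface (m), > 0.
#' @return object of class `vent_source`.
#' @export
vent_source <- function(T0_C, S0, u0, r0, depth) {
  if (u0 <= 0) stop("exit velocity must be > 0")
  if (r0 <= 0) stop("vent radius must be > 0")
  if (depth <= 0) stop("depth must be > 0")
  structure(list(T0_C = T0_C, S0 = S0, u0 = u0, r0 = r0, depth = depth),
            class = "vent_source")
}

#' Ambient water column
#'
#' Describes the stratified ambient: density at the vent depth, a reference
#' density above the non-buoyant plume, their vertical separation, and the
#' ambient temperature and salinity entrained into the plume.
#'
#' @param rho_site ambient density at vent depth (kg m^-3).
#' @param rho_ref reference density above the NBP (kg m^-3), `<= rho_site`
#'   (stable stratification).
#' @param dz_ref vertical separation of the two densities (m), > 0.
#' @param T_sw,S_sw ambient temperature (degC) and salinity (per mille).
#' @return object of class `ambient_column`.
#' @export
ambient_column <- function(rho_site, rho_ref, dz_ref, T_sw = 2.5, S_sw = 35) {
  if (dz_ref <= 0) stop("dz_ref must be > 0")
  if (rho_site < rho_ref) stop("unstable stratification: rho_site < rho_ref")
  structure(list(rho_site = rho_site, rho_ref = rho_ref, dz_ref = dz_ref,
                 T_sw = T_sw, S_sw = S_sw),
            class = "ambient_column")
}

#' Brunt-Vaisala (stratification) frequency squared
#'
#' `N^2 = (g / rho_ref) * (rho_site - rho_ref) / dz_ref` (s^-2).
#'
#' @param col an [ambient_column()].
#' @return N^2 in s^-2 (>= 0).
#' @export
buoyancy_frequency <- function(col) {
  stopifnot(inherits(col, "ambient_column"))
  .const$g / col$rho_ref * (col$rho_site - col$rho_ref) / col$dz_ref
}

#' Froude-dependent entrainment coefficient
#'
#' Interpolates between the pure-jet (`alpha_j`) and pure-plume (`alpha_p`)
#' entrainment regimes: `alpha_e = alpha_j - (alpha_j - alpha_p) (Fr_p/Fr)^2`.
#' The caller substitutes `alpha_p` when the Froude number is undefined
#' (zero or negative buoyancy); values are clamped to the
#' `[alpha_j, alpha_p]` range.
#'
#' @param Fr local Froude number (non-zero).
#' @param alpha_j jet entrainment coefficient.
#' @param alpha_p plume entrainment coefficient.
#' @param Fr_p Froude number of a pure plume.
#' @return entrainment coefficient (dimensionless).
#' @export
entrainment_coefficient <- function(Fr, alpha_j = 0.08, alpha_p = 0.16,
                                    Fr_p = 1.6) {
  if (any(Fr == 0)) stop("Fr = 0: pure-plume regime, use alpha_p")
  a <- alpha_j - (alpha_j - alpha_p) * (Fr_p / Fr)^2
  pmin(pmax(a, min(alpha_j, alpha_p)), max(alpha_j, alpha_p))
}

## Flux-form right-hand side. State: q = u r^2 (specific volume flux),
## m = u^2 r^2 (specific momentum flux), F = g (rho_a - rho)/rho_ref q
## (specific buoyancy flux), tt = rise time, phiT/phiS = excess scalar fluxes.
.plume_rhs <- function(z, y, p) {
  q <- y[1]; m <- y[2]; F <- y[3]
  u <- m / q
  r <- q / sqrt(m)
  gp <- F / q
  if (gp > 0) {
    Fr <- u / sqrt(gp * r)
    a <- entrainment_coefficient(Fr, p$alpha_j, p$alpha_p, p$Fr_p)
  } else {
    a <- p$alpha_p
  }
  if (u > p$env$umax) p$env$umax <- u
  list(c(2 * a * sqrt(m),      # dq/dz = 2 r u_e
         F * q / m,            # dm/dz = g' r^2
         -p$N2 * q,            # deficit flux changes only by stratification
         q / m,                # dt/dz = 1/u
         0, 0))                # excess T and S fluxes are conserved
}

#' Integrate a rising buoyant plume
#'
#' Solves the Morton-Turner conservation equations for volume, momentum and
#' density-deficit flux of a steady top-hat plume rising through a linearly
#' stratified ambient built from `col` (the uniform case is recovered when
#' `N^2 = 0`). Temperature and salinity mix conservatively with dilution.
#' Integration terminates at the neutral-buoyant level, detected as the
#' first height where the plume is negatively buoyant and the vertical
#' velocity has fallen below 1% of its running maximum.
#'
#' @param src a [vent_source()].
#' @param col an [ambient_column()].
#' @param n_cells number of output grid cells (default 300).
#' @param alpha_j,alpha_p,Fr_p entrainment parameters, see
#'   [entrainment_coefficient()].
#' @param rtol relative tolerance of the adaptive integration.
#' @param z_top optional integration ceiling (m); required when the ambient
#'   is unstratified (no neutral level exists), otherwise defaults to the
#'   water depth.
#' @return object of class `plume_profile`: a data.frame with columns
#'   `z, r, u, rho, T, S, dilution, Fr, alpha_e` over `n_cells` grid cells,
#'   with attributes `nbp_height` (m), `nbp_dilution` (volume-flux ratio),
#'   `rise_time` (s) and `F0` (source buoyancy flux, m^4 s^-3,
#'   volume-flux convention i.e. including the pi r^2 factor).
#' @export
integrate_plume <- function(src, col, n_cells = 300,
                            alpha_j = 0.08, alpha_p = 0.16, Fr_p = 1.6,
                            rtol = 1e-8, z_top = NULL) {
  stopifnot(inherits(src, "vent_source"), inherits(col, "ambient_column"))
  N2 <- buoyancy_frequency(col)
  rho_fluid <- seawater_density(src$T0_C, src$S0)
  q0 <- src$u0 * src$r0^2
  m0 <- src$u0^2 * src$r0^2
  F0 <- .const$g * (col$rho_site - rho_fluid) / col$rho_ref * q0

  if (F0 <= 0 && src$u0 < 1e-12) {
    return(.no_plume_profile(src, col, n_cells))
  }

  env <- new.env(); env$umax <- src$u0
  p <- list(alpha_j = alpha_j, alpha_p = alpha_p, Fr_p = Fr_p, N2 = N2,
            env = env)
  y0 <- c(q = q0, m = m0, F = F0, tt = 0,
          phiT = (src$T0_C - col$T_sw) * q0, phiS = (src$S0 - col$S_sw) * q0)

  if (is.null(z_top)) z_top <- src$depth
  stratified <- N2 > 0
  if (!stratified && is.null(z_top)) {
    stop("unstratified ambient: supply z_top (no neutral level exists)")
  }

  rootfun <- function(z, y, p) {
    u <- y[2] / y[1]
    if (y[3] < 0) u - 0.01 * p$env$umax else 1
  }
  zs <- seq(0, z_top, length.out = max(2000, n_cells))
  sol <- deSolve::lsoda(y0, zs, .plume_rhs, p, rtol = rtol, atol = 1e-12,
                        rootfunc = if (stratified) rootfun else NULL,
                        events = if (stratified) list(root = TRUE) else NULL)
  if (attr(sol, "istate")[1] < 0) {
    stop("plume solver failed to converge; last state at z = ",
         signif(max(sol[, 1]), 4), " m")
  }
  z_stop <- max(sol[, 1])

  ## second pass: clean output grid up to the termination height
  zg <- seq(0, z_stop, length.out = n_cells)
  env$umax <- src$u0
  sol <- deSolve::lsoda(y0, zg, .plume_rhs, p, rtol = rtol, atol = 1e-12)
  q <- sol[, "q"]; m <- sol[, "m"]; F <- sol[, "F"]
  u <- m / q
  r <- q / sqrt(m)
  rho_a <- col$rho_site - (col$rho_site - col$rho_ref) / col$dz_ref * zg
  rho <- rho_a - F * col$rho_ref / (.const$g * q)
  gp <- F / q
  Fr <- ifelse(gp > 0, u / sqrt(pmax(gp, 0) * r + (gp <= 0)), 0)
  ae <- ifelse(gp > 0,
               entrainment_coefficient(pmax(Fr, 1e-12), alpha_j, alpha_p, Fr_p),
               alpha_p)
  prof <- data.frame(
    z = zg, r = r, u = u, rho = rho,
    T = col$T_sw + sol[, "phiT"] / q,
    S = col$S_sw + sol[, "phiS"] / q,
    dilution = q / q0, Fr = Fr, alpha_e = ae
  )
  structure(prof,
            class = c("plume_profile", "data.frame"),
            nbp_height = z_stop,
            nbp_dilution = q[n_cells] / q0,
            rise_time = sol[n_cells, "tt"],
            F0 = pi * F0)
}

#' @keywords internal
.no_plume_profile <- function(src, col, n_cells) {
  prof <- data.frame(z = rep(0, n_cells), r = src$r0, u = 0,
                     rho = seawater_density(src$T0_C, src$S0),
                     T = src$T0_C, S = src$S0, dilution = 1, Fr = 0,
                     alpha_e = NA_real_)
  structure(prof, class = c("plume_profile", "data.frame"),
            nbp_height = 0, nbp_dilution = 1, rise_time = 0, F0 = 0)
}

#' Conservative dilution of end-member fluid with seawater
#'
#' `C_nbp = (C_f + (D - 1) C_sw) / D` per species; the same rule applies to
#' temperature and salinity. When hydrodynamic inputs are missing the
#' fallback dilution factor is 1e5.
#'
#' @param endmember named concentration vector (mol m^-3).
#' @param seawater named concentration vector (mol m^-3).
#' @param D dilution factor (>= 1), default 1e5.
#' @return named concentration vector over the union of species.
#' @export
dilute_endmember <- function(endmember, seawater, D = 1e5) {
  if (D < 1) stop("dilution factor must be >= 1")
  sp <- union(names(endmember), names(seawater))
  cf <- endmember[sp]; cf[is.na(cf)] <- 0
  cs <- seawater[sp];  cs[is.na(cs)] <- 0
  out <- (cf + (D - 1) * cs) / D
  names(out) <- sp
  out
}
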