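## The 18-guild MTS community ODE system: lambda-coupled overall metabolisms,
## multi-substrate growth law, first-order mortality with detrital recycling,
## stiff time integration and derived production-rate reporters.

#' Community model parameters
#'
#' @param V_harv harvest volume (m^3 per mol biomass), default 1000.
#' @param alpha first-order mortality rate (s^-1), default 1.16e-8.
#' @param recycling carbon fractions of dead biomass to labile DOC,
#'   refractory DOC and POC (sum to 1), default 0.40/0.10/0.50.
#' @param T_K system temperature (K), default 275.65 (2.5 degC deep sea).
#' @param P_bar pressure (bar), interface only (no default pressure
#'   correction to the energies).
#' @param S salinity (per mille), for activities.
#' @param duration simulated time (s), default 30 days.
#' @param initial_cells initial cell density (cells ml^-1), default 1e5.
#' @param cell_carbon carbon quota per cell (gC cell^-1), default 2e-14
#'   (20 fgC).
#' @param guild_fractions length-18 vector of the initial biomass split
#'   across guilds (sums to 1), default uniform.
#' @param activity_model activity model passed to the thermodynamics layer.
#' @return object of class `model_params`.
#' @export
model_params <- function(V_harv = 1000, alpha = 1.16e-8,
                         recycling = c(DOC_l = 0.4, DOC_r = 0.1, POC = 0.5),
                         T_K = 275.65, P_bar = 300, S = 35,
                         duration = 30 * 86400,
                         initial_cells = 1e5, cell_carbon = 2e-14,
                         guild_fractions = rep(1 / 18, 18),
                         activity_model = "davies") {
  if (abs(sum(recycling) - 1) > 1e-12) stop("recycling fractions must sum to 1")
  if (abs(sum(guild_fractions) - 1) > 1e-9) stop("guild fractions must sum to 1")
  if (any(c(V_harv, alpha, T_K, P_bar, duration, initial_cells,
            cell_carbon) <= 0)) {
    stop("all scalar parameters must be positive")
  }
  structure(list(V_harv = V_harv, alpha = alpha, recycling = recycling,
                 T_K = T_K, P_bar = P_bar, S = S, duration = duration,
                 initial_cells = initial_cells, cell_carbon = cell_carbon,
                 guild_fractions = guild_fractions,
                 activity_model = activity_model),
            class = "model_params")
}

#' Maximum specific growth rate
#'
#' MTS theory sets the ceiling of the growth rate at the universal attempt
#' frequency `mu_max = kB T / hP` (s^-1).
#'
#' @param T_K temperature (K).
#' @return s^-1.
#' @export
mu_max <- function(T_K) {
  if (any(T_K <= 0)) stop("temperature must be positive")
  .const$kB * T_K / .const$hP
}

#' Initial community state
#'
#' Builds the full state vector: chemical species concentrations (species
#' missing from `concentrations` start at zero) followed by the 18 guild
#' biomasses, which distribute `initial_cells x cell_carbon` according to
#' `guild_fractions`.
#'
#' @param concentrations named vector (mol m^-3) of chemical species.
#' @param params a [model_params()].
#' @param matrices output of [build_matrices()].
#' @return named state vector (mol m^-3 / molC m^-3).
#' @export
initial_community_state <- function(concentrations, params, matrices) {
  y <- setNames(numeric(length(matrices$state)), matrices$state)
  unknown <- setdiff(names(concentrations), matrices$species)
  if (length(unknown) > 0) {
    stop("unknown species in initial concentrations: ",
         paste(unknown, collapse = ", "))
  }
  y[names(concentrations)] <- concentrations
  if (any(y < 0)) stop("negative initial concentration")
  ## cells ml^-1 -> cells m^-3 (x1e6), x gC/cell, / gC per molC
  Xtot <- params$initial_cells * 1e6 * params$cell_carbon / .const$MC
  y[matrices$n_species + seq_len(matrices$n_guilds)] <-
    Xtot * params$guild_fractions
  y
}

## Precompute everything constant over one simulation: T-corrected standard
## reaction energies, activity scale factors, index masks.
#' @keywords internal
.community_setup <- function(guilds, registry, params, matrices = NULL) {
  if (is.null(matrices)) matrices <- build_matrices(guilds, registry)
  cond <- thermo_conditions(params$T_K, params$P_bar, params$S,
                            activity_model = params$activity_model)
  nsp <- matrices$n_species; ng <- matrices$n_guilds
  ## per-state formation energies at T (0 for the inert pools, which never
  ## carry a non-zero coefficient in an energetic reaction)
  dGf_sp <- rep(0, nsp)
  has_G <- !is.na(registry[matrices$species, "dGf0"])
  dGf_sp[has_G] <- gibbs_formation(matrices$species[has_G], cond, registry)
  dGf_bio <- gibbs_formation("biomass", cond, registry)
  dGf_state <- c(dGf_sp, rep(dGf_bio, ng))

  dG0_cat <- drop(crossprod(matrices$A_cat, dGf_state))
  dG0_ana <- drop(crossprod(matrices$A_ana, dGf_state))
  for (gi in seq_len(ng)) {
    ov <- guilds[[gi]]$dG_cat0_override
    if (!is.na(ov)) dG0_cat[gi] <- ov
  }

  ## activity machinery: a_i = act_scale_i * C_i for free aqueous species,
  ## fixed activity for solids/water/biomass
  unit <- activity_set(setNames(rep(1e3, nsp), matrices$species), cond, registry)
  phase <- registry[matrices$species, "phase"]
  fixed <- phase %in% c("solid", "liquid", "biomass")
  act_scale <- unit / 1e3          # gamma * molality factor per mol m^-3
  act_fixed_val <- unit            # valid where fixed (conc-independent)

  excl <- matrices$species %in% c("H2O", "H+")
  list(matrices = matrices, cond = cond, params = params,
       dG0_cat = dG0_cat, dG0_ana = dG0_ana,
       dG_diss = vapply(guilds, function(g) g$dG_diss, numeric(1)),
       act_scale = act_scale, act_fixed = fixed, act_fixed_val = act_fixed_val,
       growth_excl = c(excl, rep(TRUE, ng)),   # biomass rows never limit
       mumax = mu_max(params$T_K), RT = .const$R * params$T_K,
       nsp = nsp, ng = ng)
}

#' @keywords internal
.state_activities <- function(setup, Csp) {
  a <- setup$act_scale * pmax(Csp, 0)
  a[setup$act_fixed] <- setup$act_fixed_val[setup$act_fixed]
  a
}

#' Assemble the lambda-coupled community metabolism
#'
#' For the current concentrations, computes activity-corrected catabolic and
#' anabolic reaction energies per guild, the lambda coupling factors, and
#' the overall metabolism matrix `A_met = A_ana + A_cat diag(lambda)`.
#' Guilds whose catabolism is not exergonic are flagged inactive (their
#' growth rate is forced to zero by the growth law).
#'
#' @param guilds output of [guild_definitions()].
#' @param C named state vector (or species concentrations, mol m^-3).
#' @param params a [model_params()].
#' @param registry a [species_registry()].
#' @return list with `A_met`, `lambda`, `dG_cat`, `dG_ana`, `active`.
#' @export
assemble_metabolism <- function(guilds, C, params, registry) {
  setup <- .community_setup(guilds, registry, params)
  y <- setNames(numeric(setup$nsp + setup$ng),
                setup$matrices$state)
  y[intersect(names(C), names(y))] <- C[intersect(names(C), names(y))]
  .assemble(setup, y)
}

#' @keywords internal
.assemble <- function(setup, y) {
  m <- setup$matrices
  a <- .state_activities(setup, y[seq_len(setup$nsp)])
  ln_a <- c(log(pmax(a, 1e-30)), rep(0, setup$ng))  # biomass activity 1
  dG_cat <- setup$dG0_cat + setup$RT * drop(crossprod(m$A_cat, ln_a))
  dG_ana <- setup$dG0_ana + setup$RT * drop(crossprod(m$A_ana, ln_a))
  lambda <- lambda_factor(dG_ana, dG_cat, setup$dG_diss)
  names(lambda) <- names(dG_cat)
  active <- !is.na(lambda)
  lam0 <- ifelse(active, lambda, 0)
  A_met <- m$A_ana + m$A_cat %*% diag(lam0, setup$ng)
  dimnames(A_met) <- dimnames(m$A_ana)
  list(A_met = A_met, lambda = lambda, dG_cat = dG_cat, dG_ana = dG_ana,
       active = active)
}

#' Multi-substrate MTS growth rate
#'
#' `mu = mu_max(T) * prod_i exp(A_met,i / (V_harv [S_i]))` over the consumed
#' species i (negative metabolic coefficient), excluding water and protons
#' whose bulk concentrations carry no information about substrate scarcity.
#' Any consumed substrate at zero concentration forces `mu = 0`.
#'
#' @param A_met_col named numeric vector: one guild's column of the overall
#'   metabolism matrix.
#' @param C named concentration vector (mol m^-3).
#' @param params a [model_params()].
#' @return growth rate (s^-1), in `[0, mu_max]`.
#' @export
growth_rate <- function(A_met_col, C, params) {
  keep <- !(names(A_met_col) %in% c("H2O", "H+")) &
    !startsWith(names(A_met_col), "X_") & names(A_met_col) != "biomass"
  v <- A_met_col[keep & A_met_col < 0]
  if (length(v) == 0) return(mu_max(params$T_K))
  conc <- C[names(v)]
  conc[is.na(conc)] <- 0
  if (any(conc <= 0)) return(0)
  mu_max(params$T_K) * exp(sum(v / (params$V_harv * conc)))
}

#' @keywords internal
.growth_vec <- function(setup, y, A_met, active) {
  W <- A_met[!setup$growth_excl, , drop = FALSE]
  Cv <- pmax(y[!setup$growth_excl][seq_len(nrow(W))], 0)
  neg <- W < 0
  terms <- matrix(0, nrow(W), ncol(W))
  if (any(neg)) {
    cc <- matrix(Cv, nrow(W), ncol(W))
    terms[neg] <- W[neg] / (setup$params$V_harv * cc[neg])  # -Inf at C = 0
  }
  expo <- colSums(terms)
  mu <- setup$mumax * exp(expo)
  mu[!active | !is.finite(mu)] <- 0
  mu[is.nan(expo)] <- 0
  mu
}

#' Community derivative
#'
#' Right-hand side of the balance equation
#' `dC/dt = A_met R_met + A_death R_death`, with `R_met = diag(mu) X` and
#' `R_death = alpha X`. Exposed mainly for diagnostics; [simulate_community()]
#' drives it.
#'
#' @param state named state vector.
#' @param params a [model_params()].
#' @param guilds output of [guild_definitions()].
#' @param registry a [species_registry()].
#' @return named vector dC/dt.
#' @export
community_derivative <- function(state, params, guilds, registry) {
  setup <- .community_setup(guilds, registry, params)
  drop(.rhs(0, state, setup)[[1]])
}

#' @keywords internal
.rhs <- function(t, y, setup) {
  m <- setup$matrices
  asm <- .assemble(setup, y)
  X <- pmax(y[setup$nsp + seq_len(setup$ng)], 0)
  mu <- .growth_vec(setup, y, asm$A_met, asm$active)
  dy <- drop(asm$A_met %*% (mu * X) + m$A_death %*% (setup$params$alpha * X))
  if (any(!is.finite(dy))) {
    bad <- which(!is.finite(asm$A_met %*% (mu * X)))
    stop("non-finite rate; first offending state: ",
         m$state[bad[1]])
  }
  list(dy)
}

#' Simulate the plume microbial community
#'
#' Integrates the stiff 18-guild ODE system over the residence time of the
#' community. The lambda coupling factors and activities are recomputed at
#' every solver step. Concentrations are floored at zero when evaluating
#' rates; the integrator itself runs unclipped at tight tolerance so the
#' excursions stay within the absolute tolerance.
#'
#' @param initial named state vector from [initial_community_state()].
#' @param params a [model_params()].
#' @param guilds output of [guild_definitions()].
#' @param registry a [species_registry()].
#' @param times output times (s); default 301 evenly spaced points over
#'   `params$duration`.
#' @param method deSolve integrator, default `"lsoda"`.
#' @param rtol,atol integration tolerances.
#' @return object of class `community_trajectory`: data.frame with `time`
#'   and one column per state, carrying the setup as an attribute.
#' @export
simulate_community <- function(initial, params, guilds, registry,
                               times = NULL, method = "lsoda",
                               rtol = 1e-8, atol = 1e-15) {
  setup <- .community_setup(guilds, registry, params)
  if (is.null(times)) times <- seq(0, params$duration, length.out = 301)
  sol <- deSolve::ode(initial, times, .rhs, setup, method = method,
                      rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) {
    stop("community solver failed at t = ", signif(max(sol[, 1]), 4),
         " s; last valid state retained in the partial output")
  }
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  structure(out, class = c("community_trajectory", "data.frame"),
            setup = setup)
}

#' @keywords internal
.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Production rates from a trajectory
#'
#' Reports prokaryotic heterotrophic production (PHP) as the time-averaged
#' gross anabolic carbon flux into the two chemoorganotrophic guilds, net
#' and gross chemolithoautotrophic production, and per-guild catabolic
#' substrate-consumption (activity) rates.
#'
#' Gross production per guild is recovered from the biomass trajectory as
#' `X(T) - X(0) + alpha * int X dt` (growth minus mortality inverted), which
#' is robust to the sharp initial consumption transient that point-sampled
#' rate evaluations would miss.
#'
#' @param traj a `community_trajectory`.
#' @return list: `php_ugC_L_d`, `autotrophic_net_ugC_L_d`,
#'   `autotrophic_gross_ugC_L_d`, and `guild_rates` (data.frame with gross
#'   production in ugC L^-1 d^-1 and donor consumption in nmol m^-3 d^-1).
#' @export
production_rates <- function(traj) {
  setup <- attr(traj, "setup")
  if (is.null(setup)) stop("trajectory lacks its model setup attribute")
  m <- setup$matrices
  tt <- traj$time
  Tdur <- max(tt) - min(tt)
  if (Tdur <= 0) stop("trajectory must span positive time")
  X <- as.matrix(traj[, paste0("X_", m$guild_names), drop = FALSE])
  gross <- numeric(setup$ng)
  for (g in seq_len(setup$ng)) {
    gross[g] <- X[nrow(X), g] - X[1, g] +
      setup$params$alpha * .trapz(tt, X[, g])
  }
  gross_flux <- gross / Tdur                    # molC m^-3 s^-1, time-avg
  php <- sum(gross_flux[m$organo]) * .MOLC_S_TO_UGC_L_D
  auto_net <- sum(X[nrow(X), !m$organo] - X[1, !m$organo]) / Tdur *
    .MOLC_S_TO_UGC_L_D
  auto_gross <- sum(gross_flux[!m$organo]) * .MOLC_S_TO_UGC_L_D

  ## mean lambda over saved states for donor-consumption reporting
  lam <- matrix(NA_real_, nrow(X), setup$ng)
  for (i in seq_len(nrow(X))) {
    y <- as.numeric(traj[i, -1]); names(y) <- m$state
    lam[i, ] <- .assemble(setup, y)$lambda
  }
  lam_bar <- colMeans(lam, na.rm = TRUE)
  lam_bar[is.nan(lam_bar)] <- 0
  ana_donor <- vapply(seq_len(setup$ng), function(g) {
    don <- match(.donor_of(setup, g), m$species)
    abs(m$A_ana[don, g])
  }, numeric(1))
  donor_rate <- (lam_bar + ana_donor) * gross_flux * 1e9 * 86400
  list(php_ugC_L_d = php,
       autotrophic_net_ugC_L_d = auto_net,
       autotrophic_gross_ugC_L_d = auto_gross,
       guild_rates = data.frame(
         guild = m$guild_names,
         gross_ugC_L_d = gross_flux * .MOLC_S_TO_UGC_L_D,
         donor_nmol_m3_d = donor_rate
       ))
}

#' @keywords internal
.donor_of <- function(setup, g) {
  ## donor = species with catabolic coefficient -1
  sp <- setup$matrices$species
  col <- setup$matrices$A_cat[seq_len(setup$nsp), g]
  sp[which.min(abs(col + 1))]
}

#' Parameter sensitivity sweep
#'
#' Re-runs the community simulation over a grid of single-parameter
#' perturbations and reports the percentage change of PHP and of total gross
#' production relative to the base run.
#'
#' @param initial named state vector.
#' @param params base [model_params()].
#' @param guilds,registry model components.
#' @param ranges named list of numeric vectors: parameters to sweep
#'   (elements of `model_params`, e.g. `list(V_harv = c(1000, 5000, 10000))`).
#' @param times optional output times passed through.
#' @return data.frame: parameter, value, php_ugC_L_d, pct_change_php,
#'   total_gross_ugC_L_d, pct_change_total.
#' @export
sensitivity_sweep <- function(initial, params, guilds, registry, ranges,
                              times = NULL) {
  run1 <- function(p) {
    tr <- simulate_community(initial, p, guilds, registry, times = times)
    pr <- production_rates(tr)
    c(php = pr$php_ugC_L_d, total = sum(pr$guild_rates$gross_ugC_L_d))
  }
  base <- run1(params)
  rows <- list()
  for (nm in names(ranges)) {
    for (v in ranges[[nm]]) {
      p <- params
      p[[nm]] <- v
      r <- run1(p)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = nm, value = v,
        php_ugC_L_d = r[["php"]],
        pct_change_php = 100 * (r[["php"]] - base[["php"]]) /
          max(base[["php"]], .Machine$double.xmin),
        total_gross_ugC_L_d = r[["total"]],
        pct_change_total = 100 * (r[["total"]] - base[["total"]]) /
          max(base[["total"]], .Machine$double.xmin))
    }
  }
  do.call(rbind, rows)
}
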