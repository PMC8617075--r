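test_that("stoichiometry matrices are normalized and balance to 1e-6", {
  ## Knallgas catabolic column exactly as tabulated
  kn <- MATS$A_cat[, "knallgas"]
  expect_equal(unname(kn[c("H2", "O2", "H2O")]), c(-1, -0.5, 1))
  expect_true(all(kn[setdiff(names(kn), c("H2", "O2", "H2O"))] == 0))
  ## every anabolic column produces exactly one biomass C-mole
  bio_rows <- MATS$n_species + seq_len(MATS$n_guilds)
  expect_equal(unname(diag(MATS$A_ana[bio_rows, ])), rep(1, 18))
  ## every catabolic column consumes exactly one donor
  for (gi in seq_along(GUILDS)) {
    expect_equal(unname(MATS$A_cat[GUILDS[[gi]]$donor, gi]), -1)
  }
  ## independent element/charge oracle over all three matrices
  for (A in list(MATS$A_ana, MATS$A_cat, MATS$A_death)) {
    expect_lt(max(abs(balance_residuals(A, REG, MATS))), 1e-6)
  }
})

test_that("the printed Mn-oxidizer and nitritation anabolisms do not close", {
  g <- guild_definitions()
  g_mn <- g
  g_mn[[9]]$ana["Mn++"] <- -1   # printed coefficient
  expect_error(build_matrices(g_mn, REG), "manganese_oxidation")
  g_ni <- g
  g_ni[[6]]$ana <- g_ni[[6]]$ana[names(g_ni[[6]]$ana) != "NO2-"]  # printed form
  expect_error(build_matrices(g_ni, REG), "nitritation")
  ## corrected forms pass (already exercised by the fixture build)
  expect_silent(build_matrices(g, REG))
})

test_that("mu_max is the thermal attempt frequency", {
  expect_equal(mu_max(298.15), 1.380649e-23 * 298.15 / 6.62607015e-34)
  expect_equal(mu_max(298.15), 6.21e12, tolerance = 1e-3)
  expect_equal(mu_max(275.15), 5.73e12, tolerance = 1e-3)
  expect_equal(mu_max(2 * 300), 2 * mu_max(300))
  expect_error(mu_max(-1), "positive")
})

test_that("the multi-substrate growth law is bounded and monotone", {
  p <- model_params()
  ## saturating substrates recover mu_max
  col <- c(acetate = -1, "O2" = -2, "X_test" = 1)
  expect_equal(growth_rate(col, c(acetate = 1e12, "O2" = 1e12), p),
               mu_max(p$T_K), tolerance = 1e-9)
  ## single substrate at 1/(V_harv) mol m^-3 gives mu_max / e
  expect_equal(growth_rate(c(acetate = -1), c(acetate = 1e-3), p),
               mu_max(p$T_K) * exp(-1))
  ## a missing substrate shuts growth down
  expect_equal(growth_rate(col, c(acetate = 0, "O2" = 0.25), p), 0)
  ## water and protons never limit
  expect_equal(growth_rate(c("H2O" = -2.5, "H+" = -0.8, acetate = -1),
                           c(acetate = 1e12, H2O = 0, "H+" = 0), p),
               mu_max(p$T_K), tolerance = 1e-9)
  ## monotone in every consumed substrate and in V_harv; always in [0, mu_max]
  set.seed(7)
  for (i in 1:25) {
    conc <- c(acetate = 10^runif(1, -6, 0), "O2" = 10^runif(1, -6, 0))
    mu <- growth_rate(col, conc, p)
    expect_gte(mu, 0); expect_lte(mu, mu_max(p$T_K))
    up <- conc * c(2, 1)
    expect_gte(growth_rate(col, up, p), mu)
    p2 <- p; p2$V_harv <- p$V_harv * 3
    expect_gte(growth_rate(col, conc, p2), mu)
  }
})

test_that("metabolism assembly couples anabolism and catabolism via lambda", {
  p <- model_params()
  sw <- seawater_background()
  asm <- assemble_metabolism(GUILDS, sw$conc, p, REG)
  lam <- ifelse(is.na(asm$lambda), 0, asm$lambda)
  recomposed <- MATS$A_ana + MATS$A_cat %*% diag(lam, 18)
  expect_equal(unname(asm$A_met), unname(recomposed), tolerance = 1e-12)
  ## oxic, H2-free water: methanogenesis cannot be exergonic
  expect_false(asm$active[["methanogenesis"]])
  expect_true(is.na(asm$lambda[["methanogenesis"]]))
  ## heterotrophs are active and their lambda is positive and finite
  expect_true(asm$active[["aerobic_respiration"]])
  expect_gt(asm$lambda[["aerobic_respiration"]], 0)
  expect_lt(asm$lambda[["aerobic_respiration"]], 5)
  ## lambda = 0 collapses A_met onto the anabolism
  one <- assemble_metabolism(GUILDS, sw$conc, p, REG)
  i <- which(one$lambda == 0)
  if (length(i) > 0) {
    expect_equal(one$A_met[, i[1]], MATS$A_ana[, i[1]])
  }
})

test_that("biomass-free and mortality-only dynamics are analytic", {
  p <- model_params(duration = 5 * 86400)
  ## no biomass anywhere: the state is a fixed point
  y0 <- initial_community_state(seawater_background()$conc,
                                model_params(initial_cells = 1e-30), MATS)
  dy <- community_derivative(y0, p, GUILDS, REG)
  expect_true(all(abs(dy) < 1e-25))
  ## substrate-free water: every guild is lambda-inactive, pure mortality
  y0 <- initial_community_state(c(H2O = 55300, "H+" = 1e-5), p, MATS)
  tr <- simulate_community(y0, p, GUILDS, REG,
                           times = seq(0, p$duration, length.out = 51))
  X0 <- y0[MATS$n_species + 1]
  tt <- tr$time
  for (g in c(1, 9, 18)) {
    expect_equal(tr[[paste0("X_", MATS$guild_names[g])]],
                 unname(X0) * exp(-p$alpha * tt), tolerance = 1e-8)
  }
  ## detrital pools gain exactly the lost carbon, split 40/10/50
  lost <- 18 * unname(X0) * (1 - exp(-p$alpha * max(tt)))
  expect_equal(2 * (tr$acetate[51] - tr$acetate[1]), 0.4 * lost,
               tolerance = 1e-6)
  expect_equal(tr$DOC_r[51] - tr$DOC_r[1], 0.1 * lost, tolerance = 1e-6)
  expect_equal(tr$POC[51] - tr$POC[1], 0.5 * lost, tolerance = 1e-6)
})

test_that("a lone heterotroph on constant substrate grows exponentially", {
  ## substrate pool huge relative to biomass: mu is effectively frozen and
  ## X(t) = X0 exp((mu - alpha) t) must hold to 0.1% over 5 days
  p <- model_params(duration = 5 * 86400,
                    guild_fractions = c(rep(0, 16), 1, 0),
                    initial_cells = 1e-3)  # X0 ~ 1.7e-12 molC m^-3
  conc <- c("O2" = 0.25, acetate = 3e-5, "NH4+" = 5e-3,
            "HCO3-" = 2.2, H2O = 55300, "H+" = 1e-5)
  y0 <- initial_community_state(conc, p, MATS)
  asm <- assemble_metabolism(GUILDS, conc, p, REG)
  mu0 <- growth_rate(asm$A_met[, "aerobic_respiration"], conc, p)
  expect_gt(mu0, 0)
  tr <- simulate_community(y0, p, GUILDS, REG,
                           times = seq(0, p$duration, length.out = 21))
  X <- tr$X_aerobic_respiration
  expect_equal(X, X[1] * exp((mu0 - p$alpha) * tr$time), tolerance = 1e-3)
})

test_that("the closed system conserves carbon through a 30-day run", {
  p <- model_params()
  sites <- fixture_sites()
  nbp <- dilute_endmember(sites[[1]]$endmember, seawater_background()$conc,
                          5e4)
  y0 <- initial_community_state(nbp, p, MATS)
  tr <- simulate_community(y0, p, GUILDS, REG)
  ct <- carbon_total(tr, REG, MATS)
  ## relative drift under 1e-6 per simulated day (30 days here)
  expect_lt(max(abs(ct - ct[1])) / ct[1], 30 * 1e-6)
  ## no state goes meaningfully negative
  expect_gt(min(as.matrix(tr[, -1])), -1e-12)
  ## tolerance convergence: a coarser solve agrees on the final state
  tr2 <- simulate_community(y0, p, GUILDS, REG, rtol = 1e-6, atol = 1e-13)
  f1 <- as.numeric(tr[nrow(tr), -1]); f2 <- as.numeric(tr2[nrow(tr2), -1])
  expect_lt(max(abs(f1 - f2) / (abs(f1) + 1e-10)), 1e-4)
})

test_that("production reporting converts gross anabolic flux correctly", {
  ## fabricated linear biomass ramp: flux 1e-8 molC m^-3 s^-1 with no
  ## mortality must report 10.378 ugC L^-1 d^-1
  p <- model_params(alpha = 1e-300)
  setup <- plumeMTS:::.community_setup(GUILDS, REG, p)
  Tdur <- 86400
  traj <- as.data.frame(matrix(0, 2, 1 + length(MATS$state),
                               dimnames = list(NULL, c("time", MATS$state))))
  traj$time <- c(0, Tdur)
  traj$X_aerobic_respiration <- c(0, 1e-8 * Tdur)
  attr(traj, "setup") <- setup
  class(traj) <- c("community_trajectory", "data.frame")
  pr <- production_rates(traj)
  expect_equal(pr$php_ugC_L_d, 10.378, tolerance = 1e-4)
  ## a heterotroph-free trajectory reports zero PHP
  traj$X_aerobic_respiration <- 0
  expect_equal(production_rates(traj)$php_ugC_L_d, 0)
})

test_that("sensitivity: V_harv dominates, inert parameters do nothing", {
  p <- model_params(duration = 2 * 86400)
  nbp <- dilute_endmember(fixture_sites()[[1]]$endmember,
                          seawater_background()$conc, 5e4)
  y0 <- initial_community_state(nbp, p, MATS)
  times <- seq(0, p$duration, length.out = 25)
  sw <- sensitivity_sweep(y0, p, GUILDS, REG,
                          ranges = list(P_bar = c(100, 500),
                                        V_harv = c(2000, 10000)),
                          times = times)
  ## pressure carries no energy correction by default: zero deviation
  expect_equal(sw$pct_change_php[sw$parameter == "P_bar"], c(0, 0),
               tolerance = 1e-9)
  ## larger harvest volumes increase production, and by far more than the
  ## inert sweeps
  vh <- sw[sw$parameter == "V_harv", ]
  expect_true(all(vh$pct_change_php >= 0))
  expect_gt(max(abs(vh$pct_change_php)),
            max(abs(sw$pct_change_php[sw$parameter == "P_bar"])))
})
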