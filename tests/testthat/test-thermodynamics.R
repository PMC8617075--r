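test_that("formation energies follow the Gibbs-Helmholtz correction", {
  cond25 <- thermo_conditions(298.15, activity_model = "unit")
  expect_equal(gibbs_formation("H2O", cond25, REG), -237.18)
  ## reference-state species stay at zero at the reference temperature
  expect_equal(gibbs_formation("S0", cond25, REG), 0)
  expect_equal(gibbs_formation("H+", cond25, REG), 0)
  ## dG(T) = dG0 * T/T0 + dH0 * (1 - T/T0): at T = 2 T0 this is 2 dG0 - dH0
  f <- tempfile(fileext = ".csv")
  writeLines(c("name,phase,charge,C,H,O,N,S,Fe,Mn,dGf0,dHf0",
               "X,aqueous,0,0,0,0,0,1,0,0,-100,-120"), f)
  toy <- species_registry(f)
  expect_equal(gibbs_formation("X", thermo_conditions(2 * 298.15), toy), -80)
  expect_error(thermo_conditions(-3), "positive")
  expect_error(gibbs_formation("nosuch", cond25, REG), "unknown species")
})

test_that("reaction energies equal the stoichiometric sum at unit activities", {
  toy <- toy_registry()
  cond <- thermo_conditions(298.15, activity_model = "unit")
  ## Knallgas with gaseous reference convention
  knall <- c(H2 = -1, O2 = -0.5, H2O = 1)
  expect_equal(reaction_delta_g(knall, cond, toy), -237.1)
  ## independent dot-product oracle over random stoichiometries
  set.seed(42)
  for (i in 1:20) {
    sp <- sample(REG$name[!is.na(REG$dGf0)], 4)
    nu <- setNames(round(runif(4, -2, 2), 2), sp)
    oracle <- sum(nu * REG[sp, "dGf0"])
    expect_equal(reaction_delta_g(nu, cond, REG), oracle, tolerance = 1e-12)
    ## a reaction plus its exact reverse sums to zero
    expect_equal(reaction_delta_g(nu, cond, REG) +
                   reaction_delta_g(-nu, cond, REG), 0, tolerance = 1e-9)
  }
  expect_warning(z <- reaction_delta_g(numeric(0), cond, REG), "empty")
  expect_equal(z, 0)
  ## activity correction: RT ln Q term with explicit activities
  a <- c(H2 = 0.1, O2 = 1, H2O = 1)
  lnQ <- 1 * log(1) - 1 * log(0.1) - 0.5 * log(1)
  expect_equal(reaction_delta_g(knall, cond, toy, activities = a),
               -237.1 + 8.314462618e-3 * 298.15 * lnQ)
  expect_error(reaction_delta_g(knall, cond, toy, activities = c(H2 = -1)),
               "non-positive")
})

test_that("activity sets follow the Davies model and phase conventions", {
  ## infinite-dilution limit: all coefficients 1, water activity 1
  cond0 <- thermo_conditions(275.65, S = 0, ionic_strength = 0)
  a <- activity_set(c("Na+" = 1e3, H2O = 1e3, solidX = 5), cond0,
                    toy_registry())
  expect_equal(unname(a[["Na+"]]), 1)      # 1e3 mol m^-3 = 1 molal
  expect_equal(unname(a[["H2O"]]), 1)
  expect_equal(unname(a[["solidX"]]), 1)
  ## Davies closed form at seawater ionic strength, |z| = 1
  cond <- thermo_conditions(275.65, S = 35, ionic_strength = 0.7)
  a <- activity_set(c("Na+" = 1e3, solidX = 1e-9), cond, toy_registry())
  g_hand <- 10^(-0.509 * (sqrt(0.7) / (1 + sqrt(0.7)) - 0.3 * 0.7))
  expect_equal(unname(a[["Na+"]]), g_hand)
  ## solids at activity 1 regardless of amount
  expect_equal(unname(a[["solidX"]]), 1)
  ## water activity from salinity
  aw <- activity_set(c(H2O = 55300), cond, toy_registry())
  expect_equal(unname(aw[["H2O"]]), 1 - 0.000537 * 35)
  expect_error(activity_set(c("Na+" = -1), cond, toy_registry()), "negative")
})

test_that("Heijnen dissipation reproduces published values and is smooth", {
  expect_equal(round(heijnen_dissipation(2, 8)), 1477)
  ## both correction terms vanish for a 6-C substrate at gamma = 3.8
  expect_equal(heijnen_dissipation(6, 3.8), 201)
  ## glucose-like substrate (C = 6, gamma = 4)
  expect_equal(heijnen_dissipation(6, 4), 236.05, tolerance = 1e-4)
  ## continuity (grid refinement shrinks increments) and the >= 200 floor
  for (gam in c(0.5, 2, 3.8, 4.5, 8)) {
    v1 <- heijnen_dissipation(seq(1, 6, by = 0.02), gam)
    v2 <- heijnen_dissipation(seq(1, 6, by = 0.01), gam)
    expect_true(all(v1 >= 200))
    expect_lt(max(abs(diff(v2))), 0.7 * max(abs(diff(v1))))
  }
  expect_error(heijnen_dissipation(0.5, 4), ">= 1")
})

test_that("lambda coupling clamps, deactivates and scales correctly", {
  expect_equal(lambda_factor(-500, -60, 500), 0)   # numerator vanishes
  expect_equal(lambda_factor(100, -60, 500), 10)
  ## endergonic catabolism flags the guild inactive
  expect_true(is.na(lambda_factor(100, 5, 500)))
  expect_true(is.na(lambda_factor(100, 0, 500)))
  ## strongly exergonic anabolism cannot drive lambda negative
  expect_equal(lambda_factor(-900, -60, 500), 0)
  expect_error(lambda_factor(0, -1, -5), "positive")
  ## monotone non-increasing in |dG_cat|
  cats <- -seq(10, 500, by = 10)
  lam <- lambda_factor(100, cats, 500)
  expect_true(all(diff(lam[order(abs(cats))]) <= 0))
})
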