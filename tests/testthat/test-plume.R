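test_that("seawater density matches EOS-80 reference values and is monotone", {
  expect_gt(seawater_density(2, 35, 0), 1027)
  expect_lt(seawater_density(2, 35, 0), 1028.2)
  ## UNESCO check values
  expect_equal(seawater_density(5, 35, 0), 1027.675, tolerance = 1e-5)
  expect_equal(seawater_density(25, 35, 1000), 1062.538, tolerance = 1e-5)
  ## monotone: decreasing in T (above the density maximum), increasing in S
  Ts <- seq(2, 40, by = 1)
  expect_true(all(diff(seawater_density(Ts, 35)) < 0))
  Ss <- seq(0, 45, by = 1)
  expect_true(all(diff(seawater_density(10, Ss)) > 0))
  ## linear extrapolation stays monotone through the hot regime
  expect_true(all(diff(seawater_density(seq(30, 400, 10), 35)) < 0))
  ## identical states give zero density difference (g' = 0)
  expect_identical(seawater_density(2.5, 35), seawater_density(2.5, 35))
  expect_error(seawater_density(500, 35), "out of range")
  expect_error(seawater_density(10, 60), "out of range")
})

test_that("stratification frequency is the density-gradient form", {
  expect_equal(buoyancy_frequency(ambient_column(1040, 1040, 500)), 0)
  N2 <- buoyancy_frequency(ambient_column(1041.5, 1041.0, 500))
  expect_equal(N2, 9.81 / 1041 * 0.5 / 500, tolerance = 1e-12)
  expect_equal(N2, 9.42e-6, tolerance = 1e-3)
  ## doubling the separation halves N^2
  expect_equal(buoyancy_frequency(ambient_column(1041.5, 1041.0, 1000)),
               N2 / 2)
  expect_error(ambient_column(1040, 1041, 500), "unstable")
  expect_error(ambient_column(1041, 1040, -5), "dz_ref")
})

test_that("entrainment coefficient interpolates between jet and plume", {
  expect_equal(entrainment_coefficient(1.6), 0.16)       # Fr = Fr_p
  expect_equal(entrainment_coefficient(1e9), 0.08, tolerance = 1e-12)
  expect_equal(entrainment_coefficient(sqrt(2) * 1.6), (0.08 + 0.16) / 2)
  expect_error(entrainment_coefficient(0), "Fr")
})

test_that("pure plume in uniform ambient follows the similarity solution", {
  src <- vent_source(T0_C = 20, S0 = 35, u0 = 0.05, r0 = 0.05, depth = 5000)
  col <- ambient_column(1027, 1027, dz_ref = 500, T_sw = 2.5, S_sw = 35)
  alpha <- 0.12
  pl <- integrate_plume(src, col, alpha_j = alpha, alpha_p = alpha,
                        z_top = 60)
  far <- pl$z > 20  # well beyond 10 source radii
  ## radius spread: r(z) = (6 alpha / 5) z
  expect_true(all(abs(pl$r[far] / pl$z[far] - 6 * alpha / 5) <
                    0.05 * 6 * alpha / 5))
  ## far-field velocity decays as z^(-1/3)
  ex <- coef(lm(log(pl$u[far]) ~ log(pl$z[far])))[2]
  expect_equal(unname(ex), -1 / 3, tolerance = 0.05)
  ## density-deficit flux is conserved when the ambient is uniform
  q <- pl$u * pl$r^2
  F <- 9.81 * (1027 - pl$rho) / 1027 * q
  expect_lt(max(abs(F - F[1])) / F[1], 1e-6)
  ## entrainment only adds fluid
  expect_true(all(diff(q) > 0))
})

test_that("stratified rise height matches the classical maximum-rise formula", {
  s <- fixture_sites()[[1]]
  pl <- integrate_plume(s$source, s$ambient)
  N2 <- buoyancy_frequency(s$ambient)
  z_oracle <- 3.76 * attr(pl, "F0")^0.25 * N2^(-3 / 8)
  expect_lt(abs(attr(pl, "nbp_height") - z_oracle) / z_oracle, 0.15)
  ## plume summary invariants
  expect_true(all(diff(pl$dilution) >= 0))
  expect_equal(pl$dilution[1], 1)
  expect_gt(attr(pl, "nbp_dilution"), 1e3)
  expect_lt(attr(pl, "nbp_dilution"), 1e6)
  ## rise time for a black-smoker fixture lands in the 1-3 h range
  expect_gt(attr(pl, "rise_time"), 3600)
  expect_lt(attr(pl, "rise_time"), 3 * 3600)
})

test_that("degenerate sources yield the no-plume result", {
  ## a fluid at ambient density with (numerically) no exit momentum
  src <- vent_source(2.5, 35, u0 = 1e-13, r0 = 0.1, depth = 3000)
  col <- ambient_column(seawater_density(2.5, 35), seawater_density(2.5, 35) - 0.01,
                        500, T_sw = 2.5, S_sw = 35)
  pl <- integrate_plume(src, col)
  expect_equal(attr(pl, "nbp_height"), 0)
  expect_equal(attr(pl, "nbp_dilution"), 1)
})

test_that("conservative dilution mixes end-member and seawater", {
  em <- c(H2 = 10, CH4 = 2)
  sw <- c(CH4 = 0.001, "O2" = 0.25)
  expect_equal(dilute_endmember(em, sw, 1),
               c(H2 = 10, CH4 = 2, "O2" = 0))
  ## 1e5-fold dilution of a pure end-member species
  expect_equal(unname(dilute_endmember(c(H2 = 10), c(H2 = 0), 1e5)[["H2"]]),
               1e-4)
  ## seawater composition is the fixed point of mixing
  expect_equal(unname(dilute_endmember(c("O2" = 0), c("O2" = 0.25), 777)[["O2"]]),
               0.25 * (777 - 1) / 777 + 0)
  mixed <- dilute_endmember(em, sw, 50)
  for (sp in names(mixed)) {
    lo <- min(c(em[sp], 0, sw[sp]), na.rm = TRUE)
    hi <- max(c(em[sp], 0, sw[sp]), na.rm = TRUE)
    expect_gte(mixed[[sp]], lo); expect_lte(mixed[[sp]], hi)
  }
  expect_error(dilute_endmember(em, sw, 0.5), ">= 1")
})
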