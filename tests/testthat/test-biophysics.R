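test_that("hydraulic conductivity follows the Arrhenius law", {
  expect_equal(hydraulic_conductivity(hep, hep$T_R), hep$Lpg)
  expect_lt(hydraulic_conductivity(hep, 263.15), hep$Lpg)
  # direct scalar arithmetic oracle at 263.15 K
  oracle <- 1.5e-12 * exp(-(3.42e5 / 8.314) * (1 / 263.15 - 1 / 273.15))
  expect_equal(hydraulic_conductivity(hep, 263.15), oracle)
  Ts <- seq(240, 280, by = 5)
  expect_true(all(diff(hydraulic_conductivity(hep, Ts)) > 0))
  expect_error(hydraulic_conductivity(hep, -1), "positive")
})

test_that("water viscosity model has unit base at 450 K and diverges toward 225 K", {
  expect_equal(water_viscosity(450), 0.139)
  expect_equal(water_viscosity(273.15), 0.139 * (273.15 / 225 - 1)^(-1.64))
  expect_gt(water_viscosity(260), water_viscosity(280))
  expect_error(water_viscosity(225), "singular")
})

test_that("cytoplasm viscosity reduces to water at zero solids and grows with phi_s", {
  expect_equal(cytoplasm_viscosity(0, 270), water_viscosity(270))
  ratio <- cytoplasm_viscosity(0.51, 270) / water_viscosity(270)
  expect_equal(ratio, exp(2.5 * 0.51 / (1 - 0.609 * 0.51)))
  phis <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(cytoplasm_viscosity(phis, 270)) > 0))
  expect_error(cytoplasm_viscosity(1 / 0.609, 270), "phi_s")
})

test_that("mole fraction of water handles boundary compositions", {
  expect_equal(mole_fraction_water(1, 0), 1)
  expect_equal(mole_fraction_water(98, 1), 0.98)
  expect_equal(mole_fraction_water(0, 1), 0)
  expect_error(mole_fraction_water(-1, 1), "nonnegative")
})

test_that("freezing point depression is anchored at Tf0 and decreases with solute", {
  expect_equal(freezing_point(hep, 1), 272.63)
  expect_lt(freezing_point(hep, 0.98), 272.63)
  oracle <- 1 / (1 / 272.63 - (8.314 / (5.94124e16 * 1.01325e-13)) * log(0.95))
  expect_equal(freezing_point(hep, 0.95), oracle)
  expect_error(freezing_point(hep, 0), "x_w")
  expect_error(freezing_point(hep, 1.1), "x_w")
})

test_that("water transport vanishes at chemical equilibrium and dehydrates a supercooled cell", {
  # equilibrium water volume at T: ln(Vw/(Vw+c)) = (dHf/R)(1/T_R - 1/T)
  T <- 268
  x <- exp((hep$dHf_J / hep$Rgas) * (1 / hep$T_R - 1 / T))
  c0 <- hep$v_w * hep$v_s * hep$n_s
  Vw_eq <- c0 * x / (1 - x)
  expect_equal(water_transport_rhs(hep, hep$V_b + Vw_eq, T, 100), 0,
               tolerance = 1e-10)
  # more water than equilibrium (supercooled interior) -> water leaves:
  # dV/dT > 0 so that V falls as T falls
  expect_gt(water_transport_rhs(hep, hep$V_b + 2 * Vw_eq, T, 100), 0)
  # direct scalar arithmetic oracle for a fixed (V, T, B) triple
  V <- 4000; Tq <- 265; B <- 100
  Lp <- 1.5e-12 * exp(-(3.42e5 / 8.314) * (1 / Tq - 1 / 273.15))
  Vw <- V - 0.51 * hep$V_iso
  brk <- log(Vw / (Vw + c0)) -
    (5.94124e16 * 1.01325e-13 / 8.314) * (1 / 273.15 - 1 / Tq)
  oracle <- Lp * (1.412e3 * 1e-12) * 8.314 * Tq / (1.8e13 * 1e-18) /
    (B / 60) * brk * 1e18
  expect_equal(water_transport_rhs(hep, V, Tq, B), oracle)
  expect_error(water_transport_rhs(hep, hep$V_b, 265, 100), "degenerate")
})

test_that("dehydration trajectories are monotone and bounded", {
  for (B in c(100, 400)) {
    tr <- integrate_dehydration(hep, cooling_protocol(B = B))
    expect_true(all(diff(tr$V) <= 1e-9))          # V nonincreasing in time
    expect_true(all(tr$V >= hep$V_b))
    expect_true(all(diff(tr$x_w) <= 1e-12))
    expect_true(all(diff(tr$Tf) <= 1e-9))
    expect_true(all(diff(tr$tau) >= 0))
  }
})

test_that("moderate cooling dehydrates the cell almost completely", {
  tr <- integrate_dehydration(hep, cooling_protocol(B = 100))
  expect_lt(retained_water_fraction(tr), 0.10)
})

test_that("halving the output step leaves the retained-water fraction unchanged to 0.1 points", {
  t1 <- integrate_dehydration(hep, cooling_protocol(B = 400), dT = 0.05)
  t2 <- integrate_dehydration(hep, cooling_protocol(B = 400), dT = 0.025)
  expect_lt(abs(retained_water_fraction(t1) - retained_water_fraction(t2)),
            0.001)
})

test_that("faster cooling accumulates more nucleation exposure", {
  taus <- vapply(c(100, 200, 400), function(B) {
    tr <- integrate_dehydration(hep, cooling_protocol(B = B))
    tr$tau[nrow(tr)]
  }, numeric(1))
  expect_true(all(diff(1 - exp(-taus)) > 0))
})

test_that("nucleation is off without supercooling and quenched by dehydration", {
  st <- thermo_state(hep, hep$V_iso, 273)   # above the freezing point
  expect_identical(st$Ji, 0)
  st5 <- thermo_state(hep, hep$V_iso, st$Tf - 5)
  # direct arithmetic oracle at 5 K supercooling, fully hydrated
  eta0 <- cytoplasm_viscosity(0.51, 272.63)
  Tq <- st5$Tf - 0  # state's own freezing point
  Tx <- st$Tf - 5
  oracle <- (1.412e3 * 1e-12) * 1.1e10 * (eta0 / st5$eta) *
    sqrt(Tx / 272.63) *
    exp(-1.4e9 / (Tx^3 * (st5$Tf - Tx)^2) * (st5$Tf / 272.63)^4)
  expect_equal(st5$Ji, oracle, tolerance = 1e-12)
  expect_gt(st5$Ji, 0)
  # deep dehydration at the same temperature: huge viscosity, lower Tf
  dry <- thermo_state(hep, hep$V_b + 20, Tx)
  expect_lt(dry$Ji, st5$Ji * 1e-2)
})

test_that("tau is the trapezoidal cumulative integral with exact constant-rate form", {
  expect_equal(tau_of_time(c(0, 1, 2), c(3, 3, 3)), c(0, 3, 6))
  expect_equal(tau_of_time(0:10, rep(0.5, 11))[11], 5)
  expect_equal(tau_of_time(c(0, 2), c(0, 0)), c(0, 0))
  expect_error(tau_of_time(c(0, 0, 1), c(1, 1, 1)), "increasing")
  expect_error(tau_of_time(c(0, 1), c(-1, 1)), "nonnegative")
})

test_that("tau grid refinement is converged for the hepatocyte run", {
  t1 <- integrate_dehydration(hep, cooling_protocol(B = 100), dT = 0.05)
  t2 <- integrate_dehydration(hep, cooling_protocol(B = 100), dT = 0.0125)
  expect_equal(t1$tau[nrow(t1)], t2$tau[nrow(t2)], tolerance = 1e-3)
})

test_that("the tau map inverts by first crossing", {
  tr <- data.frame(t = 0:4, T = 272 - (0:4), tau = c(0, 0, 1, 3, 3))
  m <- tau_map(tr)
  expect_equal(m$t_of_tau(0), 0)
  expect_equal(m$t_of_tau(0.5), 2)    # first grid time with tau >= 0.5
  expect_equal(m$t_of_tau(1), 2)
  expect_equal(m$t_of_tau(2.5), 3)
  expect_true(is.na(m$t_of_tau(3.5)))
  expect_equal(m$T_of_tau(1), 270)
})
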