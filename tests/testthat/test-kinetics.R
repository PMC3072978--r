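test_that("Butler-Volmer current matches direct arithmetic", {
  p <- butler_volmer(i0 = 10, alpha_a = 0.5, alpha_c = 0.5, E_eq = -0.83,
                     T = 298)
  expect_identical(bv_current(0, p), 0)
  z <- 0.5 * 96500 * 0.1 / (8.314 * 298)   # = 1.9477...
  expect_equal(bv_current(0.1, p), 10 * (exp(z) - exp(-z)), tolerance = 1e-14)
  # odd in eta when the transfer coefficients are equal
  etas <- c(0.01, 0.05, 0.2, 0.7)
  expect_equal(bv_current(-etas, p), -bv_current(etas, p))
  # small-eta slope = i0 (alpha_a + alpha_c) F / (R T)
  h <- 1e-7
  slope_fd <- (bv_current(h, p) - bv_current(-h, p)) / (2 * h)
  expect_equal(slope_fd, 10 * (0.5 + 0.5) * 96500 / (8.314 * 298),
               tolerance = 1e-6)
  expect_equal(bv_conductance(0, p), 10 * 96500 / (8.314 * 298))
  # the overflow guard keeps extreme arguments finite
  expect_true(is.finite(bv_current(50, p)) && is.finite(bv_current(-50, p)))
})

test_that("Butler-Volmer inversion round-trips", {
  p_eq <- butler_volmer(1e-8, 1, 1, 1.23)
  for (i in c(-10, -1e-4, 0, 1e-6, 3.7, 2500)) {
    eta <- bv_invert(i, p_eq)
    expect_equal(bv_current(eta, p_eq), i, tolerance = 1e-10)
  }
  # asymmetric coefficients exercise the Newton fallback
  p_as <- butler_volmer(0.5, 0.7, 0.3, 0)
  for (i in c(-2, 0.01, 40)) {
    expect_equal(bv_current(bv_invert(i, p_as), p_as), i,
                 tolerance = 1e-9 * max(abs(i), 1))
  }
})

test_that("packaged platinum/water cell has the documented equilibrium", {
  k <- platinum_water()
  expect_equal(k$E_cell_eq, 2.06)
  expect_equal(k$anode$E_eq, 1.23)
  expect_equal(k$cathode$E_eq, -0.83)
  expect_equal(k$anode$i0, 1e-8)
  expect_equal(k$cathode$i0, 10)
  expect_equal(k$anode$T, 298)
  # overrides flow through
  expect_equal(platinum_water(E_eq_cathode = 0)$E_cell_eq, 1.23)
})

test_that("surface overpotentials close the voltage budget identically", {
  k <- platinum_water()
  # no driving force: all potential differences at equilibrium
  eta <- surface_overpotentials(2.06, 0.83, 0.83, k)
  expect_equal(eta$eta_a, 0)
  expect_equal(eta$eta_c, 0)
  # equal surface potentials: eta_a - eta_c = V_app - E_cell_eq
  eta2 <- surface_overpotentials(2.5, 0.6, 0.6, k)
  expect_equal(eta2$eta_a - eta2$eta_c, 2.5 - 2.06)
  # the decomposition V = E_cell + eta_a - eta_c + ohmic holds for any inputs
  for (v in list(c(2.8, 0.9, 0.4), c(1.5, -0.2, 0.7), c(3.5, 1.2, -0.1))) {
    e <- surface_overpotentials(v[1], v[2], v[3], k)
    expect_equal(k$E_cell_eq + e$eta_a - e$eta_c + (v[2] - v[3]), v[1])
  }
})

test_that("1D facing-electrode cell: equilibrium, monotonicity, Tafel regime", {
  k <- platinum_water()
  # at the cell equilibrium potential there is no current
  s0 <- solve_1d_cell(1e-5, 0.05, 2.06, k)
  expect_true(s0$no_drive)
  expect_identical(s0$i, 0)
  expect_true(solve_1d_cell(1e-5, 0.05, 1.5, k)$no_drive)

  # polarization curve is strictly increasing in V_app
  vs <- seq(2.1, 3.5, by = 0.2)
  is <- vapply(vs, function(v) solve_1d_cell(1e-5, 0.05, v, k)$i, numeric(1))
  expect_true(all(diff(is) > 0))

  # voltage residual closes to the stated tolerance
  s <- solve_1d_cell(1e-5, 0.05, 2.9, k)
  resid <- 2.06 + s$eta_a - s$eta_c + s$ohmic - 2.9
  expect_lt(abs(resid), 1e-10)

  # sluggish anode (i0 = 1e-8 << 10) dominates: at large V_app the anode
  # is deep in its Tafel regime and the Tafel line reproduces eta_a
  s35 <- solve_1d_cell(1e-5, 0.05, 3.5, k)
  f <- 96500 / (8.314 * 298)
  eta_tafel <- log(s35$i / k$anode$i0) / (k$anode$alpha_a * f)
  expect_equal(s35$eta_a, eta_tafel, tolerance = 1e-6)
  expect_lt(abs(s35$eta_c), 0.3 * s35$eta_a)  # cathode loss stays minor
})
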