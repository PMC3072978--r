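# Secondary-model tests run on coarse meshes (n_base 8-16); the quantities
# checked here are conservation laws and trends, not reference magnitudes.

test_that("no driving force below the cell equilibrium potential", {
  s <- solve_secondary(secondary_spec(sigma = 0.05, V_app = 2.06), n_base = 8)
  expect_true(s$no_drive)
  expect_equal(s$I_total, 0)
  expect_equal(s$P, 0)
  expect_lt(max(s$efield$magnitude), 1e-6)  # differentiation round-off only
})

test_that("anode and cathode currents cancel on a converged solution", {
  for (sg in c(0.0005, 0.05)) {
    s <- solve_secondary(secondary_spec(sigma = sg, V_app = 2.9), n_base = 16)
    expect_true(s$converged)
    expect_gt(s$anode_current$current, 0)
    expect_lt(s$cathode_current$current, 0)
    expect_lt(abs(s$anode_current$current + s$cathode_current$current),
              0.01 * abs(s$anode_current$current))
  }
})

test_that("voltage budget closes: V = E_cell + eta_a - eta_c + ohmic", {
  s <- solve_secondary(secondary_spec(sigma = 0.005, V_app = 3.1), n_base = 16)
  d <- s$diagnostics
  closure <- s$spec$kinetics$E_cell_eq + d$eta_a - d$eta_c + d$ohmic_drop
  expect_lt(abs(closure - 3.1), 0.02 * 3.1)
})

test_that("surface field is consistent with the kinetic current density", {
  # at the anode surface, sigma * |E_normal| equals the local Butler-Volmer
  # current density (checked mid-electrode, away from the corner)
  s <- solve_secondary(secondary_spec(sigma = 0.05, V_app = 3.0), n_base = 16)
  g <- s$grid
  ia <- g$segments$ANODE
  mid <- ia[round(length(ia) / 2)]
  kin <- s$spec$kinetics
  eta <- surface_overpotentials(3.0, s$phi$values[mid, 1], NA, kin)
  i_kin <- bv_current(eta$eta_a, kin$anode)
  i_field <- 0.05 * abs(s$efield$ey[mid, 1])
  expect_equal(i_field, i_kin, tolerance = 0.05)
})

test_that("total current increases with applied voltage", {
  tab <- sweep_secondary(0.005, c(2.2, 2.5, 2.8, 3.1), n_base = 12)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$converged))
  expect_true(all(diff(tab$I_total) > 0))
})

test_that("field loses its conductivity dependence at high voltage", {
  # the sluggish anode kinetics cap the current, so the relative spread of
  # the insulator-centre field across conductivities shrinks as V_app grows
  tab <- sweep_secondary(c(0.0005, 0.05), c(2.7, 3.5), n_base = 12)
  spread <- function(v) (max(v) - min(v)) / max(v)
  lo <- spread(tab$E_insulator_centre[tab$V_app == 2.7])
  hi <- spread(tab$E_insulator_centre[tab$V_app == 3.5])
  expect_lt(hi, lo)
  # and the field decreases with conductivity at fixed moderate voltage
  e27 <- tab$E_insulator_centre[tab$V_app == 2.7]
  expect_gt(e27[tab$sigma[tab$V_app == 2.7] == 0.0005],
            e27[tab$sigma[tab$V_app == 2.7] == 0.05])
})

test_that("centerline profile decays away from the insulator", {
  s <- solve_secondary(secondary_spec(sigma = 0.0005, V_app = 3.0),
                       n_base = 16)
  pr <- centerline_profile(s)
  expect_equal(nrow(pr), length(s$grid$y))
  expect_true(all(diff(pr$y_um) > 0))
  expect_equal(max(pr$y_um), 20)
  # monotone decay beyond the first few nodes
  tail_part <- pr$E_kv_cm[-(1:5)]
  expect_true(all(diff(tail_part) <= 1e-12))
  expect_equal(pr$E_kv_cm[1], s$E_insulator_centre / 1e5)
})

test_that("2D facing-electrode emulation matches the closed-form 1D cell", {
  # flat anode on the whole bottom edge, flat cathode on the top edge:
  # the 2D Newton iteration must land on the scalar polarization solution
  k <- platinum_water()
  V <- 2.9; sig <- 0.005
  geom <- secondary_geometry(length = 2e-6, insulator_thickness = 1e-8,
                             height = 1e-5)
  g <- build_secondary_grid(geom, n_base = 8, grading = 1)
  phi <- matrix(V - k$anode$E_eq, length(g$x), length(g$y))
  for (it in 1:80) {
    ps_b <- phi[, 1]; ps_t <- phi[, ncol(phi)]
    eta_a <- V - ps_b - k$anode$E_eq
    eta_c <- -ps_t - k$cathode$E_eq
    ga <- bv_conductance(eta_a, k$anode)
    gc <- bv_conductance(eta_c, k$cathode)
    ph <- solve_laplace(g, list(
      BOTTOM = robin_bc(ga, bv_current(eta_a, k$anode) + ga * ps_b),
      TOP = robin_bc(gc, bv_current(eta_c, k$cathode) + gc * ps_t)),
      sigma = sig)
    if (max(abs(ph$values - phi)) < 1e-12) { phi <- ph$values; break }
    phi <- ph$values
  }
  pf <- structure(list(grid = g, values = phi, sigma = sig, aniso_y = 1,
                       residual = 0), class = "potential_field")
  i2d <- boundary_current(pf, sig, "BOTTOM")$current / geom$length
  ref <- solve_1d_cell(gap = geom$height, sigma = sig, V_app = V, k = k)
  expect_equal(i2d, ref$i, tolerance = 0.02)
  # and the top (cathode) current balances it
  itop <- boundary_current(pf, sig, "TOP")$current / geom$length
  expect_equal(itop, -ref$i, tolerance = 0.02)
})

test_that("sweeps record per-cell failures without aborting", {
  # a negative conductivity cell fails validation but the sweep continues
  tab <- sweep_secondary(c(-1, 0.05), 2.5, n_base = 8)
  expect_equal(nrow(tab), 2)
  expect_false(tab$converged[1])
  expect_true(is.na(tab$I_total[1]))
  expect_true(tab$converged[2])
})
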