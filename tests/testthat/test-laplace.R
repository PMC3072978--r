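test_that("uniform-grid ramp between Dirichlet walls is exact", {
  g <- build_channel_grid(channel_geometry(1, 0.5), n_base = 8, grading = 1)
  ph <- solve_laplace(g, list(LEFT = dirichlet_bc(1), RIGHT = dirichlet_bc(0)))
  exact <- 1 - outer(g$x, rep(1, length(g$y)))
  expect_lt(max(abs(ph$values - exact)), 1e-12)

  # conductivity cancels in pure-Dirichlet problems
  ph2 <- solve_laplace(g, list(LEFT = dirichlet_bc(1), RIGHT = dirichlet_bc(0)),
                       sigma = 0.005)
  expect_equal(ph$values, ph2$values, tolerance = 1e-12)
})

test_that("solution matches a dense direct solve of the same equations", {
  for (eps in c(0.3, 0.5)) {
    g <- build_channel_grid(channel_geometry(0.7, eps), n_base = 8,
                            grading = 2)
    # keep the dense oracle small: 8x8-ish sub-problem via small n_base
    bc <- list(ANODE = dirichlet_bc(1), CATHODE = dirichlet_bc(0),
               INSULATOR = zero_flux_bc())
    ph <- solve_laplace(g, bc, aniso_y = 1 / 0.7^2)
    ref <- dense_laplace_oracle(g, bc, sigma = 1, aniso_y = 1 / 0.7^2)
    expect_lt(max(abs(ph$values - ref)), 1e-10)
  }
})

test_that("discrete maximum principle holds for mixed Dirichlet/zero-flux solves", {
  for (G in c(0.1, 1)) for (eps in c(0, 0.5)) {
    ph <- solve_primary(channel_geometry(G, eps), n_base = 12)$phi
    expect_gte(min(ph$values), 0)
    expect_lte(max(ph$values), 1)
  }
})

test_that("second-order convergence on a smooth manufactured solution", {
  # phi = sin(pi X) sinh(pi Y)/sinh(pi) with matching Dirichlet data;
  # probe error at the interior node (0.5, 0.5) drops ~4x per halving
  err <- vapply(c(8, 16, 32), function(n) {
    g <- build_channel_grid(channel_geometry(1, 0.5), n_base = n, grading = 1)
    ph <- solve_laplace(g, manufactured_bc(g))
    i <- which(abs(g$x - 0.5) < 1e-14); j <- which(abs(g$y - 0.5) < 1e-14)
    abs(ph$values[i, j] - manufactured_phi(0.5, 0.5)[1, 1])
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)
  expect_gt(err[2] / err[3], 3)
  expect_lt(err[1] / err[2], 5.5)
  expect_lt(err[2] / err[3], 5.5)
})

test_that("electric field differentiates exactly through quadratics", {
  g <- build_channel_grid(channel_geometry(1, 0.5), n_base = 8, grading = 2)
  nx <- length(g$x); ny <- length(g$y)
  # linear ramp: E = (-1, 0) everywhere, including boundaries
  ph <- structure(list(grid = g, values = outer(g$x, rep(1, ny)),
                       sigma = 1, aniso_y = 1, residual = 0),
                  class = "potential_field")
  ef <- electric_field(ph)
  expect_lt(max(abs(ef$ex + 1)), 1e-12)
  expect_lt(max(abs(ef$ey)), 1e-12)
  expect_equal(ef$magnitude, sqrt(ef$ex^2 + ef$ey^2))
  # quadratic: the three-point formulas are exact, d(x^2)/dx = 2x
  ph$values <- outer(g$x^2, rep(1, ny))
  ef2 <- electric_field(ph)
  expect_lt(max(abs(ef2$ex + 2 * outer(g$x, rep(1, ny)))), 1e-11)
  # y_scale rescales the vertical component
  ph$values <- outer(rep(1, nx), g$y)
  ef3 <- electric_field(ph, y_scale = 10)
  expect_lt(max(abs(ef3$ey + 10)), 1e-10)
})

test_that("boundary current obeys Ohm's law and is linear in sigma", {
  # vertical ramp cell: Dirichlet V on the whole bottom edge, 0 on top;
  # density = sigma * V / H everywhere on the bottom
  g <- build_channel_grid(channel_geometry(1, 0.5), n_base = 8, grading = 1)
  V <- 2; sig <- 0.05
  ph <- solve_laplace(g, list(BOTTOM = dirichlet_bc(V), TOP = dirichlet_bc(0)),
                      sigma = sig)
  bcur <- boundary_current(ph, sig, "BOTTOM")
  expect_equal(bcur$density, rep(sig * V, length(bcur$density)),
               tolerance = 1e-10)
  expect_equal(bcur$current, sig * V * 1, tolerance = 1e-10)
  expect_gt(bcur$current, 0)  # current enters at the driven electrode
  # doubling sigma at fixed phi doubles the density
  b2 <- boundary_current(ph, 2 * sig, "BOTTOM")
  expect_equal(b2$density, 2 * bcur$density)
  # and the segment-wise integral splits additively
  ba <- boundary_current(ph, sig, "ANODE")
  bi <- boundary_current(ph, sig, "INSULATOR")
  bct <- boundary_current(ph, sig, "CATHODE")
  expect_equal(ba$current + bi$current + bct$current, bcur$current,
               tolerance = 1e-6)
})

test_that("singular all-flux systems are rejected", {
  g <- build_channel_grid(channel_geometry(1, 0.5), n_base = 8)
  expect_error(solve_laplace(g, list(ANODE = zero_flux_bc())), "singular")
  expect_error(solve_laplace(g, list(ANODE = flux_bc(1))), "singular")
})

test_that("field snapshots round-trip through CSV", {
  g <- build_channel_grid(channel_geometry(1, 0.5), n_base = 8)
  ph <- solve_laplace(g, list(ANODE = dirichlet_bc(1),
                              CATHODE = dirichlet_bc(0)))
  f <- tempfile(fileext = ".csv")
  write_field_csv(ph, f, quantity = "potential", units = "1")
  expect_match(readLines(f, n = 1), "^# potential \\[1\\]")
  df <- utils::read.csv(f, comment.char = "#")
  expect_equal(nrow(df), length(g$x) * length(g$y))
  expect_equal(matrix(df$value, length(g$x)), unname(ph$values),
               tolerance = 1e-11)
  unlink(f)
})
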