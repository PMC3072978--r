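# The 2D secondary current distribution model: Laplace in the bulk water,
# Butler-Volmer kinetic flux conditions on the coplanar anode and cathode,
# zero flux on the insulator, side walls and far-field top.
#
# The nonlinear boundary coupling is solved by an outer Newton iteration:
# the kinetic current is linearized about the current boundary potential,
#   i(phi_s) ~ i_k - g_k (phi_s - phi_s_k),   g_k = d i / d eta >= 0,
# which yields a Robin condition for the next linear Laplace solve.  A
# continuation ladder in applied voltage (steps <= 0.1 V from the cell
# equilibrium potential) seeds each solve with the previous solution, which
# tames the stiff exponential kinetics at high voltage.

#' Specification of a secondary current distribution cell
#'
#' @param geometry a [secondary_geometry()].
#' @param kinetics a `cell_kinetics` object, e.g. [platinum_water()].
#' @param sigma water (electrolyte) conductivity, S/m; the study values
#'   are 0.0005, 0.005 and 0.05.
#' @param V_app applied cell voltage, V; must exceed the cell equilibrium
#'   potential (2.06 V for platinum/water) to drive any current.
#' @return A `secondary_spec` object.
#' @examples
#' secondary_spec(sigma = 0.0005, V_app = 2.7)
#' @export
secondary_spec <- function(geometry = secondary_geometry(),
                           kinetics = platinum_water(),
                           sigma, V_app) {
  stopifnot(inherits(geometry, "secondary_geometry"),
            inherits(kinetics, "cell_kinetics"),
            sigma > 0, V_app > 0)
  structure(list(geometry = geometry, kinetics = kinetics,
                 sigma = sigma, V_app = V_app),
            class = "secondary_spec")
}

#' @export
print.secondary_spec <- function(x, ...) {
  cat(sprintf("<secondary_spec> sigma = %g S/m, V_app = %g V, E_cell_eq = %g V\n",
              x$sigma, x$V_app, x$kinetics$E_cell_eq))
  invisible(x)
}

# One Newton solve at fixed V_app starting from phi (nx-by-ny matrix or NULL).
# Returns list(phi, residuals, converged, iterations).
secondary_newton <- function(grid, spec, V_app, phi = NULL,
                             outer_tol = 1e-7, max_outer = 60) {
  kin <- spec$kinetics
  sigma <- spec$sigma
  nx <- length(grid$x); ny <- length(grid$y)
  ia <- grid$segments$ANODE
  ic <- grid$segments$CATHODE
  if (is.null(phi)) {
    # equilibrium solution: uniform potential, eta_a = eta_c = 0
    phi <- matrix(V_app - kin$anode$E_eq, nx, ny)
  }
  surface_current <- function(ps) {
    eta <- surface_overpotentials(V_app, ps[ia], ps[ic], kin)
    list(ia = bv_current(eta$eta_a, kin$anode),
         ic = bv_current(eta$eta_c, kin$cathode),
         eta = eta)
  }
  i_old <- NULL
  residuals <- numeric(0)
  converged <- FALSE
  lambda <- 1
  for (it in seq_len(max_outer)) {
    ps <- phi[, 1]
    eta <- surface_overpotentials(V_app, ps[ia], ps[ic], kin)
    ga <- bv_conductance(eta$eta_a, kin$anode)
    gc <- bv_conductance(eta$eta_c, kin$cathode)
    bc <- list(
      ANODE = robin_bc(ga, bv_current(eta$eta_a, kin$anode) + ga * ps[ia]),
      CATHODE = robin_bc(gc, bv_current(eta$eta_c, kin$cathode) + gc * ps[ic]),
      INSULATOR = zero_flux_bc())
    sol <- solve_laplace(grid, bc, sigma = sigma)
    phi_new <- sol$values
    phi <- phi + lambda * (phi_new - phi)
    cur <- surface_current(phi[, 1])
    i_new <- c(cur$ia, cur$ic)
    if (!is.null(i_old)) {
      res <- max(abs(i_new - i_old)) / max(max(abs(i_new)), 1e-300)
      residuals <- c(residuals, res)
      # absolute floor: changes below 1e-14 A/m^2 are round-off, not physics
      if (res <= outer_tol || max(abs(i_new - i_old)) <= 1e-14) {
        converged <- TRUE
        break
      }
      n <- length(residuals)
      if (n >= 2 && residuals[n] > residuals[n - 1]) {
        lambda <- max(lambda / 2, 1 / 64)      # damp on residual growth
      } else if (lambda < 1) lambda <- min(1, lambda * 2)
    }
    i_old <- i_new
  }
  ps <- phi[, 1]
  eta <- surface_overpotentials(V_app, ps[ia], ps[ic], kin)
  if (converged &&
      (any(bv_cap_active(eta$eta_a, kin$anode)) ||
       any(bv_cap_active(eta$eta_c, kin$cathode))))
    stop("Butler-Volmer exponent cap active in a converged solution; ",
         "the parameter set is outside the model's validity range")
  list(phi = phi, residuals = residuals, converged = converged,
       iterations = length(residuals) + 1L)
}

#' Solve the secondary current distribution model
#'
#' Computes the electrolyte potential, electric field, electrode boundary
#' currents, total cell current and power input for a
#' [secondary_spec()].  When `continuation = TRUE` (default) the applied
#' voltage is approached along a ladder from the cell equilibrium
#' potential in steps of at most `v_step`, each solve seeded with the
#' previous solution.
#'
#' If `V_app` does not exceed the cell equilibrium potential there is no
#' driving force; the solution is flagged `no_drive` and carries zero
#' current and field.
#'
#' @param spec a [secondary_spec()].
#' @param n_base mesh control (see [build_secondary_grid()]).
#' @param grading grading exponent toward the insulator corners.
#' @param outer_tol relative tolerance on the max nodal change of the
#'   boundary current density between outer iterations.
#' @param max_outer maximum outer iterations per voltage step.
#' @param continuation use a voltage ladder (recommended).
#' @param v_step maximum ladder step, V.
#' @param phi_init optional initial potential matrix (overrides the
#'   default equilibrium start; used by [sweep_secondary()]).
#' @return A `secondary_solution`: list with `spec`, `grid`, `phi`
#'   (`potential_field`, V), `efield` (`electric_field`, V/m),
#'   `anode_current`, `cathode_current` (`boundary_current`), `I_total`
#'   (A per metre of depth, anode side), `P` (power input, uW/cm^2),
#'   `E_insulator_centre` (V/m at the insulator surface midpoint),
#'   `converged`, `no_drive` and `diagnostics` (residual history, ohmic
#'   drop and area-averaged overpotentials).
#' @examples
#' s <- solve_secondary(secondary_spec(sigma = 0.05, V_app = 2.5), n_base = 8)
#' s$I_total
#' @export
solve_secondary <- function(spec, n_base = 32, grading = 3,
                            outer_tol = 1e-7, max_outer = 60,
                            continuation = TRUE, v_step = 0.1,
                            phi_init = NULL) {
  stopifnot(inherits(spec, "secondary_spec"))
  grid <- build_secondary_grid(spec$geometry, n_base, grading)
  kin <- spec$kinetics
  no_drive <- spec$V_app <= kin$E_cell_eq

  if (no_drive) {
    phi_mat <- matrix(spec$V_app - kin$anode$E_eq,
                      length(grid$x), length(grid$y))
    nt <- list(phi = phi_mat, residuals = numeric(0), converged = TRUE,
               iterations = 0L)
  } else {
    phi <- phi_init
    if (continuation && is.null(phi_init)) {
      ladder <- seq(kin$E_cell_eq, spec$V_app, by = v_step)
      ladder <- unique(c(ladder, spec$V_app))
    } else ladder <- spec$V_app
    for (V in ladder) {
      nt <- secondary_newton(grid, spec, V, phi, outer_tol, max_outer)
      phi <- nt$phi
    }
    if (!nt$converged)
      warning(sprintf(
        "outer iteration not converged after %d steps (last residual %.3g)",
        nt$iterations, utils::tail(nt$residuals, 1)))
  }

  pf <- structure(list(grid = grid, values = nt$phi, sigma = spec$sigma,
                       aniso_y = 1, residual = 0), class = "potential_field")
  ef <- electric_field(pf)
  an <- boundary_current(pf, spec$sigma, "ANODE")
  ca <- boundary_current(pf, spec$sigma, "CATHODE")
  # field at the insulator surface midpoint (x = length/2, y = 0)
  icn <- which.min(abs(grid$x - grid$geom$length / 2))
  Ecen <- ef$magnitude[icn, 1]

  ps <- nt$phi[, 1]
  ia <- grid$segments$ANODE; ic <- grid$segments$CATHODE
  wa <- cv_widths(grid$x)[ia]; wc <- cv_widths(grid$x)[ic]
  phis_a <- sum(ps[ia] * wa) / sum(wa)
  phis_c <- sum(ps[ic] * wc) / sum(wc)
  eta <- surface_overpotentials(spec$V_app, phis_a, phis_c, kin)

  I_total <- an$current
  P <- 100 * spec$V_app * I_total   # uW/cm^2; see power_input()

  structure(list(
    spec = spec, grid = grid, phi = pf, efield = ef,
    anode_current = an, cathode_current = ca,
    I_total = I_total, P = P,
    E_insulator_centre = Ecen,
    converged = nt$converged, no_drive = no_drive,
    diagnostics = list(residuals = nt$residuals,
                       iterations = nt$iterations,
                       ohmic_drop = phis_a - phis_c,
                       eta_a = eta$eta_a, eta_c = eta$eta_c),
    n_base = n_base, grading = grading),
    class = "secondary_solution")
}

#' @export
print.secondary_solution <- function(x, ...) {
  cat(sprintf(paste0(
    "<secondary_solution> sigma = %g S/m, V_app = %g V%s\n",
    "  |E| at insulator centre: %.4g kV/cm\n",
    "  I = %.4g A/m depth, P = %.4g uW/cm^2 (%s)\n"),
    x$spec$sigma, x$spec$V_app, if (x$no_drive) " [NO_DRIVE]" else "",
    x$E_insulator_centre / 1e5, x$I_total, x$P,
    if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' Vertical field profile above the insulator centre
#'
#' Samples the field magnitude along the vertical line through the
#' insulator midpoint, from the insulator surface to the top boundary.
#'
#' @param sol a `secondary_solution`.
#' @return `data.frame` with `y_um` (height above the insulator, um,
#'   increasing) and `E_kv_cm` (field magnitude, kV/cm).
#' @export
centerline_profile <- function(sol) {
  stopifnot(inherits(sol, "secondary_solution"))
  grid <- sol$grid
  icn <- which.min(abs(grid$x - grid$geom$length / 2))
  data.frame(y_um = grid$y * 1e6,
             E_kv_cm = sol$efield$magnitude[icn, ] / 1e5)
}

#' Power input per reference area
#'
#' `P = V_app * I_total`, with the total current taken per metre of device
#' depth and the power referred to one square metre of reference area,
#' expressed in uW/cm^2 (so numerically `P = 100 * V_app * I_total`).
#' See the methods vignette for the calibration of this reporting
#' convention.
#'
#' @param sol a `secondary_solution`.
#' @param spec optional [secondary_spec()]; defaults to the one stored in
#'   `sol`.
#' @return Power input, uW/cm^2.
#' @export
power_input <- function(sol, spec = sol$spec) {
  stopifnot(inherits(sol, "secondary_solution"))
  100 * spec$V_app * sol$I_total
}

#' Parametric sweep of the secondary model
#'
#' For each conductivity, walks the applied-voltage list in increasing
#' order with continuation (each solve seeded by the previous one).
#' Per-cell failures are recorded in the result and do not abort the
#' sweep.
#'
#' @param sigma_list conductivities, S/m.
#' @param vapp_list applied voltages, V.
#' @param geometry,kinetics cell geometry and electrode kinetics shared by
#'   every sweep cell.
#' @inheritParams solve_secondary
#' @return `data.frame` with columns `sigma`, `V_app`, `E_insulator_centre`
#'   (kV/cm), `I_total` (A/m), `P` (uW/cm^2), `converged`.
#' @export
sweep_secondary <- function(sigma_list, vapp_list,
                            geometry = secondary_geometry(),
                            kinetics = platinum_water(),
                            n_base = 32, grading = 3,
                            outer_tol = 1e-7, max_outer = 60, v_step = 0.1) {
  stopifnot(length(sigma_list) >= 1, length(vapp_list) >= 1)
  vapp_sorted <- sort(vapp_list)
  rows <- list()
  for (sigma in sigma_list) {
    phi <- NULL
    v_prev <- NULL
    for (V in vapp_sorted) {
      row <- tryCatch({
        spec <- secondary_spec(geometry = geometry, kinetics = kinetics,
                               sigma = sigma, V_app = V)
        if (is.null(phi)) {
          sol <- solve_secondary(spec, n_base, grading, outer_tol, max_outer,
                                 continuation = TRUE, v_step = v_step)
        } else {
          # continue from the previous voltage with at most v_step substeps
          ladder <- seq(v_prev, V, by = v_step)
          ladder <- unique(c(ladder[-1], V))
          for (Vl in ladder) {
            spec_l <- secondary_spec(geometry = geometry,
                                     kinetics = kinetics,
                                     sigma = sigma, V_app = Vl)
            sol <- solve_secondary(spec_l, n_base, grading, outer_tol,
                                   max_outer, continuation = FALSE,
                                   phi_init = phi)
            phi <- sol$phi$values
          }
        }
        phi <- sol$phi$values
        v_prev <- V
        data.frame(sigma = sigma, V_app = V,
                   E_insulator_centre = sol$E_insulator_centre / 1e5,
                   I_total = sol$I_total, P = sol$P,
                   converged = sol$converged)
      }, error = function(e) {
        data.frame(sigma = sigma, V_app = V, E_insulator_centre = NA_real_,
                   I_total = NA_real_, P = NA_real_, converged = FALSE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
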