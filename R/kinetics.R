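# Butler-Volmer electrode kinetics and the overpotential bookkeeping that
# splits an applied cell voltage into its equilibrium, surface-kinetic and
# ohmic parts.
#
# Physical constants are fixed at the values of the parameter table used
# throughout the platinum/water study (not CODATA).
FARADAY <- 96500    # C/mol
GAS_CONST <- 8.314  # J/(mol K)
BV_EXP_CAP <- 500   # cap on Butler-Volmer exponent arguments

#' Butler-Volmer kinetic parameters of one half-reaction
#'
#' @param i0 exchange current density, A/m^2 (> 0).
#' @param alpha_a,alpha_c anodic and cathodic transfer coefficients
#'   (dimensionless, > 0).  For a multi-electron reaction these are
#'   effective coefficients (electrons transferred times the symmetry
#'   factor of the rate-determining step).
#' @param E_eq standard reduction equilibrium potential, V.
#' @param T temperature, K.
#' @return An object of class `butler_volmer`.
#' @examples
#' butler_volmer(i0 = 10, alpha_a = 0.5, alpha_c = 0.5, E_eq = -0.83)
#' @export
butler_volmer <- function(i0, alpha_a, alpha_c, E_eq, T = 298) {
  stopifnot(i0 > 0, alpha_a > 0, alpha_c > 0, T > 0, is.finite(E_eq))
  structure(list(i0 = i0, alpha_a = alpha_a, alpha_c = alpha_c,
                 E_eq = E_eq, T = T),
            class = "butler_volmer")
}

#' @export
print.butler_volmer <- function(x, ...) {
  cat(sprintf("<butler_volmer> i0 = %g A/m^2, alpha_a = %g, alpha_c = %g, E_eq = %g V, T = %g K\n",
              x$i0, x$alpha_a, x$alpha_c, x$E_eq, x$T))
  invisible(x)
}

#' Butler-Volmer current density
#'
#' `i = i0 * (exp(alpha_a F eta / (R T)) - exp(-alpha_c F eta / (R T)))`,
#' positive for net oxidation.  Exponent arguments are clipped at +/-500;
#' a converged solve with an active clip is reported as an error by the
#' solvers, never returned silently.
#'
#' @param eta surface overpotential, V (vectorized).
#' @param p a [butler_volmer()] parameter set.
#' @return Net current density, A/m^2.
#' @examples
#' p <- butler_volmer(10, 0.5, 0.5, -0.83)
#' bv_current(0, p)      # 0 at equilibrium
#' @export
bv_current <- function(eta, p) {
  stopifnot(inherits(p, "butler_volmer"), all(is.finite(eta)))
  f <- FARADAY / (GAS_CONST * p$T)
  za <- pmax(pmin(p$alpha_a * f * eta, BV_EXP_CAP), -BV_EXP_CAP)
  zc <- pmax(pmin(p$alpha_c * f * eta, BV_EXP_CAP), -BV_EXP_CAP)
  p$i0 * (exp(za) - exp(-zc))
}

#' Derivative of the Butler-Volmer current with respect to overpotential
#'
#' Always positive; at `eta = 0` equals `i0 (alpha_a + alpha_c) F / (R T)`.
#'
#' @inheritParams bv_current
#' @return `d i / d eta`, A/(m^2 V).
#' @export
bv_conductance <- function(eta, p) {
  stopifnot(inherits(p, "butler_volmer"))
  f <- FARADAY / (GAS_CONST * p$T)
  za <- pmax(pmin(p$alpha_a * f * eta, BV_EXP_CAP), -BV_EXP_CAP)
  zc <- pmax(pmin(p$alpha_c * f * eta, BV_EXP_CAP), -BV_EXP_CAP)
  p$i0 * f * (p$alpha_a * exp(za) + p$alpha_c * exp(-zc))
}

# TRUE where the exponent clip binds
bv_cap_active <- function(eta, p) {
  f <- FARADAY / (GAS_CONST * p$T)
  pmax(p$alpha_a * f * eta, -p$alpha_c * f * eta) >= BV_EXP_CAP
}

#' Invert the Butler-Volmer relation
#'
#' Overpotential producing a given net current density.  With equal
#' transfer coefficients the inverse is the closed form
#' `eta = asinh(i / (2 i0)) R T / (alpha F)`; otherwise a safeguarded
#' Newton iteration is used.
#'
#' @param i net current density, A/m^2 (vectorized).
#' @param p a [butler_volmer()] parameter set.
#' @param tol relative tolerance on the reproduced current.
#' @return Overpotential, V.
#' @export
bv_invert <- function(i, p, tol = 1e-12) {
  stopifnot(inherits(p, "butler_volmer"), all(is.finite(i)))
  f <- FARADAY / (GAS_CONST * p$T)
  if (isTRUE(all.equal(p$alpha_a, p$alpha_c))) {
    return(asinh(i / (2 * p$i0)) / (p$alpha_a * f))
  }
  vapply(i, function(ii) {
    eta <- asinh(ii / (2 * p$i0)) / ((p$alpha_a + p$alpha_c) / 2 * f)
    for (k in 1:100) {
      r <- bv_current(eta, p) - ii
      if (abs(r) <= tol * max(abs(ii), p$i0)) break
      eta <- eta - r / bv_conductance(eta, p)
    }
    eta
  }, numeric(1))
}

#' Kinetics of a two-electrode electrochemical cell
#'
#' @param anode,cathode [butler_volmer()] parameter sets of the two
#'   half-reactions (reduction-potential convention).
#' @return A `cell_kinetics` object with the derived cell equilibrium
#'   potential `E_cell_eq = anode$E_eq - cathode$E_eq`.
#' @examples
#' cell_kinetics(butler_volmer(1e-8, 1, 1, 1.23),
#'               butler_volmer(10, 1, 1, -0.83))$E_cell_eq  # 2.06 V
#' @export
cell_kinetics <- function(anode, cathode) {
  stopifnot(inherits(anode, "butler_volmer"), inherits(cathode, "butler_volmer"))
  structure(list(anode = anode, cathode = cathode,
                 E_cell_eq = anode$E_eq - cathode$E_eq),
            class = "cell_kinetics")
}

#' @export
print.cell_kinetics <- function(x, ...) {
  cat(sprintf("<cell_kinetics> E_cell_eq = %g V\n  anode:   ", x$E_cell_eq))
  print(x$anode)
  cat("  cathode: "); print(x$cathode)
  invisible(x)
}

#' Platinum electrodes in water: packaged kinetic parameters
#'
#' The half-reactions of water electrolysis on inert platinum: water
#' oxidation at the anode (reduction equilibrium potential 1.23 V, exchange
#' current density 1e-8 A/m^2) and water reduction at the cathode
#' (-0.83 V, 10 A/m^2), at 298 K, giving a cell equilibrium potential of
#' 2.06 V.  The effective transfer coefficients default to 1.0 on both
#' branches: two electrons transferred per elementary step times a symmetry
#' factor of 0.5 (the multi-electron form of the Butler-Volmer relation).
#' See the methods vignette for the calibration of this convention.
#'
#' Every parameter can be overridden, e.g. to model a different electrode
#' material or a single-electron convention.
#'
#' @param i0_anode,i0_cathode exchange current densities, A/m^2.
#' @param alpha_anode,alpha_cathode effective transfer coefficients
#'   (applied to both branches of each electrode).
#' @param E_eq_anode,E_eq_cathode reduction equilibrium potentials, V.
#' @param T temperature, K.
#' @return A `cell_kinetics` object.
#' @examples
#' platinum_water()$E_cell_eq  # 2.06
#' @export
platinum_water <- function(i0_anode = 1e-8, i0_cathode = 10,
                           alpha_anode = 1.0, alpha_cathode = 1.0,
                           E_eq_anode = 1.23, E_eq_cathode = -0.83,
                           T = 298) {
  cell_kinetics(
    anode = butler_volmer(i0_anode, alpha_anode, alpha_anode, E_eq_anode, T),
    cathode = butler_volmer(i0_cathode, alpha_cathode, alpha_cathode,
                            E_eq_cathode, T))
}

#' Surface overpotentials from the applied voltage and surface potentials
#'
#' With the anode metal at `V_app` and the cathode metal grounded, the
#' surface overpotentials are
#' `eta_a = V_app - phi_s_anode - E_eq_anode` and
#' `eta_c = -phi_s_cathode - E_eq_cathode`, which reproduce the voltage
#' decomposition
#' `V_app = E_cell_eq + eta_a - eta_c + (phi_s_anode - phi_s_cathode)`
#' identically (the last term is the ohmic drop through the electrolyte).
#'
#' @param V_app applied cell voltage, V.
#' @param phi_s_anode,phi_s_cathode electrolyte potential at the electrode
#'   surfaces, V (vectorized).
#' @param k a `cell_kinetics` object.
#' @return List with components `eta_a` and `eta_c` (V).
#' @export
surface_overpotentials <- function(V_app, phi_s_anode, phi_s_cathode, k) {
  stopifnot(inherits(k, "cell_kinetics"))
  list(eta_a = V_app - phi_s_anode - k$anode$E_eq,
       eta_c = -phi_s_cathode - k$cathode$E_eq)
}

#' Closed-form 1D cell: facing electrodes across a uniform gap
#'
#' Solves the scalar polarization equation
#' `V_app = E_cell_eq + eta_a(i) - eta_c(i) + i * gap / sigma`
#' for the cell current density `i`, where `eta_a` and `eta_c` invert the
#' Butler-Volmer relation at the anode (`+i`) and cathode (`-i`).  This is
#' the independent oracle for the coupled 2D secondary solver: a facing-
#' electrode geometry with uniform current has exactly this solution.
#'
#' @param gap electrode separation, m.
#' @param sigma electrolyte conductivity, S/m.
#' @param V_app applied voltage, V.
#' @param k a `cell_kinetics` object.
#' @param tol absolute tolerance on the voltage residual, V.
#' @return List with `i` (A/m^2), `eta_a`, `eta_c`, `ohmic` (V) and
#'   `no_drive` (TRUE when `V_app <= E_cell_eq`, in which case `i = 0`).
#' @examples
#' solve_1d_cell(1e-5, 0.05, 2.5, platinum_water())$i
#' @export
solve_1d_cell <- function(gap, sigma, V_app, k, tol = 1e-12) {
  stopifnot(gap > 0, sigma > 0, inherits(k, "cell_kinetics"))
  vres <- function(i) {
    k$E_cell_eq + bv_invert(i, k$anode) - bv_invert(-i, k$cathode) +
      i * gap / sigma - V_app
  }
  if (V_app <= k$E_cell_eq) {
    return(list(i = 0, eta_a = 0, eta_c = 0, ohmic = 0,
                no_drive = TRUE))
  }
  hi <- k$anode$i0
  while (vres(hi) < 0) hi <- hi * 10
  r <- stats::uniroot(vres, lower = 0, upper = hi, tol = .Machine$double.eps^0.75)
  i <- r$root
  # polish to the requested voltage residual with Newton steps
  for (it in 1:50) {
    f <- vres(i)
    if (abs(f) <= tol) break
    dfdi <- 1 / bv_conductance(bv_invert(i, k$anode), k$anode) +
      1 / bv_conductance(bv_invert(-i, k$cathode), k$cathode) + gap / sigma
    i <- max(i - f / dfdi, i * 1e-3)
  }
  list(i = i,
       eta_a = bv_invert(i, k$anode),
       eta_c = bv_invert(-i, k$cathode),
       ohmic = i * gap / sigma,
       no_drive = FALSE)
}
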