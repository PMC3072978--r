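# The non-dimensional primary current distribution model of the
# micro-electroporation channel.
#
# In non-dimensional variables (X = x/l, Y = y/h, with l the active
# electrode length and h the half channel height) the potential obeys
#   d2(Phi)/dX2 + (1/G^2) d2(Phi)/dY2 = 0,     G = h / l,
# with equipotential electrodes (Phi = 1 on the anode, 0 on the cathode),
# a zero-flux insulator of relative width epsilon = d / l between them, and
# zero-flux side and top (channel mid-plane) boundaries.  The reported
# quantity is the non-dimensional field magnitude
#   E* = sqrt( (dPhi/dX)^2 + (1/G dPhi/dY)^2 )
# at the probe point (X = 0.5, Y = 1), in units of V_d / l.

#' Solve the primary channel model
#'
#' Dirichlet 1 on the anode, 0 on the cathode, zero flux elsewhere.  In the
#' singular `epsilon = 0` limit the node where the electrodes meet carries
#' the mean of the two electrode potentials; the probe point at the channel
#' mid-plane is far from that node.  A grid line always lies at `X = 0.5`
#' and `Y = 1` is the top boundary, so the probe read is a node value.
#'
#' @param geom a [channel_geometry()].
#' @param n_base mesh control, intervals per electrode segment (see
#'   [build_channel_grid()]).
#' @param grading grading exponent toward the insulator junctions.
#' @return A `primary_result`: list with `geometry`, `grid`, `phi`
#'   (`potential_field`), `efield` (`electric_field`, non-dimensional),
#'   `probe_value` (E* at X = 0.5, Y = 1) and `n_base`.
#' @examples
#' solve_primary(channel_geometry(0.5, 0.5), n_base = 16)$probe_value
#' @export
solve_primary <- function(geom, n_base = 48, grading = 3) {
  stopifnot(inherits(geom, "channel_geometry"))
  grid <- build_channel_grid(geom, n_base, grading)
  bc <- list(ANODE = dirichlet_bc(1), CATHODE = dirichlet_bc(0),
             INSULATOR = zero_flux_bc())
  if (geom$epsilon == 0) {
    # electrodes meet at X = 0.5: assign the mean of the Dirichlet values
    # to the shared junction node (owned by the ANODE segment)
    v <- ifelse(abs(grid$x[grid$segments$ANODE] - 0.5) < 1e-12, 0.5, 1)
    bc$ANODE <- dirichlet_bc(v)
  }
  phi <- solve_laplace(grid, bc, sigma = 1, aniso_y = 1 / geom$G^2)
  ef <- electric_field(phi, y_scale = 1 / geom$G)
  ic <- which.min(abs(grid$x - 0.5))
  if (abs(grid$x[ic] - 0.5) > 1e-12)
    stop("internal error: no grid line at X = 0.5")
  probe <- ef$magnitude[ic, length(grid$y)]
  structure(list(geometry = geom, grid = grid, phi = phi, efield = ef,
                 probe_value = probe, n_base = n_base, grading = grading),
            class = "primary_result")
}

#' @export
print.primary_result <- function(x, ...) {
  cat(sprintf("<primary_result> G = %g, epsilon = %g: E* at (0.5, 1) = %.6g (n_base = %d)\n",
              x$geometry$G, x$geometry$epsilon, x$probe_value, x$n_base))
  invisible(x)
}

#' Solve the primary model on successively refined meshes
#'
#' Doubles `n_base` until the probe field changes by less than `rel_tol`
#' between the two finest levels (the mesh-convergence criterion applied
#' before any probe value is reported).
#'
#' @inheritParams solve_primary
#' @param rel_tol relative change accepted between the two finest levels.
#' @param max_levels maximum number of refinement levels.
#' @return The finest `primary_result`, with `converged` (logical) and
#'   `probe_history` (one probe value per level) added.
#' @export
solve_primary_converged <- function(geom, n_base = 48, grading = 3,
                                    rel_tol = 0.01, max_levels = 3) {
  res <- solve_primary(geom, n_base, grading)
  history <- res$probe_value
  converged <- FALSE
  for (lev in seq_len(max_levels - 1)) {
    n_base <- n_base * 2L
    res <- solve_primary(geom, n_base, grading)
    history <- c(history, res$probe_value)
    if (abs(diff(utils::tail(history, 2))) <= rel_tol * abs(res$probe_value)) {
      converged <- TRUE
      break
    }
  }
  res$converged <- converged
  res$probe_history <- history
  res
}

#' Parametric sweep of the primary model
#'
#' One solve per `(G, epsilon)` pair, G-major row order; fully
#' deterministic.
#'
#' @param G_list,eps_list geometry values to sweep.
#' @inheritParams solve_primary
#' @return `data.frame` with columns `G`, `epsilon`, `probe_E`, `n_base`.
#' @export
sweep_primary <- function(G_list, eps_list, n_base = 48, grading = 3) {
  stopifnot(length(G_list) >= 1, length(eps_list) >= 1)
  rows <- vector("list", length(G_list) * length(eps_list))
  r <- 0L
  for (G in G_list) for (eps in eps_list) {
    r <- r + 1L
    res <- tryCatch(solve_primary(channel_geometry(G, eps), n_base, grading),
                    error = function(e)
                      stop(sprintf("sweep failed at G = %g, epsilon = %g: %s",
                                   G, eps, conditionMessage(e)), call. = FALSE))
    rows[[r]] <- data.frame(G = G, epsilon = eps, probe_E = res$probe_value,
                            n_base = n_base)
  }
  do.call(rbind, rows)
}

#' Percent increase of the probe field relative to a baseline
#'
#' `100 * (value_at_eps0 - value_at_eps) / value_at_eps`: the percent
#' increase obtained by thinning the insulator from some epsilon down to
#' the singular zero-width limit, with the thick-insulator value as the
#' baseline.
#'
#' @param value_at_eps0 probe field at epsilon = 0.
#' @param value_at_eps baseline probe field at the larger epsilon.
#' @return Percent increase.
#' @examples
#' percent_increase(5.13, 1)  # 413
#' @export
percent_increase <- function(value_at_eps0, value_at_eps) {
  if (any(value_at_eps0 <= 0) || any(value_at_eps <= 0))
    stop("field magnitudes must be positive")
  100 * (value_at_eps0 - value_at_eps) / value_at_eps
}

#' Dimensional field magnitudes from a primary solution
#'
#' Scales the non-dimensional field by `V_d / l` and converts to kV/cm.
#' The maximum is taken over all nodes except the singular
#' insulator-electrode junction nodes on the bottom edge, where the
#' continuum field diverges.
#'
#' @param result a `primary_result`.
#' @param V_d potential difference between the electrodes, V.
#' @param l active electrode length, m.
#' @return List with `field` (nx-by-ny matrix, kV/cm), `probe` (kV/cm at
#'   the channel mid-plane probe) and `max_field` (kV/cm, singular corner
#'   nodes excluded).
#' @examples
#' r <- solve_primary(channel_geometry(0.2, 0.01), n_base = 16)
#' dimensionalize(r, V_d = 0.5, l = 10e-6)$probe
#' @export
dimensionalize <- function(result, V_d, l) {
  stopifnot(inherits(result, "primary_result"), V_d > 0, l > 0)
  scale <- V_d / l / 1e5   # V/m -> kV/cm
  field <- result$efield$magnitude * scale
  grid <- result$grid
  junc <- unique(vapply(grid$junctions,
                        function(a) which.min(abs(grid$x - a)), integer(1)))
  masked <- field
  masked[junc, 1] <- NA
  list(field = field,
       probe = result$probe_value * scale,
       max_field = max(masked, na.rm = TRUE))
}
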