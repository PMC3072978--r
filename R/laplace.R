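# Conservative five-point finite-volume discretization of
#   div( sigma grad(phi) ) = 0
# on a tensor-product grid, with mixed Dirichlet / zero-flux / prescribed-flux
# / linearized-kinetic (Robin) boundary conditions.  The assembled operator is
# symmetric positive definite after elimination of Dirichlet nodes and is
# factorized with a sparse Cholesky decomposition.
#
# Node (i, j) sits at (x[i], y[j]); fields are stored as nx-by-ny matrices.
# An anisotropy factor on the y-fluxes supports the non-dimensional channel
# model, whose vertical coordinate is scaled by the half channel height.
#
# Sign conventions (used consistently everywhere):
#   * boundary current density is positive when current ENTERS the
#     electrolyte, so in a driven cell the anode density is > 0 and the
#     cathode density is < 0;
#   * at the bottom edge the into-domain normal is +y, so the entering
#     density is -sigma * dphi/dy.

#' Boundary condition constructors
#'
#' Conditions attach to the labelled boundary segments of a `grid2d`:
#' the bottom segments `ANODE`, `INSULATOR`, `CATHODE` and the edges
#' `LEFT`, `RIGHT`, `TOP`.  Unlisted segments default to zero flux.
#'
#' * `dirichlet_bc(value)` fixes the potential (scalar, or one value per
#'   segment node).
#' * `zero_flux_bc()` is an insulation/symmetry boundary.
#' * `flux_bc(density)` prescribes the normal current density entering the
#'   electrolyte (A/m^2; scalar or per node).  Only supported on bottom
#'   segments.
#' * `robin_bc(g, rhs)` imposes the linearized kinetic condition
#'   `-sigma dphi/dn = rhs - g * phi` (g >= 0); used internally by the
#'   secondary-model outer iteration.
#'
#' @param value,density,g,rhs numeric scalars or per-node vectors.
#' @return A boundary-condition object.
#' @name boundary_conditions
NULL

#' @rdname boundary_conditions
#' @export
dirichlet_bc <- function(value) {
  stopifnot(is.numeric(value), all(is.finite(value)))
  structure(list(type = "dirichlet", value = value), class = "laplace_bc")
}

#' @rdname boundary_conditions
#' @export
zero_flux_bc <- function() structure(list(type = "zero_flux"), class = "laplace_bc")

#' @rdname boundary_conditions
#' @export
flux_bc <- function(density) {
  stopifnot(is.numeric(density), all(is.finite(density)))
  structure(list(type = "flux", density = density), class = "laplace_bc")
}

#' @rdname boundary_conditions
#' @export
robin_bc <- function(g, rhs) {
  stopifnot(is.numeric(g), all(is.finite(g)), all(g >= 0),
            is.numeric(rhs), all(is.finite(rhs)))
  structure(list(type = "robin", g = g, rhs = rhs), class = "laplace_bc")
}

# Node indices owned by each boundary segment (full closure; corner
# ownership is resolved in solve_laplace by Dirichlet-wins precedence).
segment_nodes <- function(grid, segment) {
  nx <- length(grid$x); ny <- length(grid$y)
  k <- function(i, j) (j - 1L) * nx + i
  switch(segment,
    ANODE     = k(grid$segments$ANODE, 1L),
    INSULATOR = if (length(grid$segments$INSULATOR))
                  k(grid$segments$INSULATOR, 1L) else integer(0),
    CATHODE   = k(grid$segments$CATHODE, 1L),
    BOTTOM    = k(seq_len(nx), 1L),
    LEFT      = k(1L, seq_len(ny)),
    RIGHT     = k(nx, seq_len(ny)),
    TOP       = k(seq_len(nx), ny),
    stop("unknown boundary segment: ", segment)
  )
}

# Control-volume half-widths
cv_widths <- function(v) {
  h <- diff(v)
  c(h[1] / 2, (h[-1] + h[-length(h)]) / 2, h[length(h)] / 2)
}

#' Solve the discrete Laplace problem
#'
#' Assembles the conservative five-point operator for
#' `div(sigma grad phi) = 0` on `grid` and applies the boundary conditions
#' in `bc` (a named list keyed by segment; see [boundary_conditions]).
#' Zero-flux boundaries are natural in the finite-volume form.  At corner
#' nodes claimed by several segments, Dirichlet conditions take precedence
#' over flux-type conditions, and bottom segments over the side/top edges.
#'
#' @param grid a `grid2d`.
#' @param bc named list of boundary conditions; segments not listed get
#'   zero flux.
#' @param sigma electrolyte conductivity (S/m); any positive constant (it
#'   cancels in pure-Dirichlet problems).
#' @param aniso_y factor multiplying the y-direction fluxes; the
#'   non-dimensional channel model uses `1 / G^2`.
#' @return A `potential_field`: list with `grid`, `values` (nx-by-ny
#'   matrix), `sigma`, `aniso_y` and the max-norm residual of the free
#'   equations in `residual`.
#' @examples
#' g <- build_channel_grid(channel_geometry(1, 0.5), n_base = 8, grading = 1)
#' ph <- solve_laplace(g, list(LEFT = dirichlet_bc(1), RIGHT = dirichlet_bc(0)))
#' max(abs(ph$values - (1 - outer(g$x, rep(1, length(g$y))))))  # linear ramp
#' @export
solve_laplace <- function(grid, bc, sigma = 1, aniso_y = 1) {
  stopifnot(inherits(grid, "grid2d"), is.list(bc), sigma > 0, aniso_y > 0)
  x <- grid$x; y <- grid$y
  nx <- length(x); ny <- length(y); N <- nx * ny
  hx <- diff(x); hy <- diff(y)
  wx <- cv_widths(x); wy <- cv_widths(y)

  known <- c("ANODE", "INSULATOR", "CATHODE", "BOTTOM", "LEFT", "RIGHT", "TOP")
  if (length(bad <- setdiff(names(bc), known)))
    stop("unknown boundary segment(s): ", paste(bad, collapse = ", "))
  for (b in bc) stopifnot(inherits(b, "laplace_bc"))

  # interior coupling: x-faces then y-faces, duplicates summed
  ii <- rep(seq_len(nx - 1), ny);        jj <- rep(seq_len(ny), each = nx - 1)
  kA <- (jj - 1L) * nx + ii;             kB <- kA + 1L
  vx <- sigma * wy[jj] / hx[ii]
  i2 <- rep(seq_len(nx), ny - 1);        j2 <- rep(seq_len(ny - 1), each = nx)
  kC <- (j2 - 1L) * nx + i2;             kD <- kC + nx
  vy <- sigma * aniso_y * wx[i2] / hy[j2]

  diag_extra <- numeric(N)
  b_vec <- numeric(N)
  fixed <- logical(N)
  fixed_val <- numeric(N)

  seg_order <- c("TOP", "LEFT", "RIGHT", "BOTTOM", "ANODE", "INSULATOR",
                 "CATHODE")
  per_node <- function(v, n, seg) {
    if (length(v) == 1L) rep(v, n)
    else if (length(v) == n) v
    else stop("boundary values for ", seg, " must have length 1 or ", n)
  }
  has_level <- FALSE
  for (seg in intersect(seg_order, names(bc))) {
    cond <- bc[[seg]]
    nodes <- segment_nodes(grid, seg)
    n <- length(nodes)
    if (n == 0) next
    if (cond$type == "dirichlet") {
      fixed[nodes] <- TRUE
      fixed_val[nodes] <- per_node(cond$value, n, seg)
      has_level <- TRUE
    } else if (cond$type %in% c("flux", "robin")) {
      if (!seg %in% c("ANODE", "INSULATOR", "CATHODE", "BOTTOM", "TOP"))
        stop("flux-type conditions are only supported on horizontal edges")
      i_b <- ((nodes - 1L) %% nx) + 1L
      if (cond$type == "flux") {
        b_vec[nodes] <- b_vec[nodes] + per_node(cond$density, n, seg) * wx[i_b]
      } else {
        g <- per_node(cond$g, n, seg)
        diag_extra[nodes] <- diag_extra[nodes] + g * wx[i_b]
        b_vec[nodes] <- b_vec[nodes] + per_node(cond$rhs, n, seg) * wx[i_b]
        if (any(g > 0)) has_level <- TRUE
      }
    } # zero_flux: natural, nothing to assemble
  }
  if (!has_level)
    stop("singular system: no Dirichlet or Robin condition fixes the potential level")

  A <- Matrix::sparseMatrix(
    i = c(kA, kB, kC, kD, kA, kB, kC, kD, seq_len(N)),
    j = c(kB, kA, kD, kC, kA, kB, kC, kD, seq_len(N)),
    x = c(-vx, -vx, -vy, -vy, vx, vx, vy, vy, diag_extra),
    dims = c(N, N))

  free <- which(!fixed)
  phi <- numeric(N)
  phi[fixed] <- fixed_val[fixed]
  if (length(free)) {
    rhs <- b_vec[free]
    if (any(fixed))
      rhs <- rhs - as.numeric(A[free, fixed, drop = FALSE] %*% fixed_val[fixed])
    Aff <- Matrix::forceSymmetric(A[free, free, drop = FALSE])
    sol <- tryCatch(
      as.numeric(Matrix::solve(Matrix::Cholesky(Aff, LDL = FALSE), rhs,
                               system = "A")),
      error = function(e) as.numeric(Matrix::solve(Aff, rhs)))
    phi[free] <- sol
    res <- max(abs(A[free, , drop = FALSE] %*% phi - b_vec[free]))
    scale <- max(abs(b_vec[free]), max(abs(vx)) * max(abs(phi)), 1e-300)
    residual <- res / scale
    if (!is.finite(residual) || residual > 1e-8)
      stop(sprintf("linear solve did not converge (relative residual %.3g)",
                   residual))
  } else residual <- 0

  structure(list(grid = grid,
                 values = matrix(phi, nrow = nx, ncol = ny),
                 sigma = sigma, aniso_y = aniso_y, residual = residual),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("<potential_field> %d x %d nodes, range [%.6g, %.6g], residual %.2g\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values),
              x$residual))
  invisible(x)
}

# Sparse differentiation matrix along a coordinate vector: second-order
# three-point formulas, central in the interior, one-sided at the ends.
deriv_matrix <- function(v) {
  n <- length(v)
  ii <- jj <- vv <- vector("list", n)
  for (k in seq_len(n)) {
    if (k == 1L) s <- 1:3 else if (k == n) s <- (n - 2):n else s <- (k - 1):(k + 1)
    x0 <- v[s] - v[k]
    # derivative weights of the quadratic through three points
    d <- vapply(1:3, function(m) {
      others <- x0[-m]
      (sum(-others)) / prod(x0[m] - others)
    }, numeric(1))
    ii[[k]] <- rep(k, 3); jj[[k]] <- s; vv[[k]] <- d
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(n, n))
}

#' Electric field from a potential field
#'
#' `E = -grad(phi)` by second-order differences: central in the interior,
#' one-sided at boundary nodes.  For the non-dimensional channel model the
#' vertical component must be rescaled by the aspect ratio
#' (`y_scale = 1 / G`), since the grid's Y coordinate is in units of the
#' half channel height while the field is referred to the electrode length.
#'
#' @param phi a `potential_field`.
#' @param y_scale factor applied to the y-derivative (default 1).
#' @return An `electric_field`: list with `grid`, `ex`, `ey`, `magnitude`
#'   (nx-by-ny matrices).
#' @export
electric_field <- function(phi, y_scale = 1) {
  stopifnot(inherits(phi, "potential_field"))
  g <- phi$grid
  Dx <- deriv_matrix(g$x)
  Dy <- deriv_matrix(g$y)
  ex <- -as.matrix(Dx %*% phi$values)
  ey <- -as.matrix(Matrix::tcrossprod(phi$values, Dy)) * y_scale
  structure(list(grid = g, ex = ex, ey = ey,
                 magnitude = sqrt(ex^2 + ey^2)),
            class = "electric_field")
}

#' @export
print.electric_field <- function(x, ...) {
  cat(sprintf("<electric_field> %d x %d nodes, |E| in [%.6g, %.6g]\n",
              nrow(x$magnitude), ncol(x$magnitude),
              min(x$magnitude), max(x$magnitude)))
  invisible(x)
}

#' Boundary current density and integrated current on a bottom segment
#'
#' The normal current density entering the electrolyte through the bottom
#' edge is `-sigma dphi/dy`, evaluated with a second-order one-sided
#' difference; the integrated current (A per metre of depth) is its
#' trapezoidal integral over the segment.
#'
#' @param phi a `potential_field`.
#' @param sigma electrolyte conductivity, S/m.
#' @param segment `"ANODE"`, `"CATHODE"`, `"INSULATOR"`, `"BOTTOM"` (whole
#'   bottom edge) or `"TOP"`.
#' @return A `boundary_current`: list with `segment`, `x`, `density`
#'   (A/m^2, positive entering the electrolyte) and `current` (A/m).
#' @export
boundary_current <- function(phi, sigma, segment) {
  stopifnot(inherits(phi, "potential_field"), sigma > 0)
  g <- phi$grid
  nx <- length(g$x); ny <- length(g$y)
  idx <- switch(segment,
                BOTTOM = seq_len(nx),
                TOP = seq_len(nx),
                # the INSULATOR segment owns the open interval between the
                # junctions; its integral includes the junction nodes as end
                # points so the three bottom segments tile the bottom edge
                INSULATOR = if (length(g$segments$INSULATOR))
                  c(max(g$segments$ANODE), g$segments$INSULATOR,
                    min(g$segments$CATHODE)) else integer(0),
                g$segments[[segment]])
  if (is.null(idx)) stop("unknown segment: ", segment)
  if (length(idx) < 2) stop("zero-length segment: ", segment)
  y <- if (segment == "TOP") rev(g$y[(ny - 2):ny]) else g$y
  h1 <- abs(y[2] - y[1]); h2 <- abs(y[3] - y[2])
  c0 <- -(2 * h1 + h2) / (h1 * (h1 + h2))
  c1 <- (h1 + h2) / (h1 * h2)
  c2 <- -h1 / (h2 * (h1 + h2))
  cols <- if (segment == "TOP") c(ny, ny - 1L, ny - 2L) else 1:3
  # derivative along the inward normal; entering density is -sigma * that
  dphidn <- c0 * phi$values[idx, cols[1]] + c1 * phi$values[idx, cols[2]] +
    c2 * phi$values[idx, cols[3]]
  density <- -sigma * dphidn
  xs <- g$x[idx]
  current <- sum((density[-1] + density[-length(density)]) / 2 * diff(xs))
  structure(list(segment = segment, x = xs, density = density,
                 current = current),
            class = "boundary_current")
}

#' @export
print.boundary_current <- function(x, ...) {
  cat(sprintf("<boundary_current> %s: integrated %.6g A/m over %d nodes\n",
              x$segment, x$current, length(x$x)))
  invisible(x)
}

#' Export a field snapshot as CSV
#'
#' Writes `(x, y, value)` triplets with a one-line comment header naming
#' the quantity and units.
#'
#' @param field a `potential_field` or `electric_field`.
#' @param path output file.
#' @param quantity,units header strings.
#' @export
write_field_csv <- function(field, path, quantity = "potential",
                            units = if (inherits(field, "potential_field")) "V" else "V/m") {
  vals <- if (inherits(field, "potential_field")) field$values else field$magnitude
  g <- field$grid
  df <- data.frame(x = rep(g$x, times = length(g$y)),
                   y = rep(g$y, each = length(g$x)),
                   value = as.vector(vals))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s [%s]", quantity, units), con)
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
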