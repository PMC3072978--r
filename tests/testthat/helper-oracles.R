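# Independent oracles used across the test files.

# Brute-force dense solve of the conservative five-point balance equations
# on a grid2d, written with plain loops and base-R solve(), independently of
# the package's sparse assembly.  bc: named list of package bc objects
# (Dirichlet and zero-flux only).
dense_laplace_oracle <- function(grid, bc, sigma = 1, aniso_y = 1) {
  x <- grid$x; y <- grid$y
  nx <- length(x); ny <- length(y); N <- nx * ny
  k <- function(i, j) (j - 1) * nx + i
  half <- function(v, i) {
    h <- diff(v)
    if (i == 1) h[1] / 2
    else if (i == length(v)) h[length(h)] / 2
    else (h[i - 1] + h[i]) / 2
  }
  A <- matrix(0, N, N); b <- numeric(N)
  dir_val <- rep(NA_real_, N)
  node_sets <- list(
    ANODE = if (length(grid$segments$ANODE)) k(grid$segments$ANODE, 1) else integer(0),
    INSULATOR = if (length(grid$segments$INSULATOR)) k(grid$segments$INSULATOR, 1) else integer(0),
    CATHODE = if (length(grid$segments$CATHODE)) k(grid$segments$CATHODE, 1) else integer(0),
    LEFT = k(1, 1:ny), RIGHT = k(nx, 1:ny), TOP = k(1:nx, ny))
  for (seg in c("TOP", "LEFT", "RIGHT", "ANODE", "INSULATOR", "CATHODE")) {
    cond <- bc[[seg]]
    if (is.null(cond) || cond$type != "dirichlet") next
    nodes <- node_sets[[seg]]
    v <- cond$value
    if (length(v) == 1) v <- rep(v, length(nodes))
    dir_val[nodes] <- v
  }
  for (j in 1:ny) for (i in 1:nx) {
    r <- k(i, j)
    if (!is.na(dir_val[r])) { A[r, r] <- 1; b[r] <- dir_val[r]; next }
    wyj <- half(y, j); wxi <- half(x, i)
    if (i > 1) { g <- sigma * wyj / (x[i] - x[i - 1]); A[r, k(i - 1, j)] <- A[r, k(i - 1, j)] - g; A[r, r] <- A[r, r] + g }
    if (i < nx) { g <- sigma * wyj / (x[i + 1] - x[i]); A[r, k(i + 1, j)] <- A[r, k(i + 1, j)] - g; A[r, r] <- A[r, r] + g }
    if (j > 1) { g <- sigma * aniso_y * wxi / (y[j] - y[j - 1]); A[r, k(i, j - 1)] <- A[r, k(i, j - 1)] - g; A[r, r] <- A[r, r] + g }
    if (j < ny) { g <- sigma * aniso_y * wxi / (y[j + 1] - y[j]); A[r, k(i, j + 1)] <- A[r, k(i, j + 1)] - g; A[r, r] <- A[r, r] + g }
  }
  matrix(solve(A, b), nx, ny)
}

# Exact harmonic reference for the manufactured-solution convergence test.
manufactured_phi <- function(x, y) outer(sin(pi * x), sinh(pi * y)) / sinh(pi)

# Dirichlet data of the manufactured solution on all boundary segments of a
# channel grid.
manufactured_bc <- function(grid) {
  f <- function(xv, yv) sin(pi * xv) * sinh(pi * yv) / sinh(pi)
  list(ANODE = dirichlet_bc(f(grid$x[grid$segments$ANODE], 0)),
       INSULATOR = if (length(grid$segments$INSULATOR))
         dirichlet_bc(f(grid$x[grid$segments$INSULATOR], 0)) else zero_flux_bc(),
       CATHODE = dirichlet_bc(f(grid$x[grid$segments$CATHODE], 0)),
       LEFT = dirichlet_bc(f(0, grid$y)),
       RIGHT = dirichlet_bc(f(1, grid$y)),
       TOP = dirichlet_bc(f(grid$x, 1)))
}
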