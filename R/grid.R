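# Structured tensor-product grids with boundary-segment labelling.
#
# Both current distribution models share one domain layout (a single
# anode-insulator-cathode period): the bottom edge is partitioned
# left-to-right into ANODE, INSULATOR, CATHODE; the left, right and top
# edges are zero-flux (symmetry / far-field) boundaries.  The electric field
# is singular at the two insulator-electrode junctions, so node spacing is
# graded toward them (and toward the bottom edge in y).

#' Graded node coordinates on an interval
#'
#' Power-law grading: nodes are the image of a uniform parameter under
#' `t^p`, concentrating nodes at the refined end(s).  `p = 1` is uniform.
#' Power-law grading is the standard choice for corner singularities of a
#' potential problem, keeps the spacing ratio bounded (`~ n^(p-1)`), and is
#' exactly nested under doubling of `n`, which makes mesh-convergence
#' studies a direct node-wise comparison.
#'
#' @param from,to interval end points (`from < to`).
#' @param n number of intervals (>= 1; even when `toward = "both"`).
#' @param p grading exponent (>= 1); spacing is non-increasing toward the
#'   refined end.
#' @param toward `"from"`, `"to"` or `"both"` (refine both ends; places a
#'   node exactly at the midpoint).
#' @return numeric vector of `n + 1` strictly increasing coordinates.
#' @keywords internal
graded_points <- function(from, to, n, p = 3, toward = c("to", "from", "both")) {
  toward <- match.arg(toward)
  stopifnot(from < to, n >= 1, p >= 1)
  if (toward == "both") {
    if (n %% 2 != 0) stop("n must be even for two-sided grading")
    mid <- (from + to) / 2
    return(c(graded_points(from, mid, n / 2, p, "from"),
             graded_points(mid, to, n / 2, p, "to")[-1]))
  }
  t <- (seq_len(n + 1) - 1) / n
  if (toward == "to") to - (to - from) * rev(t^p) else from + (to - from) * t^p
}

# Internal grid constructor shared by both builders.
# a, b: junction abscissae; L: bottom length; H: height; unit: "nd" or "m".
new_grid2d <- function(a, b, L, H, n_base, grading, unit) {
  if (n_base < 8) stop("n_base must be >= 8")
  n_e <- n_base
  n_i <- if (b > a) max(4L, 2L * ceiling(n_base / 4)) else 0L
  n_y <- 2L * n_base
  if (b > a) {
    x <- c(graded_points(0, a, n_e, grading, "to"),
           graded_points(a, b, n_i, grading, "both")[-1],
           graded_points(b, L, n_e, grading, "from")[-1])
  } else {
    x <- c(graded_points(0, a, n_e, grading, "to"),
           graded_points(b, L, n_e, grading, "from")[-1])
  }
  y <- graded_points(0, H, n_y, grading, "from")
  nx <- length(x)
  # bottom-node ownership; electrode labels win at the junction nodes
  tol <- 1e-12 * max(L, 1)
  anode <- which(x <= a + tol)
  cathode <- which(x >= b - tol)
  if (b > a) {
    insulator <- setdiff(seq_len(nx), c(anode, cathode))
  } else {
    # singular zero-width insulator: electrodes meet at one junction node,
    # assigned to the anode segment by the stated precedence
    junction <- intersect(anode, cathode)
    cathode <- setdiff(cathode, junction)
    insulator <- integer(0)
  }
  if (length(anode) < 2 || length(cathode) < 2)
    stop("epsilon too close to 1: an electrode segment has fewer than 2 nodes")
  if (any(diff(x) <= 0) || any(diff(y) <= 0))
    stop("epsilon too close to 1: electrode segments cannot be resolved ",
         "into distinct node coordinates")
  g <- structure(list(
    x = x, y = y, unit = unit,
    segments = list(ANODE = anode, INSULATOR = insulator, CATHODE = cathode),
    junctions = c(a, b),
    n_base = n_base, grading = grading
  ), class = "grid2d")
  g
}

#' Build the non-dimensional channel grid
#'
#' Discretizes the unit-length channel domain of the primary current
#' distribution model.  The bottom edge is partitioned as ANODE on
#' `[0, (1 - eps)/2]`, INSULATOR on `((1 - eps)/2, (1 + eps)/2)` and CATHODE
#' on `[(1 + eps)/2, 1]`; the top edge (the channel mid-plane) lies at
#' `Y = 1` in units of the half channel height.  Node lines are placed
#' exactly at the two insulator junction abscissae and at `X = 0.5`.
#'
#' @param geom a [channel_geometry()].
#' @param n_base node-count control: intervals per electrode segment
#'   (>= 8); the insulator receives `~ n_base / 2` intervals and the
#'   vertical direction `2 * n_base`.
#' @param grading power-law grading exponent toward the insulator-electrode
#'   junctions and the bottom edge; `1` gives uniform spacing within each
#'   segment.
#' @return A `grid2d` object.
#' @examples
#' g <- build_channel_grid(channel_geometry(1, 0.5), n_base = 16)
#' range(g$x[g$segments$ANODE])   # [0, 0.25]
#' @export
build_channel_grid <- function(geom, n_base = 48, grading = 3) {
  stopifnot(inherits(geom, "channel_geometry"))
  a <- (1 - geom$epsilon) / 2
  b <- (1 + geom$epsilon) / 2
  g <- new_grid2d(a, b, 1, 1, n_base, grading, unit = "nd")
  g$geom <- geom
  g
}

#' Build the dimensional secondary-cell grid
#'
#' Same layout as [build_channel_grid()] but in metres, with the insulator
#' centred at `x = length / 2` and the zero-flux top edge at `y = height`.
#'
#' @param geom a [secondary_geometry()].
#' @inheritParams build_channel_grid
#' @return A `grid2d` object.
#' @examples
#' g <- build_secondary_grid(secondary_geometry(), n_base = 16)
#' g$junctions * 1e6   # insulator spans [4.95, 5.05] um
#' @export
build_secondary_grid <- function(geom, n_base = 32, grading = 3) {
  stopifnot(inherits(geom, "secondary_geometry"))
  L <- geom$length
  a <- (L - geom$insulator_thickness) / 2
  b <- (L + geom$insulator_thickness) / 2
  g <- new_grid2d(a, b, L, geom$height, n_base, grading, unit = "m")
  g$geom <- geom
  g
}

#' Bisect every grid interval once
#'
#' Halves every interval in both directions, so the coarse grid nodes are an
#' exact subset of the refined grid nodes.
#'
#' @param grid a `grid2d`.
#' @return The refined `grid2d`.
#' @export
refine_grid <- function(grid) {
  stopifnot(inherits(grid, "grid2d"))
  bisect <- function(v) sort(unique(c(v, (v[-1] + v[-length(v)]) / 2)))
  out <- grid
  out$x <- bisect(grid$x)
  out$y <- bisect(grid$y)
  nx <- length(out$x)
  tol <- 1e-12 * max(out$x[nx], 1)
  a <- grid$junctions[1]; b <- grid$junctions[2]
  anode <- which(out$x <= a + tol)
  cathode <- which(out$x >= b - tol)
  if (b > a) {
    insulator <- setdiff(seq_len(nx), c(anode, cathode))
  } else {
    cathode <- setdiff(cathode, intersect(anode, cathode))
    insulator <- integer(0)
  }
  out$segments <- list(ANODE = anode, INSULATOR = insulator, CATHODE = cathode)
  out
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %d x %d nodes (%s), bottom: ANODE %d | INSULATOR %d | CATHODE %d nodes\n",
              length(x$x), length(x$y),
              if (x$unit == "m") "metres" else "non-dimensional",
              length(x$segments$ANODE), length(x$segments$INSULATOR),
              length(x$segments$CATHODE)))
  invisible(x)
}

#' Lengths of the bottom boundary segments
#'
#' @param grid a `grid2d`.
#' @return Named numeric vector of ANODE, INSULATOR and CATHODE segment
#'   lengths; they sum to the bottom-edge length.
#' @export
segment_lengths <- function(grid) {
  a <- grid$junctions[1]; b <- grid$junctions[2]
  L <- grid$x[length(grid$x)]
  c(ANODE = a, INSULATOR = b - a, CATHODE = L - b)
}
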