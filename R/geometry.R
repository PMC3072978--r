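#' Non-dimensional channel geometry
#'
#' The primary current distribution model of the micro-electroporation
#' channel is governed by two dimensionless numbers: the aspect ratio
#' `G = h / l` (half channel height over active electrode length) and the
#' relative insulator thickness `epsilon = d / l` (insulator width over
#' active electrode length).  `epsilon = 0` encodes the idealized singular
#' configuration in which anode and cathode meet at a point.
#'
#' @param G aspect ratio, `h / l`; must be positive.  Small `G` (shallow
#'   channels) is the high-field regime.
#' @param epsilon relative insulator thickness, `d / l`; must satisfy
#'   `0 <= epsilon < 1`.
#' @return An object of class `channel_geometry`.
#' @examples
#' channel_geometry(G = 0.1, epsilon = 0.5)
#' @export
channel_geometry <- function(G, epsilon) {
  stopifnot(is.numeric(G), length(G) == 1L, is.finite(G),
            is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  if (G <= 0) stop("aspect ratio G must be > 0")
  if (epsilon < 0 || epsilon >= 1)
    stop("relative insulator thickness epsilon must be in [0, 1)")
  structure(list(G = G, epsilon = epsilon), class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> G = %g, epsilon = %g%s\n", x$G, x$epsilon,
              if (x$epsilon == 0) " (singular zero-width insulator)" else ""))
  invisible(x)
}

#' Dimensional geometry of the secondary current distribution cell
#'
#' Geometry of the singularity-induced micro-electroporation configuration:
#' a rectangular electrolyte domain with anode, insulator and cathode
#' partitioning the bottom edge (insulator centred) and zero-flux walls
#' elsewhere.  Defaults are the platinum/water study configuration: a domain
#' 10 um long and 20 um high with a 100 nm insulator.
#'
#' @param length domain length along the electrode plane, metres.
#' @param insulator_thickness insulator width, metres; must be positive and
#'   smaller than `length`.
#' @param height domain height, metres.
#' @return An object of class `secondary_geometry`.
#' @examples
#' secondary_geometry()
#' @export
secondary_geometry <- function(length = 10e-6, insulator_thickness = 100e-9,
                               height = 20e-6) {
  stopifnot(is.numeric(length), is.numeric(insulator_thickness),
            is.numeric(height))
  if (!(insulator_thickness > 0 && insulator_thickness < length))
    stop("need 0 < insulator_thickness < length")
  if (height <= 0) stop("height must be > 0")
  structure(list(length = length,
                 insulator_thickness = insulator_thickness,
                 height = height),
            class = "secondary_geometry")
}

#' @export
print.secondary_geometry <- function(x, ...) {
  cat(sprintf("<secondary_geometry> %g um long, %g nm insulator, %g um high\n",
              x$length * 1e6, x$insulator_thickness * 1e9, x$height * 1e6))
  invisible(x)
}
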