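# Plain-text configuration (key = value) and CSV output.
#
# The configuration interface accepts SI units (m, V, S/m); results are
# reported in the field's customary units (kV/cm for fields, uW/cm^2 for
# power).  Every run is deterministic: the same config always produces
# byte-identical output.

config_keys <- list(
  model = "character",          # "primary" or "secondary"
  G = "numeric",                # primary: aspect ratios (comma list)
  epsilon = "numeric",          # primary: relative insulator thicknesses
  length_m = "numeric",         # secondary geometry
  insulator_m = "numeric",
  height_m = "numeric",
  sigma = "numeric",            # secondary: conductivities, S/m
  V_app = "numeric",            # secondary: applied voltages, V
  i0_anode = "numeric",         # kinetics overrides
  i0_cathode = "numeric",
  alpha_anode = "numeric",
  alpha_cathode = "numeric",
  E_eq_anode = "numeric",
  E_eq_cathode = "numeric",
  T = "numeric",
  n_base = "numeric",           # numerics
  grading = "numeric",
  outer_tol = "numeric",
  max_outer = "numeric",
  v_step = "numeric",
  out = "character",            # output paths
  profile_out = "character"
)

#' Read a run configuration
#'
#' Plain-text `key = value` format; `#` starts a comment; commas separate
#' multiple values.  Unknown keys are an error (not a warning), so typos
#' cannot silently fall back to defaults.  Documented keys: `model`
#' (primary/secondary), `G`, `epsilon`, `length_m`, `insulator_m`,
#' `height_m`, `sigma`, `V_app`, kinetic overrides (`i0_anode`,
#' `i0_cathode`, `alpha_anode`, `alpha_cathode`, `E_eq_anode`,
#' `E_eq_cathode`, `T`), numerics (`n_base`, `grading`, `outer_tol`,
#' `max_outer`, `v_step`) and output paths (`out`, `profile_out`).
#'
#' @param path config file.
#' @return Named list of parsed values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected 'key = value'): ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(config_keys))
      stop("unknown config key '", key, "'; accepted keys: ",
           paste(names(config_keys), collapse = ", "))
    if (config_keys[[key]] == "numeric") {
      v <- suppressWarnings(as.numeric(trimws(strsplit(val, ",")[[1]])))
      if (anyNA(v)) stop("non-numeric value for key '", key, "': ", val)
      cfg[[key]] <- v
    } else {
      cfg[[key]] <- val
    }
  }
  cfg
}

cfg_get <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Run a model from a configuration
#'
#' Executes the sweep requested by a config file (or an equivalent named
#' list) and writes the results as CSV.  For `model = primary` a
#' `(G, epsilon)` sweep is written to `out`.  For `model = secondary` a
#' `(sigma, V_app)` sweep is written to `out`, and, if `profile_out` is
#' set, one centerline field profile per conductivity (at the highest
#' applied voltage) is written to files derived from `profile_out` by
#' inserting the conductivity.
#'
#' Any non-converged mandatory solve raises an error after the table is
#' written.
#'
#' @param config path to a config file, or a named list as returned by
#'   [read_run_config()].
#' @return Invisibly, the paths of the files written.
#' @export
run_from_config <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  model <- cfg_get(cfg, "model", NULL)
  if (is.null(model) || !model %in% c("primary", "secondary"))
    stop("config must set model = primary or model = secondary")
  out <- cfg_get(cfg, "out", NULL)
  if (is.null(out)) stop("config must set an output path: out = <file>")
  n_base <- cfg_get(cfg, "n_base", if (model == "primary") 48 else 32)
  grading <- cfg_get(cfg, "grading", 3)
  written <- character(0)

  if (model == "primary") {
    G <- cfg_get(cfg, "G", NULL); eps <- cfg_get(cfg, "epsilon", NULL)
    if (is.null(G) || is.null(eps))
      stop("primary model config needs keys G and epsilon")
    tab <- sweep_primary(G, eps, n_base = n_base, grading = grading)
    write_sweep_csv(tab, out, params = cfg)
    written <- out
  } else {
    sigma <- cfg_get(cfg, "sigma", NULL); V <- cfg_get(cfg, "V_app", NULL)
    if (is.null(sigma) || is.null(V))
      stop("secondary model config needs keys sigma and V_app")
    kin <- platinum_water(
      i0_anode = cfg_get(cfg, "i0_anode", 1e-8),
      i0_cathode = cfg_get(cfg, "i0_cathode", 10),
      alpha_anode = cfg_get(cfg, "alpha_anode", 1),
      alpha_cathode = cfg_get(cfg, "alpha_cathode", 1),
      E_eq_anode = cfg_get(cfg, "E_eq_anode", 1.23),
      E_eq_cathode = cfg_get(cfg, "E_eq_cathode", -0.83),
      T = cfg_get(cfg, "T", 298))
    geom <- secondary_geometry(
      length = cfg_get(cfg, "length_m", 10e-6),
      insulator_thickness = cfg_get(cfg, "insulator_m", 100e-9),
      height = cfg_get(cfg, "height_m", 20e-6))
    tab <- sweep_secondary(sigma, V, geometry = geom, kinetics = kin,
                           n_base = n_base, grading = grading,
                           outer_tol = cfg_get(cfg, "outer_tol", 1e-7),
                           max_outer = cfg_get(cfg, "max_outer", 60),
                           v_step = cfg_get(cfg, "v_step", 0.1))
    write_sweep_csv(tab, out, params = cfg)
    written <- out
    profile_out <- cfg_get(cfg, "profile_out", NULL)
    if (!is.null(profile_out)) {
      for (s in sigma) {
        spec <- secondary_spec(geometry = geom, kinetics = kin,
                               sigma = s, V_app = max(V))
        sol <- solve_secondary(spec, n_base = n_base, grading = grading)
        pr <- centerline_profile(sol)
        pth <- sub("(\\.[^.]*)?$", sprintf("_sigma%g\\1", s), profile_out)
        write_profile_csv(pr, pth, params = c(cfg, list(sigma_used = s)))
        written <- c(written, pth)
      }
    }
    if (any(!tab$converged))
      stop("one or more solves did not converge; table written to ", out)
  }
  invisible(written)
}

format_sig12 <- function(x) {
  if (is.numeric(x)) sprintf("%.12g", x) else as.character(x)
}

write_commented_csv <- function(df, path, params) {
  if (is.null(df) || nrow(df) == 0) stop("refusing to write an empty table")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params)) {
    v <- params[[k]]
    writeLines(sprintf("# %s = %s", k,
                       paste(vapply(v, format_sig12, character(1)),
                             collapse = ",")), con)
  }
  out <- as.data.frame(lapply(df, function(col) {
    vapply(col, format_sig12, character(1))
  }), stringsAsFactors = FALSE)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sweep table / centerline profile as CSV
#'
#' RFC-4180 CSV with `#`-prefixed comment lines carrying the parameters
#' that produced the table, a fixed column order, and 12 significant
#' digits.
#'
#' @param table,profile the `data.frame` to write.
#' @param path output file.
#' @param params named list echoed into the comment header.
#' @return Invisibly, `path`.
#' @export
write_sweep_csv <- function(table, path, params = list()) {
  write_commented_csv(table, path, params)
}

#' @rdname write_sweep_csv
#' @export
write_profile_csv <- function(profile, path, params = list()) {
  write_commented_csv(profile, path, params)
}

#' Read back a CSV written by the sweep/profile writers
#'
#' @param path file written by [write_sweep_csv()] or
#'   [write_profile_csv()].
#' @return `data.frame` (comment header skipped).
#' @export
read_sweep_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
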