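#' Default physical and numerical configuration
#'
#' Returns the full set of model parameters with their defaults: an adult
#' African elephant trunk of ~100 kg and 185 cm modelled backbone length,
#' apparent Young's modulus 1e6 N/m^2 (optionally split into proximal /
#' middle / distal regions of three segments each), radii tapering linearly
#' from 0.15 m at the base to 0.05 m at the tip, classification thresholds
#' of 20 deg/m (curvature) and 0.02 m (elongation), and a 100 Hz sampling
#' rate.
#'
#' @return A named list of class `trunk_config`. Fields:
#' \describe{
#'   \item{total_mass}{kg, mass distributed over the nodes (default 100).}
#'   \item{total_length}{m, modelled backbone length spanning the 9 segments
#'     (default 1.85).}
#'   \item{base_radius, tip_radius}{m, cross-section semi-axis at the most
#'     proximal / most distal section (defaults 0.15 and 0.05).}
#'   \item{n_sections}{number of cross-sections (default 10; 5 nodes each).}
#'   \item{E_proximal, E_middle, E_distal}{N/m^2, apparent Young's modulus of
#'     the three trunk regions (defaults all 1e6).}
#'   \item{area_fraction_longitudinal, area_fraction_radial,
#'     area_fraction_connective}{dimensionless fractions of the local
#'     cross-section area pi*a*b assigned to each rod type (0.15, 0.10,
#'     0.05).}
#'   \item{damping}{s^-1, coefficient c of the mass-proportional viscous term
#'     C = c*M (default 2; set 0 for undamped). Damps slow, gross motion.}
#'   \item{damping_beta}{s, coefficient of the stiffness-proportional
#'     (Kelvin-Voigt) term: each rod carries an axial viscous force
#'     beta*k*d(len)/dt (default 0.005; set 0 for undamped). Damps the
#'     high-frequency ringing of the stiff axial/radial modes that
#'     piecewise-constant force input would otherwise excite.}
#'   \item{gravity}{m/s^2 (default 9.81; set 0 to disable).}
#'   \item{k_thresh_bend}{deg/m, bending classification threshold (20).}
#'   \item{l_thresh_elong}{m, elongation classification threshold (0.02).}
#'   \item{sample_rate}{Hz, default trial/controller sampling rate (100).}
#'   \item{force_bound}{N, box bound on estimated active forces (5000).}
#'   \item{solver_rtol, solver_atol}{integration tolerances (1e-6, 1e-9).}
#'   \item{max_iter}{maximum optimizer iterations per timestep (200).}
#' }
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$total_mass
default_config <- function() {
  structure(list(
    total_mass = 100,
    total_length = 1.85,
    base_radius = 0.15,
    tip_radius = 0.05,
    n_sections = 10L,
    E_proximal = 1e6,
    E_middle = 1e6,
    E_distal = 1e6,
    area_fraction_longitudinal = 0.15,
    area_fraction_radial = 0.10,
    area_fraction_connective = 0.05,
    damping = 2,
    damping_beta = 0.005,
    gravity = 9.81,
    k_thresh_bend = 20,
    l_thresh_elong = 0.02,
    sample_rate = 100,
    force_bound = 5000,
    solver_rtol = 1e-6,
    solver_atol = 1e-9,
    max_iter = 200L
  ), class = "trunk_config")
}

# keys that must be strictly positive
.positive_keys <- c(
  "total_mass", "total_length", "base_radius", "tip_radius", "n_sections",
  "E_proximal", "E_middle", "E_distal",
  "area_fraction_longitudinal", "area_fraction_radial",
  "area_fraction_connective",
  "k_thresh_bend", "l_thresh_elong", "sample_rate", "force_bound",
  "solver_rtol", "solver_atol", "max_iter"
)

#' Validate a configuration list
#'
#' Strict schema check: unknown keys are rejected (a typo in a physical
#' constant must fail loudly, not silently fall back to a default), physical
#' values must be positive, `damping` and `gravity` non-negative.
#'
#' @param config named list of overrides or a full config.
#' @return A complete, validated `trunk_config` (defaults filled in).
#' @export
validate_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(base, config)
  for (key in names(cfg)) {
    val <- cfg[[key]]
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val)) {
      stop("config key '", key, "' must be a single finite number")
    }
  }
  for (key in .positive_keys) {
    if (cfg[[key]] <= 0) stop("config key '", key, "' must be positive")
  }
  if (cfg$damping < 0) stop("config key 'damping' must be non-negative")
  if (cfg$damping_beta < 0) {
    stop("config key 'damping_beta' must be non-negative")
  }
  if (cfg$gravity < 0) stop("config key 'gravity' must be non-negative")
  cfg$n_sections <- as.integer(cfg$n_sections)
  if (cfg$n_sections < 2) stop("config key 'n_sections' must be at least 2")
  class(cfg) <- "trunk_config"
  cfg
}

#' Load a configuration file
#'
#' Reads a YAML (or JSON) key-value file, fills defaults and validates
#' strictly; an empty file yields the full default configuration.
#'
#' @param path path to a YAML/JSON config file.
#' @return A validated `trunk_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(txt))) return(default_config())
  cfg <- if (grepl("^\\s*\\{", txt)) {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else {
    yaml::yaml.load(txt)
  }
  validate_config(cfg)
}
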