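#' Model configuration
#'
#' Constructs the complete run configuration for the V1-to-MT network:
#' connection gains, decay rates, activity thresholds, spatiotemporal filter
#' parameters, lattice geometry, and numerics. The defaults reproduce the
#' published constant-parameter table of the model; every field can be
#' overridden by name.
#'
#' Time is expressed in one abstract unit throughout (the printed "ms"
#' labels of the source model are taken at face value as that same unit);
#' one lattice step equals one filter-grid pixel.
#'
#' The two gains `G_igcs` (form input from extra-classical-RF cells to MT
#' integration neurons) and `G_sges` (end-stopped inhibition of MT
#' segmentation neurons) are the model's *variable* parameters: sweeping
#' them moves MT cells between component- and pattern-motion selectivity.
#'
#' @param ... Named overrides of any configuration field.
#' @return An object of class `mt_config`: a validated named list.
#' @examples
#' cfg <- model_config()
#' cfg$G_iges
#' model_config(G_igcs = 0.8, G_sges = 0.1)$G_igcs
#' @export
model_config <- function(...) {
  cfg <- list(
    # -- gains: V1 end-stopped stage
    G_escx1 = 2,    # complex -> end-stopped drive
    G_escx2 = 3,    # lateral inhibition onto end-stopped cells
    # -- gains: into / within MT integration
    G_igcx  = 0.5,  # complex V1 -> integration
    G_iges  = 0.7,  # end-stopped V1 -> integration
    G_igig2 = 0.2,  # same-direction neighbour excitation (lambda)
    G_igig1 = 1,    # inter-directional inhibition (gamma)
    G_igig3 = 1,    # long-range same-direction inhibition (zeta)
    G_igsg  = 0.1,  # segmentation -> integration inhibition
    G_igcs  = 0.1,  # VARIABLE: gated form input (kappa) -> integration
    # -- gains: into / within MT segmentation
    G_sgcx  = 1,    # complex V1 -> segmentation
    G_sges  = 0.8,  # VARIABLE: end-stopped inhibition of segmentation
    G_sgig  = 0.5,  # integration -> segmentation excitation (eta)
    G_sgsg1 = 0.1,  # surround facilitation, same direction (chi_e)
    G_sgsg2 = 0.2,  # surround suppression, opposite direction (chi_i)
    # -- decay rates and thresholds
    tau_es  = 0.01,
    tau_ig  = 0.2,
    tau_sg  = 0.2,
    c_cx    = 0.12, # threshold on complex activity (end-stopped gate)
    c_sg    = 0.02, # threshold on segmentation activity entering sums
    c_ig    = 0.05, # threshold on integration activity entering sums
    # -- numerics
    dt      = 0.01, # Euler step, time units
    T_ig    = 0.1,  # delay of inhibition between MT integration neurons
    # -- spatiotemporal filters
    tau_g   = 0.01, # temporal-filter time constant
    n_fast  = 6L,   # stages of the fast temporal filter
    n_slow  = 9L,   # stages of the slow temporal filter
    f       = 1.1,  # Gabor spatial frequency, cycles/degree
    energy_gain = 0.3, # complex activity at the calibration-stimulus peak
    sigma_x = 0.5,  # Gabor envelope sd (degrees)
    sigma_y = 0.5,
    # -- extra-classical-RF difference-of-Gaussians (degrees)
    A_C      = 1,
    A_S      = 0.72,
    sigma_xc = 0.35,
    sigma_yc = 0.4,
    sigma_xs = 0.4,
    sigma_ys = 0.5,
    # -- geometry
    N_dir            = 8L,
    grid_shape       = c(64L, 64L), # (rows, cols) of the V1 lattice
    px_per_deg       = 4,           # lattice steps per degree of visual angle
    v1_rf_px         = 5,           # nominal V1 RF diameter, lattice steps
    mt_rf_scale      = 7,           # MT centre RF AREA in V1-RF units
    mt_surround_scale = 10,         # MT surround AREA in V1-RF units
    es_patch_radius  = 4L,          # end-stopped inhibition patch (+-4)
    es_gate_radius   = 3L,          # end-stopped gate neighbourhood (+-3)
    gamma_weighting  = "uniform",   # or "cosine"
    lambda_mass      = 2.65,           # total weight of the lambda centre kernel
    gamma_mass       = 0.4,         # total weight of the gamma centre kernel
    zeta_mass        = 0.35,        # total weight of the zeta surround kernel
    seed             = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all configuration overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  nonneg <- c(
    "G_escx1", "G_escx2", "G_igcx", "G_iges", "G_igig1", "G_igig2", "G_igig3",
    "G_igsg", "G_igcs", "G_sgcx", "G_sges", "G_sgig", "G_sgsg1", "G_sgsg2",
    "tau_es", "tau_ig", "tau_sg", "c_cx", "c_sg", "c_ig", "T_ig"
  )
  for (nm in nonneg) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] < 0) {
      stop("config field `", nm, "` must be a single non-negative number", call. = FALSE)
    }
  }
  if (cfg$dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (cfg$tau_g <= 0) stop("tau_g must be > 0", call. = FALSE)
  if (cfg$N_dir != 8L) stop("the model is defined for N_dir = 8 directions", call. = FALSE)
  if (cfg$mt_surround_scale <= cfg$mt_rf_scale) {
    stop("mt_surround_scale must exceed mt_rf_scale", call. = FALSE)
  }
  if (length(cfg$grid_shape) != 2L || any(cfg$grid_shape < 8L)) {
    stop("grid_shape must be two lattice extents >= 8", call. = FALSE)
  }
  if (!cfg$gamma_weighting %in% c("uniform", "cosine")) {
    stop("gamma_weighting must be 'uniform' or 'cosine'", call. = FALSE)
  }
  cfg$grid_shape <- as.integer(cfg$grid_shape)
  cfg$N_dir <- as.integer(cfg$N_dir)
  cfg$n_fast <- as.integer(cfg$n_fast)
  cfg$n_slow <- as.integer(cfg$n_slow)
  structure(cfg, class = "mt_config")
}

#' @export
print.mt_config <- function(x, ...) {
  cat("<mt_config> V1-to-MT network configuration\n")
  cat("  lattice:", x$grid_shape[1], "x", x$grid_shape[2],
      "| directions:", x$N_dir, "| dt:", x$dt, "\n")
  cat("  variable gains: G_igcs =", x$G_igcs, " G_sges =", x$G_sges, "\n")
  invisible(x)
}

#' Read or write a model configuration as YAML
#'
#' The configuration file is a flat key-value YAML document. All keys are
#' optional (missing keys take their defaults); unknown keys are rejected.
#'
#' @param path File path.
#' @param config An `mt_config` object (for writing).
#' @return `read_model_config()` returns an `mt_config`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.null(vals$grid_shape)) vals$grid_shape <- as.integer(vals$grid_shape)
  do.call(model_config, vals)
}

#' @rdname read_model_config
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "mt_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# ---- direction geometry -----------------------------------------------------

#' Direction and orientation geometry
#'
#' The model uses `n` uniformly spaced motion directions (degrees,
#' counter-clockwise from rightward +x, with +y pointing up) and `n/2`
#' orientations. `opposite_direction()` maps a direction index to the index
#' 180 degrees away; `orthogonal_orientation()` maps a direction to the
#' orientation orthogonal to it (the orientation of an edge moving in that
#' direction), as an index into `orientation_angles()`.
#'
#' @param n Number of directions (8 for the standard model).
#' @return `direction_angles()`/`orientation_angles()`: numeric vectors in
#'   degrees; the index maps return integer indices.
#' @examples
#' direction_angles()
#' opposite_direction(1, 8)
#' @export
direction_angles <- function(n = 8L) seq(0, 360 - 360 / n, by = 360 / n)

#' @rdname direction_angles
#' @export
orientation_angles <- function(n = 8L) seq(0, 180 - 360 / n, by = 360 / n)

#' @rdname direction_angles
#' @param d Direction index (1-based).
#' @export
opposite_direction <- function(d, n = 8L) 1L + (as.integer(d) - 1L + n %/% 2L) %% n

#' @rdname direction_angles
#' @export
orthogonal_orientation <- function(d, n = 8L) {
  ang <- (direction_angles(n)[d] + 90) %% 180
  match(ang, orientation_angles(n))
}

# index of a direction angle (degrees) in direction_angles(n)
direction_index <- function(angle, n = 8L) {
  i <- match((angle %% 360), direction_angles(n))
  if (any(is.na(i))) stop("direction angle not on the ", n, "-direction lattice", call. = FALSE)
  i
}
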