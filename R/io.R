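#' Scalar simulation configuration
#'
#' All scalar model parameters with their units, pre-filled from one of two
#' presets: \code{"frog"} (quasi-2D tongue slab: support radius 10 mm,
#' boundary pressures 10.6/1.60 kPa, permeabilities 1.0/5.0 x 10^-12 m^2,
#' pressure-drop parameter 0.01 x 10^-12 m^3) or \code{"brain"} (3D:
#' support radius 30 mm, boundary pressures 13.3/0.66 kPa, permeabilities
#' 12.5/25.0 x 10^-12 m^2, pressure-drop parameter 0.20 x 10^-12 m^3,
#' alpha 1.0 x 10^-5 m s/kg). Individual values can be overridden by name.
#'
#' @param preset \code{"frog"} or \code{"brain"}
#' @param ... named overrides of any configuration entry
#' @return object of class \code{sim_config}: validated named list
#' @export
sim_config <- function(preset = c("frog", "brain"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    mu = 3.0e-3, # blood viscosity [Pa s]
    hct = 0.40, # hematocrit [-]
    phi_a = 0.05, phi_v = 0.10, # porosities (CBV fractions) [-]
    t0 = 7.5, C0 = 1, aif_A = 3, aif_B = 1, # gamma-variate AIF
    t_sim = 120, sample_dt = 5, cfl_factor = 10, # tracer time stepping [s]
    solver_tol = 1e-6,
    smooth_radius = 2.5, smooth_sigma = 1.5 # parameter-map smoothing [mm]
  )
  if (preset == "frog") {
    cfg <- c(cfg, list(
      epsilon = 10.0, # support radius [mm]
      alpha = 1.00e-6, # perfusion proportionality [m s/kg]
      k_a = 1.00e-12, k_v = 5.00e-12, # permeabilities [m^2]
      p_root_a = 10.6e3, p_root_v = 1.60e3, # boundary pressures [Pa]
      gamma_a = 0.01e-12, gamma_v = 0.01e-12, # pressure-drop par. [m^3]
      dimension = 2
    ))
  } else {
    cfg <- c(cfg, list(
      epsilon = 30.0,
      alpha = 1.00e-5,
      k_a = 12.5e-12, k_v = 25.0e-12,
      p_root_a = 13.3e3, p_root_v = 0.66e3,
      gamma_a = 0.20e-12, gamma_v = 0.20e-12,
      dimension = 3
    ))
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_config <- function(cfg) {
  pos <- c(
    "mu", "phi_a", "phi_v", "k_a", "k_v", "epsilon",
    "p_root_a", "p_root_v", "gamma_a", "gamma_v", "t_sim",
    "sample_dt", "cfl_factor", "solver_tol", "C0"
  )
  for (key in pos) {
    v <- cfg[[key]]
    if (is.null(v) || !is.numeric(v) || v <= 0) {
      stop("configuration entry '", key, "' must be a positive number")
    }
  }
  if (cfg$alpha < 0) stop("alpha must be >= 0")
  if (cfg$hct < 0 || cfg$hct >= 1) stop("hct must lie in [0, 1)")
  if (cfg$phi_a > 1 || cfg$phi_v > 1) stop("porosities must be <= 1")
  if (!cfg$dimension %in% c(2, 3)) stop("dimension must be 2 or 3")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config '%s'> epsilon = %g mm, p_root = %g/%g kPa, gamma = %g m^3\n",
    x$preset, x$epsilon, x$p_root_a / 1e3, x$p_root_v / 1e3, x$gamma_a
  ))
  invisible(x)
}

#' Write a configuration to a JSON file
#' @param config a \code{sim_config}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Load and validate a configuration from JSON
#' @param path file written by \code{\link{save_config}} (or hand-edited)
#' @return a \code{sim_config}
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  preset <- if (is.null(raw$preset)) "frog" else raw$preset
  raw$preset <- NULL
  do.call(sim_config, c(list(preset = preset), raw))
}

#' Read a binary mask volume (NIfTI)
#'
#' Reads a NIfTI volume, takes the voxel size from its header and returns a
#' logical mask on a \code{\link{voxel_grid}}. 2D images get a singleton
#' third dimension. Non-binary volumes are thresholded at 0.5 with a
#' warning. Rotational affines are rejected: volumes must be axis-aligned.
#'
#' @param path NIfTI file (.nii or .nii.gz)
#' @return list with \code{mask} (logical array) and \code{grid}
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  h <- RNifti::pixdim(img)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 2L) {
    arr <- array(arr, c(d, 1L))
    d <- dim(arr)
    h <- c(h[1:2], 1)
  }
  if (length(d) != 3L) stop("expected a 2D or 3D volume, got ", length(d), "D")
  if (length(h) < 3L || any(!is.finite(h[1:3])) || any(h[1:3] <= 0)) {
    stop("missing or invalid voxel-size metadata in ", path)
  }
  vals <- unique(as.numeric(arr))
  if (!all(vals %in% c(0, 1))) {
    warning("non-binary volume thresholded at 0.5")
  }
  grid <- voxel_grid(d, h[1:3])
  list(mask = array(arr > 0.5, d), grid = grid)
}

#' Write a mask or scalar field as NIfTI
#' @param x logical or numeric array
#' @param grid the \code{voxel_grid} (voxel size goes into the header)
#' @param path output path (.nii or .nii.gz)
#' @return \code{path}, invisibly
#' @export
write_volume <- function(x, grid, path) {
  arr <- array(as.numeric(x), grid$shape)
  img <- RNifti::asNifti(arr)
  # a trailing singleton dimension is dropped by the NIfTI container;
  # match the pixdim length to what survives
  RNifti::pixdim(img) <- grid$h[seq_along(dim(img))]
  RNifti::writeNifti(img, path)
  invisible(path)
}
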