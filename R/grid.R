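#' Regular voxel grid
#'
#' Defines the regular grid the tissue model lives on: matrix size, voxel
#' size and physical origin. Physical positions are voxel centers, with the
#' first voxel centred at \code{origin + h/2}; voxel indices are 1-based in R
#' code. The field of view per axis is \code{shape * h}.
#'
#' @param shape integer vector of length 3, matrix size (nx, ny, nz).
#' @param voxel_size numeric length 3, voxel edge lengths in mm.
#' @param origin numeric length 3, physical position of the grid corner in mm.
#' @return An object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(shape, voxel_size, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 2L) voxel_size <- c(voxel_size, 1)
  stopifnot(length(shape) == 3L, length(voxel_size) == 3L)
  if (any(shape < 1L)) stop("all shape entries must be >= 1")
  if (any(voxel_size <= 0)) stop("all voxel sizes must be > 0")
  structure(
    list(shape = shape, h = voxel_size, origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %d x %d x %d, h = (%g, %g, %g) mm, FOV = (%g, %g, %g) mm\n",
    x$shape[1], x$shape[2], x$shape[3], x$h[1], x$h[2], x$h[3],
    x$shape[1] * x$h[1], x$shape[2] * x$h[2], x$shape[3] * x$h[3]
  ))
  invisible(x)
}

#' Voxel volume of a grid in cubic metres
#' @param grid a \code{voxel_grid}
#' @return scalar volume of one voxel [m^3]
#' @export
voxel_volume <- function(grid) prod(grid$h) * .mm2m^3

#' Physical center coordinates (mm) of voxels given by linear index
#' @param grid a \code{voxel_grid}
#' @param idx integer vector of 1-based linear (column-major) voxel indices
#' @return numeric matrix with one (x, y, z) row per index
#' @export
voxel_centers <- function(grid, idx) {
  ai <- arrayInd(idx, grid$shape)
  sweep(sweep(ai - 0.5, 2, grid$h, "*"), 2, grid$origin, "+")
}

#' Map physical positions (mm) to 1-based linear voxel indices
#' @param grid a \code{voxel_grid}
#' @param pos numeric matrix of (x, y, z) rows, or a single position
#' @return integer vector of linear indices (positions are clamped to grid)
#' @export
pos_to_index <- function(grid, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1)
  ijk <- sweep(sweep(pos, 2, grid$origin, "-"), 2, grid$h, "/")
  ijk <- floor(ijk) + 1
  for (d in 1:3) ijk[, d] <- pmin(pmax(ijk[, d], 1), grid$shape[d])
  as.integer(ijk[, 1] + grid$shape[1] * ((ijk[, 2] - 1) +
    grid$shape[2] * (ijk[, 3] - 1)))
}

.as_field <- function(x, grid) {
  if (length(x) == 1L) {
    array(x, dim = grid$shape)
  } else {
    stopifnot(all(dim(x) == grid$shape) || length(x) == prod(grid$shape))
    array(x, dim = grid$shape)
  }
}

#' Tissue domain: mask plus per-voxel model parameters
#'
#' Bundles the tissue mask \eqn{\Omega_B} with the porous-media parameter
#' fields of the two compartments: porosities \eqn{\phi_a, \phi_v} (the
#' neuroimaging CBV), permeabilities \eqn{k_a, k_v} and the perfusion
#' proportionality factor \eqn{\alpha} of \eqn{P = \alpha(p_a - p_v)}.
#' Scalars are expanded to constant fields. Values outside the mask are
#' carried but never read by the solvers.
#'
#' @param grid a \code{voxel_grid}
#' @param mask logical array over the grid: the tissue region
#' @param phi_a,phi_v porosity fields or scalars, dimensionless in [0, 1]
#' @param k_a,k_v permeability fields or scalars [m^2]
#' @param alpha perfusion proportionality field or scalar [m s/kg]
#' @param mu blood viscosity [Pa s]
#' @return An object of class \code{tissue_domain}.
#' @export
tissue_domain <- function(grid, mask, phi_a = 0.05, phi_v = 0.10,
                          k_a = 1e-12, k_v = 5e-12, alpha = 1e-6,
                          mu = 3.0e-3) {
  stopifnot(inherits(grid, "voxel_grid"))
  mask <- array(as.logical(mask), dim = grid$shape)
  if (!any(mask)) stop("tissue mask is empty")
  dom <- structure(
    list(
      grid = grid, mask = mask,
      phi_a = .as_field(phi_a, grid), phi_v = .as_field(phi_v, grid),
      k_a = .as_field(k_a, grid), k_v = .as_field(k_v, grid),
      alpha = .as_field(alpha, grid), mu = mu
    ),
    class = "tissue_domain"
  )
  validate_domain(dom)
  dom
}

validate_domain <- function(dom) {
  m <- dom$mask
  if (any(dom$phi_a[m] < 0) || any(dom$phi_a[m] > 1) ||
    any(dom$phi_v[m] < 0) || any(dom$phi_v[m] > 1)) {
    stop("porosities must lie in [0, 1] on the mask")
  }
  if (any(dom$k_a[m] <= 0) || any(dom$k_v[m] <= 0)) {
    stop("permeabilities must be > 0 on the mask")
  }
  if (any(dom$alpha[m] < 0)) stop("alpha must be >= 0 on the mask")
  if (dom$mu <= 0) stop("viscosity must be > 0")
  invisible(dom)
}

#' @export
print.tissue_domain <- function(x, ...) {
  cat(sprintf(
    "<tissue_domain> %d masked voxels of %d; mu = %g Pa s\n",
    sum(x$mask), prod(x$grid$shape), x$mu
  ))
  invisible(x)
}

#' Distance to the tissue boundary
#'
#' Physical distance (mm) from each masked voxel center to the nearest voxel
#' of the boundary shell of the mask. The shell consists of masked voxels
#' with at least one 6-neighbour outside the mask or outside the image.
#'
#' @param mask logical array
#' @param grid a \code{voxel_grid}
#' @return list with \code{shell} (logical array) and \code{dist}
#'   (numeric array, mm; Inf where no shell exists)
#' @export
boundary_shell <- function(mask, grid) {
  d <- grid$shape
  m <- array(as.logical(mask), d)
  has_out <- array(FALSE, d)
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    for (s in c(-1L, 1L)) {
      off <- integer(3)
      off[ax] <- s
      nb <- .shift3(array(as.numeric(m), d), off) # 0 beyond the image too
      has_out <- has_out | (nb < 0.5)
    }
  }
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  if (d[3] > 1L) border[, , c(1, d[3])] <- TRUE
  shell <- m & (has_out | border)
  dist_to_shell <- array(.cpp_edt(!shell, d, grid$h), d)
  list(shell = shell, dist = dist_to_shell)
}

#' Gaussian smoothing of a parameter map restricted to the mask
#'
#' Smooths piecewise-constant tissue parameter maps with a truncated
#' Gaussian kernel (defaults: radius 2.5 mm, standard deviation 1.5 mm),
#' renormalizing the kernel over the mask so that masked-region averages are
#' preserved and no weight leaks across the tissue boundary. Emulates
#' partial-volume mixing at tissue interfaces.
#'
#' @param field numeric array over the grid
#' @param mask logical array; only masked voxels are smoothed and read
#' @param grid a \code{voxel_grid}
#' @param radius kernel truncation radius [mm]
#' @param sigma Gaussian standard deviation [mm]
#' @return smoothed field (unchanged outside the mask)
#' @export
smooth_parameter_map <- function(field, mask, grid, radius = 2.5,
                                 sigma = 1.5) {
  d <- grid$shape
  field <- array(field, d)
  mask <- array(mask, d)
  # separable-in-offsets direct convolution over the truncated stencil
  offs <- lapply(1:3, function(ax) {
    r <- floor(radius / grid$h[ax])
    if (d[ax] == 1L) 0L else seq.int(-r, r)
  })
  num <- array(0, d)
  den <- array(0, d)
  fm <- field
  fm[!mask] <- 0
  mm <- array(as.numeric(mask), d)
  for (ox in offs[[1]]) {
    for (oy in offs[[2]]) {
      for (oz in offs[[3]]) {
        r2 <- (ox * grid$h[1])^2 + (oy * grid$h[2])^2 + (oz * grid$h[3])^2
        if (r2 > radius^2) next
        w <- exp(-r2 / (2 * sigma^2))
        sf <- .shift3(fm, c(ox, oy, oz))
        sm <- .shift3(mm, c(ox, oy, oz))
        num <- num + w * sf
        den <- den + w * sm
      }
    }
  }
  out <- field
  ok <- mask & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

# shift a 3D array by integer offsets, zero-filling
.shift3 <- function(x, off) {
  d <- dim(x)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      src[[ax]] <- seq_len(d[ax] - o)
      dst[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      src[[ax]] <- seq_len(d[ax] + o) - o
      dst[[ax]] <- seq_len(d[ax] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}
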