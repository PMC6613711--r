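#' Smooth compactly supported shape function
#'
#' The normalized bump function
#' \deqn{\eta(x) = C \exp(1 / (|x|^2 - 1)), |x| < 1; 0 otherwise,}
#' which is continuously differentiable everywhere, strictly positive on the
#' open unit ball and integrates to one over it. The normalization constant
#' C has no closed form and is computed once per spatial dimension by
#' adaptive quadrature of the radial integral and cached.
#'
#' @param x numeric matrix of dimensionless offsets (one row per point) or a
#'   single vector
#' @param dimension effective spatial dimension, 2 or 3; controls the
#'   normalization constant
#' @return nonnegative values of \eqn{\eta} at the given offsets
#' @export
shape_eta <- function(x, dimension = 3) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  r2 <- rowSums(x^2)
  out <- numeric(length(r2))
  inside <- r2 < 1
  out[inside] <- exp(1 / (r2[inside] - 1))
  eta_norm_const(dimension) * out
}

.eta_cache <- new.env(parent = emptyenv())

#' Normalization constant of the bump shape function
#' @param dimension 2 or 3
#' @return C such that the integral of \eqn{\eta} over the unit ball is 1
#' @export
eta_norm_const <- function(dimension = 3) {
  key <- as.character(dimension)
  if (!is.null(.eta_cache[[key]])) return(.eta_cache[[key]])
  unnorm <- function(r) exp(1 / (r^2 - 1))
  I <- switch(key,
    "2" = 2 * pi * integrate(function(r) r * unnorm(r), 0, 1,
      rel.tol = 1e-12
    )$value,
    "3" = 4 * pi * integrate(function(r) r^2 * unnorm(r), 0, 1,
      rel.tol = 1e-12
    )$value,
    stop("dimension must be 2 or 3")
  )
  C <- 1 / I
  .eta_cache[[key]] <- C
  C
}

#' Discrete terminal support kernel
#'
#' Evaluates the rescaled support function
#' \eqn{\eta^\epsilon(x - \tilde x_k) = \epsilon^{-n}\eta((x-\tilde x_k)/\epsilon)}
#' at voxel centers (physical mm coordinates, anisotropic voxel sizes
#' respected), zeroes it outside the tissue mask and renormalizes so that
#' the discrete integral over the mask is exactly one:
#' \eqn{\sum_i w_i |\Omega_i| = 1}. The renormalization makes discrete mass
#' balance exact even when the support ball is clipped by the tissue
#' boundary.
#'
#' @param position numeric (x, y, z) terminal position in mm
#' @param domain a \code{tissue_domain}
#' @param epsilon support radius in mm
#' @param dimension effective dimension passed to \code{\link{shape_eta}}
#' @return list with \code{idx} (1-based linear voxel indices inside the
#'   support and mask), \code{w} (kernel values, 1/m^3, summing to
#'   1/voxel-volume), and \code{wgt} (= \code{w * voxel volume}, the
#'   dimensionless flow fractions summing to one)
#' @export
kernel_weights <- function(position, domain, epsilon, dimension = 3) {
  stopifnot(epsilon > 0)
  grid <- domain$grid
  d <- grid$shape
  # bounding box of the support ball in index space
  lo <- pmax(1L, floor((position - epsilon - grid$origin) / grid$h - 0.5) + 1L)
  hi <- pmin(d, ceiling((position + epsilon - grid$origin) / grid$h + 0.5))
  if (any(lo > hi)) stop("orphan terminal: support does not intersect mask")
  ii <- seq.int(lo[1], hi[1])
  jj <- seq.int(lo[2], hi[2])
  kk <- seq.int(lo[3], hi[3])
  box <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  idx <- box[, 1] + d[1] * ((box[, 2] - 1) + d[2] * (box[, 3] - 1))
  inmask <- domain$mask[idx]
  idx <- idx[inmask]
  if (!length(idx)) stop("orphan terminal: support does not intersect mask")
  ctr <- voxel_centers(grid, idx)
  off <- sweep(ctr, 2, position, "-") / epsilon
  eta <- shape_eta(off, dimension)
  keep <- eta > 0
  idx <- idx[keep]
  eta <- eta[keep]
  if (!length(idx)) {
    # support narrower than one voxel: collapse to the Dirac limit in the
    # nearest masked voxel of the bounding box
    idx0 <- pos_to_index(grid, position)
    if (!domain$mask[idx0]) {
      stop("orphan terminal: support does not intersect mask")
    }
    idx <- idx0
    eta <- 1
  }
  vv <- voxel_volume(grid)
  w <- eta / (sum(eta) * vv) # discrete renormalization: sum(w) * vv == 1
  list(idx = as.integer(idx), w = w, wgt = w * vv)
}

#' Build support kernels for every interior terminal of a network
#'
#' @param network classified \code{vessel_network}
#' @param domain a \code{tissue_domain}
#' @param epsilon support radius in mm
#' @param dimension effective spatial dimension (2 for thin, quasi-planar
#'   domains, 3 otherwise)
#' @return object of class \code{support_kernels}: a list of kernels keyed
#'   by terminal node id, with attributes \code{epsilon} and
#'   \code{dimension}
#' @export
build_kernels <- function(network, domain, epsilon, dimension = 3) {
  term <- interior_terminals(network)
  ker <- lapply(term, function(id) {
    row <- which(network$nodes$id == id)
    kernel_weights(
      as.numeric(network$nodes[row, c("x", "y", "z")]),
      domain, epsilon, dimension
    )
  })
  names(ker) <- as.character(term)
  structure(ker,
    class = "support_kernels",
    epsilon = epsilon, dimension = dimension
  )
}

#' Summed kernel field for inspection
#'
#' Adds up all terminal kernels of a \code{support_kernels} set into one
#' voxel field (the grey haze around the network when visualized).
#'
#' @param kernels a \code{support_kernels} object
#' @param domain a \code{tissue_domain}
#' @return numeric array over the grid
#' @export
kernel_field <- function(kernels, domain) {
  out <- array(0, domain$grid$shape)
  for (k in kernels) out[k$idx] <- out[k$idx] + k$w
  out
}
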