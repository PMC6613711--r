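#' Synthetic tissue domains
#'
#' Generates elliptical/ellipsoidal tissue masks with parameter fields
#' filled from a simulation configuration, for testing the whole pipeline
#' without imaging data. The \code{"two_tissue"} variant embeds an inner
#' region whose perfusion proportionality factor is 1.6 times the outer
#' value, emulating the grey/white contrast of a brain parameter map; its
#' piecewise-constant parameter maps are smoothed by a masked Gaussian
#' (radius 2.5 mm, sd 1.5 mm) to mimic partial-volume mixing.
#'
#' @param shape matrix size; 2D shapes get a third dimension of 1
#' @param kind \code{"ellipse2d"}, \code{"ellipsoid3d"} or
#'   \code{"two_tissue"}
#' @param fov physical field of view in mm (per axis)
#' @param config simulation configuration from \code{\link{sim_config}};
#'   supplies viscosity, porosities, permeabilities and alpha
#' @param smooth logical: smooth the two-tissue parameter maps
#' @param seed integer; generation is deterministic given the seed
#' @return a \code{tissue_domain}; for \code{"two_tissue"} the integer
#'   array attribute \code{"tissue_label"} marks outer (1) and inner (2)
#'   tissue
#' @export
make_tissue <- function(shape = c(128, 128, 1),
                        kind = c("ellipse2d", "ellipsoid3d", "two_tissue"),
                        fov = NULL, config = sim_config("frog"),
                        smooth = TRUE, seed = 1) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  if (any(shape[shape > 1L] < 32L)) stop("degenerate shape: need >= 32 voxels per axis")
  if (is.null(fov)) {
    fov <- if (kind == "ellipse2d") c(40, 33, 1) else c(120, 120, 120)
  }
  if (length(fov) == 2L) fov <- c(fov, 1)
  grid <- voxel_grid(shape, fov / shape)
  ctr <- fov / 2
  semi <- c(0.45, 0.42, 0.42) * fov
  idx <- seq_len(prod(shape))
  pos <- voxel_centers(grid, idx)
  if (kind == "ellipse2d" || shape[3] == 1L) {
    r2 <- ((pos[, 1] - ctr[1]) / semi[1])^2 + ((pos[, 2] - ctr[2]) / semi[2])^2
  } else {
    r2 <- ((pos[, 1] - ctr[1]) / semi[1])^2 + ((pos[, 2] - ctr[2]) / semi[2])^2 +
      ((pos[, 3] - ctr[3]) / semi[3])^2
  }
  mask <- array(r2 <= 1, shape)
  alpha <- config$alpha
  dom <- tissue_domain(grid, mask,
    phi_a = config$phi_a, phi_v = config$phi_v,
    k_a = config$k_a, k_v = config$k_v,
    alpha = alpha, mu = config$mu
  )
  if (kind == "two_tissue") {
    inner <- array(r2 <= 0.6^2, shape)
    lab <- array(1L, shape)
    lab[inner] <- 2L
    lab[!mask] <- 0L
    amap <- array(alpha, shape)
    amap[inner] <- 1.6 * alpha
    if (smooth) {
      amap <- smooth_parameter_map(amap, mask, grid, radius = 2.5, sigma = 1.5)
    }
    dom$alpha <- amap
    attr(dom, "tissue_label") <- lab
  }
  attr(dom, "seed") <- seed
  dom
}

#' Recursive binary vascular tree with known ground truth
#'
#' Grows a binary tree of straight tubular branches from a root on the
#' tissue boundary, rasterizes it into a voxel mask (voxel centers within
#' the tube radius of the branch segment, clipped to the tissue mask) and
#' returns both the mask and the exact graph used for rasterization, so
#' graph extraction can be validated against known topology.
#'
#' @param spec list with \code{root} (mm position), \code{dir} (initial
#'   unit direction), \code{depth} (number of bifurcation generations),
#'   \code{len0} (root branch length, mm), \code{len_decay},
#'   \code{radius0} (root radius, mm), \code{radius_decay},
#'   \code{angle} (bifurcation half-angle, degrees), \code{jitter}
#'   (sd of angular noise, degrees; 0 disables) and \code{seed}
#' @param domain a \code{tissue_domain}
#' @return list with \code{mask} (logical array) and \code{network}
#'   (ground-truth \code{vessel_network} with medial axes)
#' @export
make_tree <- function(spec, domain) {
  grid <- domain$grid
  d <- grid$shape
  planar <- d[3] == 1L
  rng <- .tree_rng(spec$seed)
  jitter <- if (is.null(spec$jitter)) 0 else spec$jitter

  nodes <- list(list(pos = spec$root))
  edges <- list()
  grow <- function(from_id, dir, len, radius, depth) {
    p0 <- nodes[[from_id]]$pos
    p1 <- p0 + dir * len
    nodes[[length(nodes) + 1L]] <<- list(pos = p1)
    to_id <- length(nodes)
    edges[[length(edges) + 1L]] <<- list(
      from = from_id, to = to_id, radius = radius
    )
    if (depth > 0L) {
      ang <- (spec$angle + jitter * rng()) * pi / 180
      for (s in c(-1, 1)) {
        nd <- .rotate_dir(dir, s * ang, planar, rng)
        grow(
          to_id, nd, len * spec$len_decay,
          radius * spec$radius_decay, depth - 1L
        )
      }
    }
  }
  grow(1L, spec$dir / sqrt(sum(spec$dir^2)), spec$len0, spec$radius0,
    depth = spec$depth
  )

  # rasterize: tube mask and voxelized medial axes
  mask <- array(FALSE, d)
  axes <- vector("list", length(edges))
  step <- 0.4 * min(grid$h[grid$h > 0][1:ifelse(planar, 2, 3)])
  for (e in seq_along(edges)) {
    p0 <- nodes[[edges[[e]]$from]]$pos
    p1 <- nodes[[edges[[e]]$to]]$pos
    r <- edges[[e]]$radius
    mask <- mask | .rasterize_segment(grid, p0, p1, r)
    ts <- seq(0, 1, by = step / sqrt(sum((p1 - p0)^2)))
    pts <- outer(ts, p1 - p0) + matrix(p0, length(ts), 3, byrow = TRUE)
    ax <- pos_to_index(grid, pts)
    axes[[e]] <- ax[!duplicated(ax)]
  }
  if (!any(mask & domain$mask)) stop("tree lies entirely outside the domain")
  mask <- mask & domain$mask

  nd <- data.frame(
    id = seq_along(nodes),
    t(vapply(nodes, function(n) n$pos, numeric(3)))
  )
  names(nd) <- c("id", "x", "y", "z")
  ed <- data.frame(
    from = vapply(edges, function(e) e$from, integer(1)),
    to = vapply(edges, function(e) e$to, integer(1)),
    length = vapply(seq_along(edges), function(e) {
      sqrt(sum((nodes[[edges[[e]]$to]]$pos - nodes[[edges[[e]]$from]]$pos)^2))
    }, numeric(1)),
    radius = vapply(edges, function(e) e$radius, numeric(1))
  )
  net <- vessel_network(nd, ed, medial_axes = axes, mu = domain$mu)
  list(mask = mask, network = net)
}

# small deterministic Park-Miller generator so tree generation does not
# touch R's global RNG stream (double arithmetic stays exact below 2^53)
.tree_rng <- function(seed) {
  state <- as.numeric(if (is.null(seed)) 1 else seed) %% 2147483646 + 1
  function() {
    state <<- (16807 * state) %% 2147483647
    (state / 2147483647) * 2 - 1 # in (-1, 1)
  }
}

.rotate_dir <- function(dir, ang, planar, rng) {
  if (planar) {
    ca <- cos(ang)
    sa <- sin(ang)
    c(ca * dir[1] - sa * dir[2], sa * dir[1] + ca * dir[2], 0)
  } else {
    # rotate within a plane spanned by dir and a pseudo-random perpendicular
    ref <- c(rng(), rng(), rng())
    perp <- ref - sum(ref * dir) * dir
    nrm <- sqrt(sum(perp^2))
    if (nrm < 1e-8) perp <- c(dir[2], -dir[1], 0) else perp <- perp / nrm
    out <- cos(ang) * dir + sin(ang) * perp
    out / sqrt(sum(out^2))
  }
}

.rasterize_segment <- function(grid, p0, p1, radius) {
  d <- grid$shape
  lo <- pmax(1L, floor((pmin(p0, p1) - radius - grid$origin) / grid$h) + 1L)
  hi <- pmin(d, ceiling((pmax(p0, p1) + radius - grid$origin) / grid$h) + 1L)
  out <- array(FALSE, d)
  if (any(lo > hi)) return(out)
  box <- as.matrix(expand.grid(
    i = seq.int(lo[1], hi[1]), j = seq.int(lo[2], hi[2]),
    k = seq.int(lo[3], hi[3])
  ))
  idx <- box[, 1] + d[1] * ((box[, 2] - 1) + d[2] * (box[, 3] - 1))
  ctr <- voxel_centers(grid, idx)
  v <- p1 - p0
  L2 <- sum(v^2)
  w <- sweep(ctr, 2, p0, "-")
  t <- pmin(pmax(as.numeric(w %*% v) / L2, 0), 1)
  nearest <- outer(t, v) + matrix(p0, length(t), 3, byrow = TRUE)
  dist2 <- rowSums((ctr - nearest)^2)
  out[idx[dist2 <= radius^2]] <- TRUE
  out
}

#' Full synthetic simulation scenario with paired vascular trees
#'
#' The canonical end-to-end regression fixture: an elliptical tissue slab
#' with one arterial and one mirrored venous tree, both rooted on the lower
#' tissue boundary (arterial inlet and venous outlet at the bottom),
#' classified networks, support kernels and a frog- or brain-style
#' parameter configuration. The \code{scale} argument refines the grid at
#' fixed physical field of view for scale-invariance studies.
#'
#' @param seed integer seed (generation is deterministic given the seed)
#' @param preset \code{"frog"} (quasi-2D slab) or \code{"brain"} (3D
#'   two-tissue ellipsoid)
#' @param shape base matrix size before scaling
#' @param scale multiplicative resolution scale (1, 2, 4, ...)
#' @param config optional \code{\link{sim_config}} override
#' @param depth bifurcation generations of each tree
#' @return object of class \code{perfusion_scenario}: list with
#'   \code{domain}, classified \code{arterial}/\code{venous} networks,
#'   their masks, \code{kernels_a}/\code{kernels_v} and \code{config}
#' @export
make_paired_scenario <- function(seed = 1, preset = c("frog", "brain"),
                                 shape = NULL, scale = 1,
                                 config = NULL, depth = 3) {
  preset <- match.arg(preset)
  if (is.null(config)) config <- sim_config(preset)
  planar <- preset == "frog"
  if (is.null(shape)) shape <- if (planar) c(128, 108, 1) else c(48, 48, 48)
  shape <- as.integer(shape)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  sshape <- shape
  sshape[shape > 1L] <- shape[shape > 1L] * scale
  fov <- if (planar) c(40, 33, 1) else c(120, 120, 120)
  dom <- make_tissue(sshape,
    kind = if (planar) "ellipse2d" else "two_tissue",
    fov = fov, config = config, seed = seed
  )
  ctr <- fov / 2
  semi <- c(0.45, 0.42, 0.42) * fov
  zmid <- if (planar) fov[3] / 2 else NA

  # roots on the lower boundary, left (arterial) and right (venous)
  ang_a <- -115 * pi / 180
  ang_v <- -65 * pi / 180
  root_at <- function(ang) {
    if (planar) {
      c(ctr[1] + semi[1] * cos(ang), ctr[2] + semi[2] * sin(ang), zmid)
    } else {
      c(ctr[1] + semi[1] * cos(ang), ctr[2] + semi[2] * sin(ang), ctr[3])
    }
  }
  # trunks grow straight up from the lower boundary so the two fans stay on
  # their own side of the midline and never intersect
  dir_a <- c(0, 1, 0)
  dir_v <- c(0, 1, 0)
  ra <- root_at(ang_a)
  rv <- root_at(ang_v)
  len0 <- 0.26 * min(fov[1:2])
  spec_a <- list(
    root = ra, dir = dir_a, depth = depth, len0 = len0,
    len_decay = 0.58, radius0 = 0.012 * min(fov[1:2]), radius_decay = 0.78,
    angle = 28, jitter = 0, seed = seed
  )
  spec_v <- spec_a
  spec_v$root <- rv
  spec_v$dir <- dir_v
  spec_v$seed <- seed + 1L
  tree_a <- make_tree(spec_a, dom)
  tree_v <- make_tree(spec_v, dom)
  # 3D branch orientations are seed-dependent; on the rare draw where the
  # fans touch, redraw the venous tree with a shifted stream
  tries <- 0L
  while (any(tree_a$mask & tree_v$mask) && tries < 8L) {
    tries <- tries + 1L
    spec_v$seed <- spec_v$seed + 1009L
    tree_v <- make_tree(spec_v, dom)
  }
  if (any(tree_a$mask & tree_v$mask)) {
    stop("arterial and venous trees overlap; adjust tree geometry")
  }
  art <- tree_a$network
  ven <- tree_v$network
  art$compartment <- "a"
  ven$compartment <- "v"
  art <- classify_nodes(art, dom)
  ven <- classify_nodes(ven, dom)
  dimension <- if (planar) 2L else 3L
  kern_a <- build_kernels(art, dom, config$epsilon, dimension)
  kern_v <- build_kernels(ven, dom, config$epsilon, dimension)
  structure(
    list(
      domain = dom, arterial = art, venous = ven,
      mask_a = tree_a$mask, mask_v = tree_v$mask,
      kernels_a = kern_a, kernels_v = kern_v,
      config = config, seed = seed, scale = scale, preset = preset
    ),
    class = "perfusion_scenario"
  )
}
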