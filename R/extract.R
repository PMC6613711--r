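#' Adaptive (local mean + k sd) thresholding
#'
#' First-pass vessel segmentation of an intensity volume: a voxel is kept
#' when its intensity exceeds the local mean plus \code{k} local standard
#' deviations, both computed over a cubic moving window. Bright tubular
#' structure on a darker background survives; smooth background does not.
#'
#' @param intensity numeric array (any nonnegative scale)
#' @param window odd window edge length in voxels
#' @param k number of local standard deviations above the local mean
#' @return logical array of most-probable vessel voxels
#' @export
adaptive_threshold <- function(intensity, window = 15, k = 3) {
  d <- dim(intensity)
  if (is.null(d)) stop("intensity must be an array")
  if (length(d) == 2L) {
    intensity <- array(intensity, c(d, 1L))
    d <- dim(intensity)
  }
  if (!all(is.finite(intensity))) stop("intensity must be finite")
  r <- max(1L, floor(window / 2))
  ones <- array(1, d)
  nloc <- .box_sum(ones, r)
  s1 <- .box_sum(intensity, r)
  s2 <- .box_sum(intensity^2, r)
  mu <- s1 / nloc
  v <- pmax(s2 / nloc - mu^2, 0)
  out <- intensity > mu + k * sqrt(v)
  if (!any(out)) warning("adaptive threshold produced an empty mask")
  out
}

# separable moving box sum of half-width r (truncated at the borders)
.box_sum <- function(x, r) {
  d <- dim(x)
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    x <- apply(x, setdiff(1:3, ax), function(v) {
      cs <- c(0, cumsum(v))
      n <- length(v)
      hi <- pmin(n, seq_len(n) + r)
      lo <- pmax(0L, seq_len(n) - r - 1L)
      cs[hi + 1L] - cs[lo + 1L]
    })
    # apply collapses the swept axis to the first dimension: restore order
    x <- aperm(array(x, c(d[ax], d[setdiff(1:3, ax)])),
      order(c(ax, setdiff(1:3, ax)))
    )
  }
  x
}

#' Join disconnected vessel fragments into one connected mask
#'
#' Satellite components of a fragmented segmentation are reconnected to the
#' largest (root) component by backtracing steepest-descent paths in a fast
#' marching arrival-time field whose speed is the intensity image itself, so
#' bridging paths follow bright (vessel-like) structure. Each bridge is
#' dilated to a tube whose radius is the mean of the two structures' mean
#' radii, the satellite is merged into the root and the arrival-time field
#' is recomputed.
#'
#' @param intensity nonnegative numeric array used as marching speed
#' @param segmentation logical array: fragmented vessel segmentation
#' @param grid a \code{voxel_grid}
#' @param order \code{"far-first"} (default) or \code{"near-first"}
#'   processing order of the satellites by Euclidean distance to the root
#' @return logical array: one 26-connected component containing every input
#'   component
#' @export
connect_components <- function(intensity, segmentation, grid,
                               order = c("far-first", "near-first")) {
  order <- match.arg(order)
  d <- grid$shape
  seg <- array(as.logical(segmentation), d)
  if (!any(seg)) stop("segmentation is empty")
  if (any(intensity < 0)) stop("intensity must be >= 0")
  lab <- array(.cpp_label_components(seg, d, 26L), d)
  ncomp <- max(lab)
  if (ncomp <= 1L) return(seg)
  if (all(intensity == 0)) stop("all-zero intensity: no admissible path")
  sizes <- tabulate(lab[lab > 0], nbins = ncomp)
  root_id <- which.max(sizes)
  root <- lab == root_id
  edt_all <- array(.cpp_edt(seg, d, grid$h), d) # radius estimator source
  mean_radius <- function(m) mean(edt_all[m])
  dist_to_root <- array(.cpp_edt(!root, d, grid$h), d)
  sat_ids <- setdiff(seq_len(ncomp), root_id)
  sat_dist <- vapply(sat_ids, function(s) min(dist_to_root[lab == s]), numeric(1))
  sat_ids <- sat_ids[order(sat_dist,
    decreasing = (order == "far-first")
  )]
  for (s in sat_ids) {
    sat <- lab == s
    T <- array(.cpp_fast_march(as.numeric(intensity), root, d, grid$h), d)
    tin <- T[sat]
    if (all(!is.finite(tin))) stop("satellite unreachable: zero-speed barrier")
    start <- which(sat)[which.min(tin)]
    path <- .cpp_backtrace(T, root, d, start)
    r_tube <- (mean_radius(root) + mean_radius(sat)) / 2
    bridge <- array(FALSE, d)
    bridge[path] <- TRUE
    if (r_tube > 0) {
      tube_dist <- array(.cpp_edt(!bridge, d, grid$h), d)
      bridge <- tube_dist <= r_tube
    }
    root <- root | bridge | sat
  }
  root
}

#' Extract a vascular graph from a connected vessel mask
#'
#' Solves the eikonal equation inside the mask with speed
#' \code{dist-to-boundary + xi} (fast marching from the root points), finds
#' leafs as regional maxima of the arrival time, and backtraces each leaf to
#' the root set by steepest descent. Bifurcation nodes are created wherever
#' a backtraced path first meets a previously traced path or a root point;
#' the path segments between nodes become edges carrying their geodesic
#' medial-axis length and the mean distance-to-boundary radius.
#'
#' @param vessel_mask logical array, a single 26-connected component
#' @param domain a \code{tissue_domain} (supplies grid and tissue boundary)
#' @param seeds optional integer vector of linear voxel indices to use as
#'   root points; by default the intersection of the vessel mask with the
#'   tissue-boundary shell (one root per connected intersection patch)
#' @param xi small positive constant added to the distance speed
#' @param min_leaf_time discard leaf candidates with arrival time below this
#'   fraction of the largest arrival time (suppresses spurious maxima next
#'   to the roots); default 0.05
#' @return a classified \code{vessel_network} with medial axes and node
#'   volumes filled
#' @export
extract_graph <- function(vessel_mask, domain, seeds = NULL, xi = 0.1,
                          min_leaf_time = 0.05, compartment = c("a", "v"),
                          prune = TRUE, spur_factor = 3) {
  compartment <- match.arg(compartment)
  grid <- domain$grid
  d <- grid$shape
  vm <- array(as.logical(vessel_mask), d)
  lab <- .cpp_label_components(vm, d, 26L)
  if (max(lab) != 1L) stop("vessel mask must be a single connected component")

  # root points: zero-arrival is imposed on the whole intersection patch of
  # the mask with the domain boundary (suppresses rim artifacts around the
  # root), with one root node per patch at its centroid voxel
  if (is.null(seeds)) {
    shell <- boundary_shell(domain$mask, grid)
    tol <- sqrt(sum(grid$h^2))
    cand <- vm & (shell$dist <= tol)
    if (!any(cand)) stop("no root points: mask does not touch the domain boundary")
  } else {
    cand <- array(FALSE, d)
    cand[seeds] <- TRUE
    cand <- cand & vm
    if (!any(cand)) stop("no root points: seeds lie outside the mask")
  }
  clab <- array(.cpp_label_components(cand, d, 26L), d)
  seeds <- vapply(seq_len(max(clab)), function(s) {
    vox <- which(clab == s)
    ctr <- voxel_centers(grid, vox)
    cen <- colMeans(ctr)
    vox[which.min(rowSums(sweep(ctr, 2, cen)^2))]
  }, integer(1))
  seed_mask <- cand

  # arrival time along the network, fastest in the tube centers
  edt_vox <- .cpp_edt(vm, d, grid$h) / min(grid$h)
  speed <- ifelse(vm, edt_vox + xi, 0)
  T <- array(.cpp_fast_march(as.numeric(speed), seed_mask & vm, d, grid$h), d)

  # leafs: regional maxima (plateaus collapse to their centroid voxel)
  rmax <- array(.cpp_regional_max(as.numeric(T), vm & is.finite(T), d), d)
  rmax[seed_mask] <- FALSE
  Tmax <- max(T[vm & is.finite(T)])
  leaf_lab <- array(.cpp_label_components(rmax, d, 26L), d)
  leafs <- integer(0)
  for (s in seq_len(max(leaf_lab))) {
    vox <- which(leaf_lab == s)
    if (max(T[vox]) < min_leaf_time * Tmax) next
    ctr <- voxel_centers(grid, vox)
    cen <- colMeans(ctr)
    leafs <- c(leafs, vox[which.min(rowSums(sweep(ctr, 2, cen)^2))])
  }
  if (!length(leafs)) stop("no leafs found in the vessel mask")
  leafs <- leafs[order(T[leafs], decreasing = TRUE)]

  # incremental tracing with edge splitting at path intersections
  edt_mm <- array(.cpp_edt(vm, d, grid$h), d)
  nodes <- list() # id -> list(vox, kind)
  edges <- list() # id -> list(from, to, axis)
  node_at <- array(0L, d)
  edge_of <- array(0L, d)
  pos_of <- array(0L, d)
  new_node <- function(vox) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(vox = vox)
    node_at[vox] <<- id
    id
  }
  mark_edge <- function(eid) {
    ax <- edges[[eid]]$axis
    inner <- ax[node_at[ax] == 0L]
    edge_of[inner] <<- eid
    pos_of[inner] <<- match(inner, ax)
  }
  root_nodes <- vapply(seeds, new_node, integer(1))
  # capture zone: voxels within the local tube radius of an already traced
  # path. Later backtraces stop on entry (wall-parallel duplicates of an
  # existing centerline are absorbed instead of forming parallel spurs).
  capture <- seed_mask
  mark_capture <- function(path) {
    for (v in path) {
      r <- max(edt_mm[v], min(grid$h))
      ijk <- arrayInd(v, d)[1, ]
      lo <- pmax(1L, ijk - ceiling(r / grid$h))
      hi <- pmin(d, ijk + ceiling(r / grid$h))
      box <- as.matrix(expand.grid(
        i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]
      ))
      bidx <- box[, 1] + d[1] * ((box[, 2] - 1) + d[2] * (box[, 3] - 1))
      dd2 <- ((box[, 1] - ijk[1]) * grid$h[1])^2 +
        ((box[, 2] - ijk[2]) * grid$h[2])^2 +
        ((box[, 3] - ijk[3]) * grid$h[3])^2
      capture[bidx[dd2 <= r^2]] <<- TRUE
    }
  }
  on_struct <- function(v) node_at[v] > 0L || edge_of[v] > 0L

  for (lf in leafs) {
    if (capture[lf]) next # leaf sits inside an already traced tube
    path <- .cpp_backtrace(T, capture, d, lf)
    if (length(path) < 2L) next
    endvox <- path[length(path)]
    if (!seed_mask[endvox] && !on_struct(endvox)) {
      # stopped inside a capture zone: bridge to the nearest traced voxel
      r_search <- 3 * max(edt_mm[endvox], min(grid$h))
      target <- .nearest_marked(node_at, edge_of, grid, endvox, r_search)
      if (is.na(target)) next # nothing to connect to: drop this leaf
      bridge <- .voxel_segment(grid, endvox, target)
      path <- c(path, bridge[-1])
      endvox <- target
    }
    leaf_id <- new_node(lf)
    end_id <- node_at[endvox]
    if (end_id == 0L && edge_of[endvox] > 0L) {
      # split the intersected edge at the meeting voxel
      eid <- edge_of[endvox]
      old <- edges[[eid]]
      p <- match(endvox, old$axis)
      end_id <- new_node(endvox)
      edges[[eid]] <- list(
        from = old$from, to = end_id, axis = old$axis[seq_len(p)]
      )
      edges[[length(edges) + 1L]] <- list(
        from = end_id, to = old$to,
        axis = old$axis[seq.int(p, length(old$axis))]
      )
      mark_edge(eid)
      mark_edge(length(edges))
    }
    if (end_id == 0L) {
      # met the seed set at a voxel that is not a node (numerical slack):
      # snap to the nearest root node
      rvox <- vapply(root_nodes, function(id) nodes[[id]]$vox, integer(1))
      pc <- voxel_centers(grid, endvox)
      rc <- voxel_centers(grid, rvox)
      end_id <- root_nodes[which.min(rowSums(sweep(rc, 2, as.numeric(pc))^2))]
    }
    eid <- length(edges) + 1L
    edges[[eid]] <- list(from = leaf_id, to = end_id, axis = path)
    mark_edge(eid)
    mark_capture(path)
  }

  if (!length(edges)) stop("tracing produced no edges")
  path_len <- function(ax) {
    if (length(ax) < 2L) return(min(grid$h))
    ctr <- voxel_centers(grid, ax)
    sum(sqrt(rowSums(diff(ctr)^2)))
  }
  ed <- data.frame(
    from = vapply(edges, function(e) e$from, integer(1)),
    to = vapply(edges, function(e) e$to, integer(1)),
    length = vapply(edges, function(e) path_len(e$axis), numeric(1)),
    radius = vapply(edges, function(e) max(mean(edt_mm[e$axis]), min(grid$h) / 2),
      numeric(1)
    )
  )
  axes <- lapply(edges, function(e) as.integer(e$axis))

  # wall-adjacent regional maxima of the arrival time generate short spur
  # branches (length of the order of the tube radius); prune them and merge
  # the degree-2 nodes left behind, as in standard skeleton post-processing
  if (prune) {
    pr <- .prune_spurs(ed, axes,
      is_root = seq_along(nodes) %in% root_nodes,
      min_len = 2 * sqrt(sum(grid$h^2)), spur_factor = spur_factor
    )
    ed <- pr$ed
    axes <- pr$axes
  }

  # renumber surviving nodes (drops unused roots and pruned leafs)
  used <- sort(unique(c(ed$from, ed$to)))
  id_map <- setNames(seq_along(used), used)
  nd <- data.frame(
    id = seq_along(used),
    t(vapply(used, function(i) as.numeric(voxel_centers(grid, nodes[[i]]$vox)),
      numeric(3)
    ))
  )
  names(nd) <- c("id", "x", "y", "z")
  ed$from <- as.integer(id_map[as.character(ed$from)])
  ed$to <- as.integer(id_map[as.character(ed$to)])
  net <- vessel_network(nd, ed,
    compartment = compartment, medial_axes = axes,
    mu = domain$mu
  )
  net <- classify_nodes(net, domain)
  part <- .partition_vessel_mask(vm, net, grid)
  net$nodes$volume <- as.numeric(part$node_volume[as.character(net$nodes$id)])
  net
}

# nearest voxel carrying a node or edge marker within physical radius maxr
# of voxel `vox` (NA when none); ties broken by smallest distance
.nearest_marked <- function(node_at, edge_of, grid, vox, maxr) {
  d <- grid$shape
  ijk <- arrayInd(vox, d)[1, ]
  lo <- pmax(1L, ijk - ceiling(maxr / grid$h))
  hi <- pmin(d, ijk + ceiling(maxr / grid$h))
  box <- as.matrix(expand.grid(
    i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]
  ))
  bidx <- box[, 1] + d[1] * ((box[, 2] - 1) + d[2] * (box[, 3] - 1))
  hit <- node_at[bidx] > 0L | edge_of[bidx] > 0L
  if (!any(hit)) return(NA_integer_)
  bidx <- bidx[hit]
  box <- box[hit, , drop = FALSE]
  dd2 <- ((box[, 1] - ijk[1]) * grid$h[1])^2 +
    ((box[, 2] - ijk[2]) * grid$h[2])^2 +
    ((box[, 3] - ijk[3]) * grid$h[3])^2
  bidx[which.min(dd2)]
}

# voxelized straight segment between two voxel centers (both ends included)
.voxel_segment <- function(grid, v0, v1) {
  p0 <- as.numeric(voxel_centers(grid, v0))
  p1 <- as.numeric(voxel_centers(grid, v1))
  L <- sqrt(sum((p1 - p0)^2))
  if (L == 0) return(v0)
  ts <- seq(0, 1, length.out = max(2L, ceiling(L / (0.4 * min(grid$h))) + 1L))
  pts <- outer(ts, p1 - p0) + matrix(p0, length(ts), 3, byrow = TRUE)
  ax <- pos_to_index(grid, pts)
  ax[!duplicated(ax)]
}

# Remove terminal spur edges shorter than max(spur_factor * radius, min_len)
# and merge the degree-2 nodes this leaves behind. Root nodes are never
# removed and never merged away. Iterates until stable.
.prune_spurs <- function(ed, axes, is_root, min_len, spur_factor = 3) {
  nn <- max(c(ed$from, ed$to, which(is_root)))
  repeat {
    deg <- tabulate(c(ed$from, ed$to), nbins = nn)
    thr <- pmax(spur_factor * ed$radius, min_len)
    spur_end <- function(e) {
      a <- ed$from[e]
      b <- ed$to[e]
      (deg[a] == 1L && !is_root[a]) || (deg[b] == 1L && !is_root[b])
    }
    drop <- which(ed$length < thr &
      vapply(seq_len(nrow(ed)), spur_end, logical(1)))
    # keep at least one edge and never disconnect a lone terminal branch
    if (!length(drop) || length(drop) >= nrow(ed)) break
    ed <- ed[-drop, , drop = FALSE]
    axes <- axes[-drop]
    # merge chains through non-root degree-2 nodes
    repeat {
      deg <- tabulate(c(ed$from, ed$to), nbins = nn)
      mid <- which(deg == 2L & !is_root)
      if (!length(mid)) break
      m <- mid[1]
      es <- which(ed$from == m | ed$to == m)
      if (length(es) != 2L) break # parallel edges: leave as is
      orient <- function(e, tail_is_m) {
        ax <- axes[[e]]
        if ((tail_is_m && ed$to[e] != m) || (!tail_is_m && ed$from[e] != m)) {
          ax <- rev(ax)
          ends <- c(ed$to[e], ed$from[e])
        } else {
          ends <- c(ed$from[e], ed$to[e])
        }
        list(ax = ax, far = if (tail_is_m) ends[1] else ends[2])
      }
      o1 <- orient(es[1], tail_is_m = TRUE) # runs far1 -> m
      o2 <- orient(es[2], tail_is_m = FALSE) # runs m -> far2
      L <- ed$length[es[1]] + ed$length[es[2]]
      R <- (ed$length[es[1]] * ed$radius[es[1]] +
        ed$length[es[2]] * ed$radius[es[2]]) / L
      merged <- data.frame(from = o1$far, to = o2$far, length = L, radius = R)
      keep <- setdiff(seq_len(nrow(ed)), es)
      ed <- rbind(ed[keep, , drop = FALSE], merged)
      axes <- c(axes[keep], list(c(o1$ax, o2$ax[-1])))
    }
  }
  rownames(ed) <- NULL
  list(ed = ed, axes = axes)
}

#' Fast-marching arrival times (exported convenience wrapper)
#'
#' Solves \eqn{|\nabla T| = 1/S} with \eqn{T = 0} on the seed set by
#' second-order fast marching. Voxels with nonpositive speed are barriers.
#'
#' @param speed nonnegative numeric array [length/time in grid units]
#' @param seed logical array of zero-arrival voxels
#' @param grid a \code{voxel_grid}
#' @return numeric array of arrival times (Inf where unreachable)
#' @export
fast_march <- function(speed, seed, grid) {
  d <- grid$shape
  array(.cpp_fast_march(as.numeric(speed), as.logical(seed), d, grid$h), d)
}
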