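#' Gamma-variate arterial input function
#'
#' \eqn{c_{AIF}(t) = C_0 (t - t_0)^A e^{-(t - t_0)/B}} for \eqn{t > t_0},
#' zero before the delay. With the defaults A = 3, B = 1 s the bolus peaks
#' at \eqn{t_0 + A B}.
#'
#' @param t time(s) [s]
#' @param C0 amplitude [mol/m^3]
#' @param A dimensionless shape exponent
#' @param B time scale [s]
#' @param t0 bolus delay [s]
#' @return concentration values, same length as \code{t}
#' @export
aif_gamma <- function(t, C0 = 1, A = 3, B = 1, t0 = 7.5) {
  out <- numeric(length(t))
  late <- t > t0
  out[late] <- C0 * (t[late] - t0)^A * exp(-(t[late] - t0) / B)
  out
}

#' Split vessel edges into subsegments for tracer transport
#'
#' One subsegment per medial-axis voxel where a medial axis is available;
#' otherwise edges are split into approximately voxel-length pieces.
#' Subsegments are ordered downstream according to the solved edge flow
#' (edges with zero flow default to from-to order with a warning). When a
#' vessel mask is supplied, every mask voxel is assigned to the closest
#' medial-axis point, giving disc-like subsegment volumes and junction-region
#' node volumes; otherwise subsegment volumes split the cylinder volume
#' \eqn{\pi R^2 L} evenly.
#'
#' @param network \code{vessel_network} with solved edge flows
#' @param grid the \code{voxel_grid} the medial axes are indexed on
#' @param vessel_mask optional logical array: the binary vessel mask
#' @return object of class \code{edge_discretization}: per-edge list with
#'   subsegment count \code{n}, volumes [m^3], upstream node id \code{up},
#'   downstream node id \code{down}, absolute flow \code{q} [m^3/s] and the
#'   downstream-ordered medial axis voxels; plus \code{node_volume} [m^3]
#'   per node id when a vessel mask is given
#' @export
discretize_edges <- function(network, grid, vessel_mask = NULL) {
  ne <- nrow(network$edges)
  vv <- voxel_volume(grid)
  axes <- network$medial_axes
  zero_flow <- FALSE
  per_edge <- vector("list", ne)

  part <- NULL
  if (!is.null(vessel_mask) && !is.null(axes)) {
    part <- .partition_vessel_mask(vessel_mask, network, grid)
  }

  for (e in seq_len(ne)) {
    q <- network$edges$flow[e]
    if (is.na(q)) q <- 0
    up <- network$edges$from[e]
    down <- network$edges$to[e]
    if (q < 0) {
      up <- network$edges$to[e]
      down <- network$edges$from[e]
    } else if (q == 0) {
      zero_flow <- TRUE
    }
    ax <- if (!is.null(axes) && length(axes) >= e) axes[[e]] else NULL
    if (!is.null(ax) && length(ax)) {
      n <- length(ax)
      # medial axis lists run from the 'from' node to the 'to' node
      if (q < 0) ax <- rev(ax)
      if (!is.null(part)) {
        vols <- part$subseg_volumes[[e]]
        if (q < 0) vols <- rev(vols)
      } else {
        tube <- pi * (network$edges$radius[e] * .mm2m)^2 *
          (network$edges$length[e] * .mm2m)
        vols <- rep(tube / n, n)
      }
    } else {
      n <- max(1L, round(network$edges$length[e] / min(grid$h)))
      tube <- pi * (network$edges$radius[e] * .mm2m)^2 *
        (network$edges$length[e] * .mm2m)
      vols <- rep(tube / n, n)
      ax <- NULL
    }
    # discs claimed entirely by a junction region get the one-voxel floor,
    # paid back out of the junction volume so the total is conserved
    floored <- which(vols <= 0)
    if (length(floored) && !is.null(part)) {
      for (i in floored) {
        donor <- as.character(if (i <= n / 2) up else down)
        part$node_volume[donor] <- max(part$node_volume[donor] - vv, vv)
      }
    }
    vols[floored] <- vv
    per_edge[[e]] <- list(
      n = as.integer(n), volumes = vols, up = up, down = down,
      q = abs(q), axis = ax
    )
  }
  if (zero_flow) {
    warning("edge(s) with zero flow: subsegment order defaults to from-to")
  }
  node_volume <- if (!is.null(part)) part$node_volume else NULL
  structure(
    list(edges = per_edge, node_volume = node_volume),
    class = "edge_discretization"
  )
}

# Assign every vessel-mask voxel to the nearest medial-axis point or node
# center (geodesic nearest within the mask). Returns per-edge subsegment
# volumes (in from-to axis order) and per-node junction-region volumes.
.partition_vessel_mask <- function(vessel_mask, network, grid) {
  d <- grid$shape
  vv <- voxel_volume(grid)
  lab <- array(0L, d)
  # one label per medial-axis voxel (subsegment) and per node
  axes <- network$medial_axes
  next_label <- 0L
  seg_label <- vector("list", length(axes))
  for (e in seq_along(axes)) {
    ax <- axes[[e]]
    seg_label[[e]] <- next_label + seq_along(ax)
    lab[ax] <- next_label + seq_along(ax)
    next_label <- next_label + length(ax)
  }
  node_vox <- pos_to_index(grid, as.matrix(network$nodes[, c("x", "y", "z")]))
  node_lab <- next_label + seq_along(node_vox)
  lab[node_vox] <- node_lab # node centers override coincident axis points
  filled <- .cpp_nearest_label(
    as.integer(lab), as.logical(vessel_mask), d, grid$h
  )
  counts <- tabulate(filled, nbins = next_label + length(node_vox))
  subseg_volumes <- lapply(seq_along(axes), function(e) {
    counts[seg_label[[e]]] * vv
  })
  nvol <- pmax(counts[node_lab], 1L) * vv
  list(
    subseg_volumes = subseg_volumes,
    node_volume = setNames(nvol, as.character(network$nodes$id))
  )
}

# Unknown layout of the transport system:
# [ cD_a | cD_v | cN_a | cN_v | cE_a subsegments | cE_v subsegments ]
.transport_layout <- function(lay_flow, arterial, venous, disc_a, disc_v) {
  nva <- nrow(arterial$nodes)
  nvv <- nrow(venous$nodes)
  nsa <- sum(vapply(disc_a$edges, function(e) e$n, integer(1)))
  nsv <- sum(vapply(disc_v$edges, function(e) e$n, integer(1)))
  off_ea <- 2L * lay_flow$nvox + nva + nvv
  list(
    nvox = lay_flow$nvox, vox = lay_flow$vox, vmap = lay_flow$vmap,
    off_ca = 0L, off_cv = lay_flow$nvox,
    off_na = 2L * lay_flow$nvox, off_nv = 2L * lay_flow$nvox + nva,
    off_ea = off_ea, off_ev = off_ea + nsa,
    nsa = nsa, nsv = nsv,
    n = off_ea + nsa + nsv
  )
}

#' Assemble the upwind finite-volume tracer transport operator
#'
#' Builds the linear operator B and AIF forcing pattern of the semi-discrete
#' tracer system dc/dt = B c + b(t) over voxel, node and edge-subsegment
#' concentrations: upwind advection across voxel faces, upstream-weighted
#' perfusion exchange between the compartments, kernel-distributed terminal
#' exchange with the upstream side, plug-flow subsegment chains along edges,
#' and the gamma-variate input at arterial inlet roots.
#'
#' @param solution a \code{pressure_solution}
#' @param disc_a,disc_v \code{edge_discretization}s of the two trees
#' @param aif list with \code{C0}, \code{A}, \code{B}, \code{t0} for
#'   \code{\link{aif_gamma}}
#' @return object of class \code{tracer_transport}
#' @export
assemble_transport <- function(solution, disc_a, disc_v,
                               aif = list(C0 = 1, A = 3, B = 1, t0 = 7.5)) {
  sys <- solution$system
  dom <- sys$domain
  grid <- dom$grid
  vv <- voxel_volume(grid)
  lay <- .transport_layout(sys$layout, sys$arterial, sys$venous, disc_a, disc_v)
  if (any(dom$phi_a[dom$mask] <= 0) || any(dom$phi_v[dom$mask] <= 0)) {
    stop("tracer transport requires strictly positive porosities on the mask")
  }
  trip_i <- list()
  trip_j <- list()
  trip_x <- list()
  push <- function(i, j, x) {
    keep <- x != 0
    if (!any(keep)) return(invisible())
    n <- length(trip_i) + 1L
    trip_i[[n]] <<- i[keep]
    trip_j[[n]] <<- j[keep]
    trip_x[[n]] <<- x[keep]
  }
  bcoef <- numeric(lay$n)

  for (beta in c("a", "v")) {
    net <- if (beta == "a") solution$arterial else solution$venous
    disc <- if (beta == "a") disc_a else disc_v
    kernels <- if (beta == "a") sys$kernels_a else sys$kernels_v
    qterm <- if (beta == "a") solution$q_a else solution$q_v
    p <- if (beta == "a") solution$p_a else solution$p_v
    phiV <- (if (beta == "a") dom$phi_a else dom$phi_v)[lay$vox] * vv
    off_c <- if (beta == "a") lay$off_ca else lay$off_cv
    off_n <- if (beta == "a") lay$off_na else lay$off_nv
    off_e <- if (beta == "a") lay$off_ea else lay$off_ev
    ids <- net$nodes$id

    # --- voxel-voxel advection, upwind face concentration
    fc <- tpfa_transmissibilities(dom, beta)
    FF <- fc$t * (p[fc$i] - p[fc$j])
    # orient so flow goes u -> w
    u <- ifelse(FF >= 0, fc$i, fc$j)
    w <- ifelse(FF >= 0, fc$j, fc$i)
    Fq <- abs(FF)
    ru <- off_c + lay$vmap[u]
    rw <- off_c + lay$vmap[w]
    push(ru, ru, -Fq / phiV[lay$vmap[u]])
    push(rw, ru, Fq / phiV[lay$vmap[w]])

    # --- perfusion exchange with upstream-compartment concentration
    PV <- dom$alpha[lay$vox] * (solution$p_a[lay$vox] - solution$p_v[lay$vox]) * vv
    up_is_a <- PV >= 0
    src_col <- ifelse(up_is_a, lay$off_ca, lay$off_cv) + seq_len(lay$nvox)
    rows <- off_c + seq_len(lay$nvox)
    sgn <- if (beta == "a") -1 else 1 # tracer leaves arterial, enters venous
    push(rows, src_col, sgn * abs(PV) * sign(PV) / phiV)

    # --- terminal exchange through the support kernels
    for (id_chr in names(kernels)) {
      ker <- kernels[[id_chr]]
      q <- qterm[[id_chr]]
      if (is.na(q) || q == 0) next
      nrow_k <- off_n + match(as.integer(id_chr), ids)
      vrows <- off_c + lay$vmap[ker$idx]
      pv_loc <- phiV[lay$vmap[ker$idx]]
      if (q > 0) {
        # node is upstream: tissue voxels receive node concentration
        push(vrows, rep(nrow_k, length(vrows)), q * ker$wgt / pv_loc)
      } else {
        # tissue is upstream: voxels lose, node receives the kernel-weighted
        # tissue concentration
        push(vrows, vrows, -abs(q) * ker$wgt / pv_loc)
      }
    }

    # --- node balances
    Vn <- net$nodes$volume
    if (!is.null(disc$node_volume)) {
      Vn <- as.numeric(disc$node_volume[as.character(ids)])
    }
    Vn[is.na(Vn) | Vn <= 0] <- vv
    # index of first subsegment of each edge within this tree's block
    e_off <- c(0L, cumsum(vapply(disc$edges, function(e) e$n, integer(1))))
    for (r in seq_along(ids)) {
      id <- ids[r]
      cls <- net$nodes$class[r]
      nr <- off_n + r
      V <- Vn[r]
      if (cls == "root_terminal") {
        q <- qterm[[as.character(id)]]
        if (q < 0) {
          # inlet: relaxation toward the (possibly zero) input concentration
          push(nr, nr, -abs(q) / V)
          if (beta == "a") bcoef[nr] <- abs(q) / V
        } else if (q > 0) {
          # outlet: fed by the incoming edge, tracer leaves the system
          e <- .terminal_attachment(net, id)$edge
          last <- off_e + e_off[e] + disc$edges[[e]]$n
          push(nr, last, q / V)
          push(nr, nr, -q / V)
        }
      } else if (cls == "terminal") {
        q <- qterm[[as.character(id)]]
        if (is.na(q) || q == 0) next
        e <- .terminal_attachment(net, id)$edge
        if (q > 0) {
          # fluid arrives through the edge, leaves into the tissue
          last <- off_e + e_off[e] + disc$edges[[e]]$n
          push(nr, last, q / V)
          push(nr, nr, -q / V)
        } else {
          # fluid arrives from the tissue (kernel-weighted), leaves via edge
          ker <- kernels[[as.character(id)]]
          vcols <- off_c + lay$vmap[ker$idx]
          push(rep(nr, length(vcols)), vcols, abs(q) * ker$wgt / V)
          push(nr, nr, -abs(q) / V)
        }
      } else { # interior node: fed by incoming edges, drained by outgoing
        es <- which(net$edges$from == id | net$edges$to == id)
        for (e in es) {
          de <- disc$edges[[e]]
          if (de$q == 0) next
          if (de$down == id) {
            last <- off_e + e_off[e] + de$n
            push(nr, last, de$q / V)
          }
        }
        qout <- sum(vapply(es, function(e) {
          de <- disc$edges[[e]]
          if (de$up == id) de$q else 0
        }, numeric(1)))
        push(nr, nr, -qout / V)
      }
    }

    # --- edge subsegment chains (plug flow, full porosity)
    for (e in seq_along(disc$edges)) {
      de <- disc$edges[[e]]
      if (de$q == 0) next
      rows_e <- off_e + e_off[e] + seq_len(de$n)
      up_row <- off_n + match(de$up, ids)
      prev <- c(up_row, rows_e[-de$n])
      push(rows_e, prev, de$q / de$volumes)
      push(rows_e, rows_e, -de$q / de$volumes)
    }
  }

  B <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(lay$n, lay$n)
  )

  # control-volume sizes per unknown (for mass audits) and outlet bookkeeping
  vols <- numeric(lay$n)
  vols[lay$off_ca + seq_len(lay$nvox)] <- dom$phi_a[lay$vox] * vv
  vols[lay$off_cv + seq_len(lay$nvox)] <- dom$phi_v[lay$vox] * vv
  outlets <- list()
  for (beta in c("a", "v")) {
    net <- if (beta == "a") solution$arterial else solution$venous
    disc <- if (beta == "a") disc_a else disc_v
    qterm <- if (beta == "a") solution$q_a else solution$q_v
    off_n <- if (beta == "a") lay$off_na else lay$off_nv
    off_e <- if (beta == "a") lay$off_ea else lay$off_ev
    ids <- net$nodes$id
    Vn <- net$nodes$volume
    if (!is.null(disc$node_volume)) {
      Vn <- as.numeric(disc$node_volume[as.character(ids)])
    }
    Vn[is.na(Vn) | Vn <= 0] <- vv
    vols[off_n + seq_along(ids)] <- Vn
    e_off <- c(0L, cumsum(vapply(disc$edges, function(e) e$n, integer(1))))
    for (e in seq_along(disc$edges)) {
      vols[off_e + e_off[e] + seq_len(disc$edges[[e]]$n)] <- disc$edges[[e]]$volumes
    }
    for (r in which(net$nodes$class == "root_terminal")) {
      q <- qterm[[as.character(ids[r])]]
      if (q > 0) outlets[[length(outlets) + 1L]] <- c(row = off_n + r, q = q)
    }
  }

  structure(
    list(
      B = B, bcoef = bcoef, layout = lay, aif = aif, vols = vols,
      outlets = if (length(outlets)) do.call(rbind, outlets) else NULL,
      inflow_total = sum(bcoef * vols), # sum over inlets of |q|
      solution = solution, disc_a = disc_a, disc_v = disc_v
    ),
    class = "tracer_transport"
  )
}

#' CFL-derived time step for the tracer solve
#'
#' The strictest explicit (CFL) bound over all control volumes is
#' \eqn{\min_i \phi_i |\Omega_i| / (\text{total outflux})_i}, read off the
#' diagonal of the assembled transport operator. Backward Euler permits
#' longer steps: the step used is \code{factor} times the CFL bound, and the
#' number of steps is \code{floor(t_sim / dt)}.
#'
#' @param transport a \code{tracer_transport}
#' @param t_sim total simulated time [s]
#' @param factor multiple of the CFL bound (10 by default)
#' @return list with \code{dt} [s], \code{n_steps} and \code{cfl_dt}
#' @export
tracer_timestep <- function(transport, t_sim = 120, factor = 10) {
  dg <- -Matrix::diag(transport$B)
  mx <- max(dg)
  if (!is.finite(mx) || mx <= 0) stop("stagnant field: no flow anywhere")
  cfl <- 1 / mx
  dt <- factor * cfl
  n <- floor(t_sim / dt)
  if (n < 1L) {
    stop("time step exceeds the simulation window; lower `factor` or raise `t_sim`")
  }
  list(dt = dt, n_steps = as.integer(n), cfl_dt = cfl)
}

#' Run the backward-Euler tracer simulation
#'
#' Advances \eqn{(I - \delta t B) c^{i+1} = c^i + \delta t\, b_i} from
#' \eqn{c^0 = 0}, reusing one sparse factorization of the stepping matrix
#' for all iterations. Voxel concentration frames are retained on a coarse
#' sampling grid; compartment-mean curves are recorded at every step.
#'
#' @param transport a \code{tracer_transport}
#' @param dt time step [s]
#' @param n_steps number of steps
#' @param sample_dt spacing of stored voxel frames [s]
#' @return object of class \code{tracer_series}: sampled \code{times},
#'   voxel concentration \code{frames} (lists with \code{c_a}, \code{c_v}
#'   arrays), per-step \code{curves} (AIF and compartment means) and the
#'   final state vector
#' @export
backward_euler_run <- function(transport, dt, n_steps, sample_dt = 5) {
  lay <- transport$layout
  dom <- transport$solution$system$domain
  M <- Matrix::Diagonal(lay$n) - dt * transport$B
  fac <- Matrix::lu(M)
  cvec <- numeric(lay$n)
  aif <- transport$aif
  sample_every <- max(1L, round(sample_dt / dt))
  times <- numeric(0)
  frames <- list()
  curves <- data.frame(
    t = dt * seq_len(n_steps), aif = NA_real_,
    mean_ca = NA_real_, mean_cv = NA_real_,
    mass = NA_real_, inflow = NA_real_, outflow = NA_real_
  )
  mvox <- lay$vmap[dom$mask]
  grab <- function(cvec) {
    c_a <- c_v <- array(NA_real_, dom$grid$shape)
    c_a[lay$vox] <- cvec[lay$off_ca + seq_len(lay$nvox)]
    c_v[lay$vox] <- cvec[lay$off_cv + seq_len(lay$nvox)]
    list(c_a = c_a, c_v = c_v)
  }
  # initial state (t = 0)
  times <- 0
  frames[[1]] <- grab(cvec)
  for (i in seq_len(n_steps)) {
    t_i <- (i - 1) * dt
    caif_i <- aif_gamma(t_i, aif$C0, aif$A, aif$B, aif$t0)
    b <- transport$bcoef * caif_i
    cvec <- as.numeric(Matrix::solve(fac, cvec + dt * b))
    curves$aif[i] <- aif_gamma(i * dt, aif$C0, aif$A, aif$B, aif$t0)
    ca <- cvec[lay$off_ca + seq_len(lay$nvox)]
    cv <- cvec[lay$off_cv + seq_len(lay$nvox)]
    curves$mean_ca[i] <- mean(ca)
    curves$mean_cv[i] <- mean(cv)
    # discrete mass audit terms: stored mass after the step, inflow rate at
    # the step's forcing time, outflow rate at the implicit end point
    curves$mass[i] <- sum(transport$vols * cvec)
    curves$inflow[i] <- transport$inflow_total * caif_i
    curves$outflow[i] <- if (is.null(transport$outlets)) 0 else {
      sum(transport$outlets[, "q"] * cvec[transport$outlets[, "row"]])
    }
    if (i %% sample_every == 0L || i == n_steps) {
      times <- c(times, i * dt)
      frames[[length(frames) + 1L]] <- grab(cvec)
    }
  }
  structure(
    list(
      times = times, frames = frames, curves = curves,
      final_state = cvec, dt = dt, n_steps = n_steps,
      transport = transport
    ),
    class = "tracer_series"
  )
}

#' Observable concentration, time-to-peak and mean-transit-time maps
#'
#' The observable (volumetric) tracer concentration is
#' \eqn{C(x,t) = (c_a \phi_a + c_v \phi_v)(1 - Hct)}; TTP is the sample time
#' of its per-voxel maximum (NA where the curve stays flat); MTT is the
#' kinetic identity CBV/CBF \eqn{= (\phi_a + \phi_v)/P} where perfusion is
#' positive.
#'
#' @param series a \code{tracer_series}
#' @param domain a \code{tissue_domain}
#' @param perfusion a \code{perfusion_map}
#' @param hct hematocrit in [0, 1)
#' @return object of class \code{kinetic_maps}: \code{TTP} [s], \code{MTT}
#'   [s], observable frames \code{C}, masked means, and \code{flat} (logical
#'   array marking voxels with undefined TTP)
#' @export
kinetic_maps <- function(series, domain, perfusion, hct = 0.40) {
  stopifnot(hct >= 0, hct < 1)
  m <- domain$mask
  Cfr <- lapply(series$frames, function(f) {
    (f$c_a * domain$phi_a + f$c_v * domain$phi_v) * (1 - hct)
  })
  nfr <- length(Cfr)
  best <- array(-Inf, domain$grid$shape)
  ttp <- array(NA_real_, domain$grid$shape)
  for (i in seq_len(nfr)) {
    Ci <- Cfr[[i]]
    upd <- m & (Ci > best)
    ttp[upd] <- series$times[i]
    best[upd] <- Ci[upd]
  }
  flat <- m & (best <= 0)
  ttp[flat] <- NA_real_
  P <- perfusion$P
  mtt <- (domain$phi_a + domain$phi_v) / P
  mtt[!m | !(P > 0)] <- NA_real_
  structure(
    list(
      TTP = ttp, MTT = mtt, C = Cfr, times = series$times, flat = flat,
      mean_TTP = mean(ttp[m], na.rm = TRUE),
      mean_MTT = mean(mtt[m], na.rm = TRUE)
    ),
    class = "kinetic_maps"
  )
}
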