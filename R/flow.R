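#' Two-point flux approximation transmissibilities
#'
#' For every interior face between two masked voxels the TPFA
#' transmissibility is the harmonic mean of the two half-cell conductivities
#' \eqn{\lambda = k_\beta/\mu} times face area over center distance. Faces
#' towards unmasked voxels or the image border get no entry, which is the
#' no-flow Neumann boundary condition of the tissue domain.
#'
#' @param domain a \code{tissue_domain}
#' @param compartment \code{"a"} or \code{"v"}
#' @return data.frame with columns \code{i}, \code{j} (1-based linear voxel
#'   indices of the two masked cells) and \code{t} [m^3 Pa^-1 s^-1]
#' @export
tpfa_transmissibilities <- function(domain, compartment = c("a", "v")) {
  compartment <- match.arg(compartment)
  grid <- domain$grid
  d <- grid$shape
  kfield <- if (compartment == "a") domain$k_a else domain$k_v
  lam <- kfield / domain$mu # [m^2 / (Pa s)]
  mask <- domain$mask
  out_i <- out_j <- integer(0)
  out_t <- numeric(0)
  h_m <- grid$h * .mm2m
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    # voxel pairs (idx, idx + stride) both inside the mask
    sel <- slice.index(mask, ax) < d[ax]
    stride <- c(1, d[1], d[1] * d[2])[ax]
    i1 <- which(mask & sel)
    i2 <- i1 + stride
    keep <- mask[i2]
    i1 <- i1[keep]
    i2 <- i2[keep]
    if (!length(i1)) next
    area <- prod(h_m[-ax])
    dist <- h_m[ax]
    l1 <- lam[i1]
    l2 <- lam[i2]
    t <- (2 * l1 * l2 / (l1 + l2)) * area / dist
    out_i <- c(out_i, i1)
    out_j <- c(out_j, i2)
    out_t <- c(out_t, t)
  }
  data.frame(i = out_i, j = out_j, t = out_t)
}

# Unknown layout of the coupled system:
#   [ p_a on masked voxels | p_v on masked voxels | node pressures a | node pressures v ]
.flow_layout <- function(domain, arterial, venous) {
  vox <- which(domain$mask)
  nvox <- length(vox)
  vmap <- array(0L, domain$grid$shape)
  vmap[vox] <- seq_len(nvox)
  list(
    vox = vox, nvox = nvox, vmap = vmap,
    ids_a = arterial$nodes$id, ids_v = venous$nodes$id,
    off_va = 0L, off_vv = nvox,
    off_na = 2L * nvox,
    off_nv = 2L * nvox + nrow(arterial$nodes),
    n = 2L * nvox + nrow(arterial$nodes) + nrow(venous$nodes)
  )
}

#' Assemble the coupled tissue/vessel pressure system
#'
#' Builds the sparse linear system in the concatenated unknowns
#' (voxel pressures of both compartments, then node pressures of both
#' trees). Rows are: voxel mass balance with TPFA fluxes, the perfusion
#' exchange \eqn{\pm\alpha_i(p_{a,i}-p_{v,i})|\Omega_i|} and kernel-
#' distributed terminal flows; Kirchhoff balance at interior nodes;
#' the pressure-continuity closure
#' \eqn{\tilde q_k = (\gamma_\beta/\mu)(\tilde p_k - \sum_j w_j p_j)} at
#' interior terminals; and Dirichlet identity rows at root terminals.
#'
#' @param domain a \code{tissue_domain}
#' @param arterial,venous classified \code{vessel_network}s
#' @param kernels_a,kernels_v \code{support_kernels} for the interior
#'   terminals of each tree
#' @param gamma_a,gamma_v pressure-drop closure parameters [m^3]
#' @param p_root_a,p_root_v Dirichlet boundary pressures [Pa]; scalars or
#'   vectors named by root node id
#' @return object of class \code{flow_system}
#' @export
assemble_flow_system <- function(domain, arterial, venous,
                                 kernels_a, kernels_v,
                                 gamma_a, gamma_v,
                                 p_root_a, p_root_v) {
  if (gamma_a <= 0 || gamma_v <= 0) stop("gamma must be > 0")
  lay <- .flow_layout(domain, arterial, venous)
  vv <- voxel_volume(domain$grid)
  mu <- domain$mu
  trip_i <- list()
  trip_j <- list()
  trip_x <- list()
  rhs <- numeric(lay$n)
  push <- function(i, j, x) {
    n <- length(trip_i) + 1L
    trip_i[[n]] <<- i
    trip_j[[n]] <<- j
    trip_x[[n]] <<- x
  }

  for (beta in c("a", "v")) {
    net <- if (beta == "a") arterial else venous
    kernels <- if (beta == "a") kernels_a else kernels_v
    gamma <- if (beta == "a") gamma_a else gamma_v
    p_root <- if (beta == "a") p_root_a else p_root_v
    off_v <- if (beta == "a") lay$off_va else lay$off_vv
    off_n <- if (beta == "a") lay$off_na else lay$off_nv
    ids <- net$nodes$id

    if (!any(net$nodes$class == "root_terminal") &&
      all(domain$alpha[domain$mask] == 0)) {
      stop("floating compartment: no root terminal and alpha is zero")
    }

    # TPFA voxel-voxel fluxes
    fc <- tpfa_transmissibilities(domain, beta)
    r1 <- off_v + lay$vmap[fc$i]
    r2 <- off_v + lay$vmap[fc$j]
    push(r1, r1, fc$t)
    push(r1, r2, -fc$t)
    push(r2, r2, fc$t)
    push(r2, r1, -fc$t)

    # perfusion exchange (sink in arterial rows, source in venous rows)
    av <- domain$alpha[lay$vox] * vv
    sgn <- if (beta == "a") 1 else -1
    rows <- off_v + seq_len(lay$nvox)
    push(rows, lay$off_va + seq_len(lay$nvox), sgn * av)
    push(rows, lay$off_vv + seq_len(lay$nvox), -sgn * av)

    # terminal flows distributed by the support kernels, with the terminal
    # flow expressed through the attached edge's Hagen-Poiseuille relation
    for (id_chr in names(kernels)) {
      id <- as.integer(id_chr)
      ker <- kernels[[id_chr]]
      att <- .terminal_attachment(net, id)
      kap <- net$edges$conductance[att$edge]
      col_k <- off_n + match(id, ids)
      col_n <- off_n + match(att$neighbour, ids)
      vrow <- off_v + lay$vmap[ker$idx]
      # - q_k * wgt_i, with q_k = kappa (p_n - p_k)
      push(vrow, rep(col_n, length(vrow)), -ker$wgt * kap)
      push(vrow, rep(col_k, length(vrow)), ker$wgt * kap)
      # pressure-continuity closure row for the terminal node:
      # kappa (p_n - p_k) - (gamma/mu)(p_k - sum_i wgt_i p_i) = 0
      push(col_k, col_n, kap)
      push(col_k, col_k, -kap - gamma / mu)
      push(
        rep(col_k, length(vrow)), off_v + lay$vmap[ker$idx],
        (gamma / mu) * ker$wgt
      )
    }

    # interior node Kirchhoff rows
    deg <- node_degree(net)
    for (r in seq_len(nrow(net$nodes))) {
      id <- ids[r]
      cls <- net$nodes$class[r]
      row <- off_n + r
      if (cls == "root_terminal") {
        push(row, row, 1)
        p0 <- if (length(p_root) > 1L) p_root[[as.character(id)]] else p_root
        if (is.null(p0) || is.na(p0)) {
          stop("missing root pressure for node ", id)
        }
        rhs[row] <- p0
      } else if (cls == "interior") {
        es <- which(net$edges$from == id | net$edges$to == id)
        for (e in es) {
          other <- if (net$edges$from[e] == id) net$edges$to[e] else net$edges$from[e]
          kap <- net$edges$conductance[e]
          push(row, off_n + match(other, ids), kap)
          push(row, row, -kap)
        }
      } else if (cls == "terminal" && !(as.character(id) %in% names(kernels))) {
        stop("interior terminal ", id, " has no support kernel")
      }
    }
  }

  A <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(lay$n, lay$n)
  )
  structure(
    list(
      A = A, b = rhs, layout = lay, domain = domain,
      arterial = arterial, venous = venous,
      kernels_a = kernels_a, kernels_v = kernels_v,
      gamma_a = gamma_a, gamma_v = gamma_v
    ),
    class = "flow_system"
  )
}

#' Solve the coupled pressure system
#'
#' Default path is a complete sparse LU factorization; \code{"gmres"} runs
#' restarted GMRES with Jacobi preconditioning; \code{"dense"} uses a dense
#' direct solve and is intended as an independent cross-check on small
#' grids. Node pressures, terminal flows (through the attached edge) and
#' edge flows are back-substituted from the solution vector.
#'
#' @param system a \code{flow_system}
#' @param method \code{"direct"}, \code{"gmres"} or \code{"dense"}
#' @param tol relative residual tolerance
#' @param maxiter GMRES iteration cap
#' @return object of class \code{pressure_solution}: pressure fields
#'   \code{p_a}, \code{p_v} (NA outside the mask), updated networks with
#'   node pressures and edge flows, terminal flows, residual norm and
#'   iteration count
#' @export
solve_pressure <- function(system, method = c("auto", "direct", "gmres", "dense"),
                           tol = 1e-6, maxiter = 2000L) {
  method <- match.arg(method)
  A <- system$A
  b <- system$b
  if (method == "auto") {
    # wide kernel supports make the border rows of the matrix near-dense;
    # a complete factorization then fills in catastrophically, so switch to
    # GMRES preconditioned by the LU of a truncated-kernel companion system
    supp <- vapply(
      c(system$kernels_a, system$kernels_v),
      function(k) length(k$idx), integer(1)
    )
    method <- if (length(supp) && max(supp) > 2500L) "gmres" else "direct"
  }
  iters <- 1L
  x <- switch(method,
    direct = as.numeric(Matrix::solve(A, b)),
    dense = as.numeric(solve(as.matrix(A), b)),
    gmres = {
      ps <- .precond_solver(system)
      g <- .gmres(A, b,
        tol = tol * 1e-2, maxiter = maxiter, restart = 400L, psolve = ps
      )
      # one step of iterative refinement sharpens the solution beyond the
      # left-preconditioned residual plateau
      r <- as.numeric(b - A %*% g$x)
      g2 <- .gmres(A, r,
        tol = 1e-4, maxiter = maxiter, restart = 400L, psolve = ps
      )
      iters <- g$iterations + g2$iterations
      g$x + g2$x
    }
  )
  resid <- sqrt(sum(as.numeric(A %*% x - b)^2)) / max(sqrt(sum(b^2)), 1e-300)
  if (!is.finite(resid) || resid > tol) {
    stop(sprintf(
      "pressure solve did not reach tolerance: relative residual %.3e > %.1e",
      resid, tol
    ))
  }
  lay <- system$layout
  p_a <- p_v <- array(NA_real_, system$domain$grid$shape)
  p_a[lay$vox] <- x[lay$off_va + seq_len(lay$nvox)]
  p_v[lay$vox] <- x[lay$off_vv + seq_len(lay$nvox)]
  arterial <- system$arterial
  venous <- system$venous
  arterial$nodes$pressure <- x[lay$off_na + seq_len(nrow(arterial$nodes))]
  venous$nodes$pressure <- x[lay$off_nv + seq_len(nrow(venous$nodes))]
  fill_flows <- function(net) {
    pf <- net$nodes$pressure[match(net$edges$from, net$nodes$id)]
    pt <- net$nodes$pressure[match(net$edges$to, net$nodes$id)]
    net$edges$flow <- net$edges$conductance * (pf - pt)
    net
  }
  arterial <- fill_flows(arterial)
  venous <- fill_flows(venous)
  term_flow <- function(net) {
    ids <- c(interior_terminals(net), root_terminals(net))
    q <- vapply(ids, function(id) {
      att <- .terminal_attachment(net, id)
      kap <- net$edges$conductance[att$edge]
      pn <- net$nodes$pressure[match(att$neighbour, net$nodes$id)]
      pk <- net$nodes$pressure[match(id, net$nodes$id)]
      kap * (pn - pk)
    }, numeric(1))
    setNames(q, as.character(ids))
  }
  structure(
    list(
      p_a = p_a, p_v = p_v,
      arterial = arterial, venous = venous,
      q_a = term_flow(arterial), q_v = term_flow(venous),
      residual_norm = resid, solver_iterations = iters,
      system = system
    ),
    class = "pressure_solution"
  )
}

#' @export
print.pressure_solution <- function(x, ...) {
  mb <- mass_balance(x)
  cat(sprintf(
    "<pressure_solution> residual %.2e; inflow %.4e m^3/s, outflow %.4e m^3/s, total perfusion %.4e m^3/s\n",
    x$residual_norm, mb$root_inflow, mb$root_outflow, mb$total_perfusion
  ))
  invisible(x)
}

# Block-diagonal preconditioner for the coupled system. The voxel block
# (TPFA + perfusion exchange) is symmetric positive semi-definite and is
# factorized by a supernodal Cholesky after a tiny diagonal shift; the node
# block is small and solved densely. The vessel-tissue coupling the
# preconditioner ignores has rank bounded by twice the number of terminal
# node columns, so preconditioned GMRES converges in a correspondingly
# bounded number of iterations.
.precond_solver <- function(system) {
  lay <- system$layout
  nv <- 2L * lay$nvox
  n <- nrow(system$A)
  A11 <- Matrix::forceSymmetric(system$A[seq_len(nv), seq_len(nv)])
  shift <- 1e-10 * mean(Matrix::diag(A11))
  ch <- Matrix::Cholesky(A11, Imult = shift, LDL = FALSE, perm = TRUE)
  A22 <- as.matrix(system$A[(nv + 1L):n, (nv + 1L):n])
  lu22 <- qr(A22)
  function(v) {
    c(
      as.numeric(Matrix::solve(ch, v[seq_len(nv)], system = "A")),
      as.numeric(solve(lu22, v[(nv + 1L):n]))
    )
  }
}

# restarted GMRES with left preconditioning: `psolve` applies the inverse
# of the preconditioner (defaults to Jacobi scaling)
.gmres <- function(A, b, x0 = NULL, tol = 1e-6, restart = 60L,
                   maxiter = 2000L, psolve = NULL) {
  n <- length(b)
  if (is.null(psolve)) {
    dg <- Matrix::diag(A)
    dg[dg == 0] <- 1
    psolve <- function(v) v / dg
  }
  x <- if (is.null(x0)) numeric(n) else x0
  bn <- sqrt(sum(psolve(b)^2))
  if (bn == 0) return(list(x = numeric(n), iterations = 0L))
  total <- 0L
  repeat {
    r <- psolve(as.numeric(b - A %*% x))
    beta <- sqrt(sum(r^2))
    if (beta / bn <= tol || total >= maxiter) break
    m <- min(restart, maxiter - total)
    V <- matrix(0, n, m + 1)
    H <- matrix(0, m + 1, m)
    cs <- sn <- numeric(m)
    g <- numeric(m + 1)
    g[1] <- beta
    V[, 1] <- r / beta
    k <- 0L
    for (j in seq_len(m)) {
      w <- psolve(as.numeric(A %*% V[, j]))
      for (i in seq_len(j)) {
        H[i, j] <- sum(w * V[, i])
        w <- w - H[i, j] * V[, i]
      }
      H[j + 1, j] <- sqrt(sum(w^2))
      if (H[j + 1, j] > 0) V[, j + 1] <- w / H[j + 1, j]
      # apply accumulated Givens rotations
      for (i in seq_len(j - 1)) {
        t1 <- cs[i] * H[i, j] + sn[i] * H[i + 1, j]
        H[i + 1, j] <- -sn[i] * H[i, j] + cs[i] * H[i + 1, j]
        H[i, j] <- t1
      }
      dd <- sqrt(H[j, j]^2 + H[j + 1, j]^2)
      cs[j] <- H[j, j] / dd
      sn[j] <- H[j + 1, j] / dd
      H[j, j] <- dd
      H[j + 1, j] <- 0
      g[j + 1] <- -sn[j] * g[j]
      g[j] <- cs[j] * g[j]
      k <- j
      if (abs(g[j + 1]) / bn <= tol) break
    }
    y <- backsolve(H[seq_len(k), seq_len(k), drop = FALSE], g[seq_len(k)])
    x <- x + V[, seq_len(k), drop = FALSE] %*% y
    x <- as.numeric(x)
    total <- total + k
    if (abs(g[k + 1]) / bn <= tol) break
  }
  list(x = x, iterations = total)
}

#' Global and per-node mass-balance audit
#'
#' Reports total arterial root inflow, venous root outflow and the tissue
#' perfusion integral \eqn{\int_{\Omega_B} P\,dx} (all m^3/s), which must
#' agree pairwise for a conservative solution, plus the largest Kirchhoff
#' residual over interior nodes relative to the local flow magnitude.
#'
#' @param solution a \code{pressure_solution}
#' @return list with \code{root_inflow}, \code{root_outflow},
#'   \code{total_perfusion}, \code{rel_err_in_perf},
#'   \code{rel_err_out_perf}, \code{max_node_rel_imbalance}
#' @export
mass_balance <- function(solution) {
  dom <- solution$system$domain
  vv <- voxel_volume(dom$grid)
  m <- dom$mask
  P <- dom$alpha * (solution$p_a - solution$p_v)
  total_perf <- sum(P[m]) * vv
  inflow <- -sum(solution$q_a[as.character(root_terminals(solution$arterial))])
  outflow <- sum(solution$q_v[as.character(root_terminals(solution$venous))])
  node_imb <- function(net) {
    worst <- 0
    for (r in which(net$nodes$class == "interior")) {
      id <- net$nodes$id[r]
      es <- which(net$edges$from == id | net$edges$to == id)
      q <- ifelse(net$edges$from[es] == id,
        -net$edges$flow[es], net$edges$flow[es]
      )
      scale <- max(sum(abs(q)), 1e-300)
      worst <- max(worst, abs(sum(q)) / scale)
    }
    worst
  }
  list(
    root_inflow = inflow, root_outflow = outflow,
    total_perfusion = total_perf,
    rel_err_in_perf = abs(inflow - total_perf) / max(abs(total_perf), 1e-300),
    rel_err_out_perf = abs(outflow - total_perf) / max(abs(total_perf), 1e-300),
    max_node_rel_imbalance = max(node_imb(solution$arterial), node_imb(solution$venous))
  )
}

#' Perfusion map from a pressure solution
#'
#' Pointwise \eqn{P = \alpha (p_a - p_v)} on the tissue mask, in 1/s, with
#' the conventional ml/min/100ml map attached.
#'
#' @param solution a \code{pressure_solution}
#' @param domain a \code{tissue_domain} (defaults to the solve's domain)
#' @return object of class \code{perfusion_map}: list with \code{P}
#'   (array, 1/s, NA outside mask), \code{P_ml_min_100ml} and the masked
#'   mean of each
#' @export
perfusion_map <- function(solution, domain = solution$system$domain) {
  P <- domain$alpha * (solution$p_a - solution$p_v)
  P[!domain$mask] <- NA_real_
  structure(
    list(
      P = P,
      P_ml_min_100ml = P * .perfusion_unit_factor,
      mean_P = mean(P[domain$mask]),
      mean_P_ml_min_100ml = mean(P[domain$mask]) * .perfusion_unit_factor
    ),
    class = "perfusion_map"
  )
}

#' @export
print.perfusion_map <- function(x, ...) {
  cat(sprintf(
    "<perfusion_map> mean %.4g 1/s = %.4g ml/min/100ml\n",
    x$mean_P, x$mean_P_ml_min_100ml
  ))
  invisible(x)
}
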