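#' Vascular network graph
#'
#' An undirected graph of vessel nodes and edges for one compartment
#' (arterial or venous). Nodes carry physical positions (mm), a class
#' (\code{interior}, \code{terminal} or \code{root_terminal}), a distribution
#' volume [m^3] and, after solving, a pressure [Pa]. Edges carry the medial
#' axis geodesic length L (mm), mean tubular radius R (mm), the
#' Hagen-Poiseuille conductance \eqn{\kappa = \pi R^4 / (8 \mu L)}
#' [m^3/(Pa s)] and, after solving, the signed flow from \code{from} to
#' \code{to} [m^3/s]. Medial axes are stored as 1-based linear voxel indices.
#'
#' @param nodes data.frame with columns \code{id, x, y, z} (mm) and
#'   optionally \code{class}, \code{volume}, \code{pressure}
#' @param edges data.frame with columns \code{from, to, length, radius}
#'   (mm) and optionally \code{conductance}, \code{flow}
#' @param compartment \code{"a"} (arterial) or \code{"v"} (venous)
#' @param medial_axes optional list (one integer vector per edge) of voxel
#'   indices along each edge's medial axis
#' @param mu viscosity [Pa s] used to fill missing conductances
#' @return object of class \code{vessel_network}
#' @export
vessel_network <- function(nodes, edges, compartment = c("a", "v"),
                           medial_axes = NULL, mu = 3.0e-3) {
  compartment <- match.arg(compartment)
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  stopifnot(all(c("id", "x", "y", "z") %in% names(nodes)))
  stopifnot(all(c("from", "to", "length", "radius") %in% names(edges)))
  if (is.null(nodes$class)) nodes$class <- NA_character_
  if (is.null(nodes$volume)) nodes$volume <- NA_real_
  if (is.null(nodes$pressure)) nodes$pressure <- NA_real_
  if (any(edges$length <= 0)) stop("edge lengths must be > 0")
  if (any(edges$radius <= 0)) stop("edge radii must be > 0")
  if (any(edges$from == edges$to)) stop("self-loop edges are not allowed")
  if (!all(c(edges$from, edges$to) %in% nodes$id)) {
    stop("edge endpoints must reference existing node ids")
  }
  if (is.null(edges$conductance)) {
    edges$conductance <- edge_conductance(
      edges$radius * .mm2m, edges$length * .mm2m, mu
    )
  }
  if (is.null(edges$flow)) edges$flow <- NA_real_
  net <- structure(
    list(
      compartment = compartment, nodes = nodes, edges = edges,
      medial_axes = medial_axes
    ),
    class = "vessel_network"
  )
  if (!network_connected(net)) stop("vessel network must be connected")
  net
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf(
    "<vessel_network '%s'> %d nodes (%d root, %d terminal), %d edges\n",
    x$compartment, nrow(x$nodes),
    sum(x$nodes$class == "root_terminal", na.rm = TRUE),
    sum(x$nodes$class == "terminal", na.rm = TRUE), nrow(x$edges)
  ))
  invisible(x)
}

#' Node degrees of a vessel network
#' @param network a \code{vessel_network}
#' @return named integer vector, one entry per node id
#' @export
node_degree <- function(network) {
  ids <- network$nodes$id
  deg <- table(factor(c(network$edges$from, network$edges$to), levels = ids))
  setNames(as.integer(deg), ids)
}

network_connected <- function(network) {
  ids <- network$nodes$id
  n <- length(ids)
  if (n <= 1L) return(TRUE)
  pos <- match(c(network$edges$from, network$edges$to), ids)
  adj <- split(
    c(match(network$edges$to, ids), match(network$edges$from, ids)),
    pos
  )
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    nb <- adj[[as.character(v)]]
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' Hagen-Poiseuille conductance of a straight tube
#'
#' \eqn{\kappa = \pi R^4 / (8 \mu L)}: laminar flow of a Newtonian fluid
#' through a rigid tube of constant circular cross-section.
#'
#' @param R tube radius [m]
#' @param L tube length [m]
#' @param mu dynamic viscosity [Pa s]
#' @return conductance [m^3 Pa^-1 s^-1] such that flow = conductance *
#'   pressure drop
#' @export
edge_conductance <- function(R, L, mu) {
  if (any(R <= 0) || any(L <= 0) || any(mu <= 0)) {
    stop("edge_conductance: R, L and mu must all be > 0")
  }
  pi * R^4 / (8 * mu * L)
}

#' Classify nodes as interior, terminal or root terminal
#'
#' Degree-1 nodes are terminals; a terminal whose position lies on the
#' tissue/background interface (within one voxel diagonal of the mask
#' boundary shell, or on the image border) is a pressurized root terminal.
#' All other nodes are interior.
#'
#' @param network a \code{vessel_network}
#' @param domain a \code{tissue_domain}
#' @param tol_mm boundary tolerance in mm; defaults to one voxel diagonal
#' @return the network with \code{nodes$class} filled
#' @export
classify_nodes <- function(network, domain, tol_mm = NULL) {
  grid <- domain$grid
  if (is.null(tol_mm)) tol_mm <- sqrt(sum(grid$h^2))
  deg <- node_degree(network)
  if (!any(deg == 1L)) stop("no terminals: every node has degree >= 2")
  shell <- boundary_shell(domain$mask, grid)
  cls <- rep("interior", nrow(network$nodes))
  leaf <- deg[as.character(network$nodes$id)] == 1L
  cls[leaf] <- "terminal"
  pos <- as.matrix(network$nodes[, c("x", "y", "z")])
  vidx <- pos_to_index(grid, pos)
  near_boundary <- shell$dist[vidx] <= tol_mm | shell$shell[vidx]
  cls[leaf & near_boundary] <- "root_terminal"
  if (!any(cls == "root_terminal")) {
    stop("no pressurized inlet/outlet: no terminal lies on the domain boundary")
  }
  network$nodes$class <- cls
  if (all(is.na(network$nodes$volume))) {
    network$nodes$volume <- voxel_volume(grid)
  }
  network
}

#' Interior terminals of a classified network
#' @param network classified \code{vessel_network}
#' @return node ids of interior (non-root) terminals
#' @export
interior_terminals <- function(network) {
  network$nodes$id[network$nodes$class == "terminal"]
}

#' Root terminals of a classified network
#' @param network classified \code{vessel_network}
#' @return node ids of pressurized root terminals
#' @export
root_terminals <- function(network) {
  network$nodes$id[network$nodes$class == "root_terminal"]
}

# the single neighbour (node id) and edge row of a degree-1 node
.terminal_attachment <- function(network, id) {
  e <- which(network$edges$from == id | network$edges$to == id)
  if (length(e) != 1L) stop("node ", id, " is not a terminal (degree != 1)")
  other <- ifelse(network$edges$from[e] == id,
    network$edges$to[e], network$edges$from[e]
  )
  list(edge = e, neighbour = other)
}

#' Serialize a vessel network to JSON
#'
#' Writes nodes (positions, classes, volumes, pressures), edges (endpoints,
#' length, radius, conductance, flow) and medial-axis voxel lists to a JSON
#' document that \code{\link{read_network_json}} restores losslessly.
#'
#' @param network a \code{vessel_network}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_network_json <- function(network, path) {
  doc <- list(
    compartment = network$compartment,
    nodes = network$nodes,
    edges = network$edges,
    medial_axes = network$medial_axes
  )
  jsonlite::write_json(doc, path,
    dataframe = "columns", auto_unbox = TRUE,
    digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a vessel network from JSON
#' @param path file written by \code{\link{write_network_json}}
#' @return a \code{vessel_network}
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ma <- doc$medial_axes
  if (!is.null(ma)) ma <- lapply(ma, as.integer)
  net <- vessel_network(
    nodes = as.data.frame(doc$nodes),
    edges = as.data.frame(doc$edges),
    compartment = doc$compartment,
    medial_axes = ma
  )
  net
}
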