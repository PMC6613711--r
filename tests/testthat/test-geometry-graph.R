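test_that("Hagen-Poiseuille conductance follows the fourth-power law", {
  # hand evaluation of pi R^4 / (8 mu L) for R = 1 mm, L = 10 mm
  expect_equal(edge_conductance(1e-3, 10e-3, 3.0e-3), 1.3090e-8,
    tolerance = 1e-4
  )
  k0 <- edge_conductance(2e-4, 5e-3, 3e-3)
  expect_equal(edge_conductance(4e-4, 5e-3, 3e-3), 16 * k0)
  expect_equal(edge_conductance(2e-4, 10e-3, 3e-3), k0 / 2)
  expect_error(edge_conductance(-1e-4, 5e-3, 3e-3), "must all be > 0")
  expect_error(edge_conductance(1e-4, 0, 3e-3), "must all be > 0")
})

test_that("node classification distinguishes interior, terminal and root nodes", {
  g <- voxel_grid(c(32, 32, 1), c(1, 1, 1))
  dom <- tissue_domain(g, array(TRUE, c(32, 32, 1)))
  # Y-shaped tree rooted on the image boundary
  nodes <- data.frame(
    id = 1:4,
    x = c(0.5, 14, 22, 22), y = c(16, 16, 10, 22), z = 0.5
  )
  edges <- data.frame(
    from = c(1, 2, 2), to = c(2, 3, 4),
    length = c(13.5, 10, 10), radius = 0.3
  )
  net <- classify_nodes(vessel_network(nodes, edges, "a"), dom)
  cls <- setNames(net$nodes$class, net$nodes$id)
  expect_identical(unname(cls["1"]), "root_terminal")
  expect_identical(unname(cls["2"]), "interior")
  expect_identical(unname(cls[c("3", "4")]), c("terminal", "terminal"))

  # classification is invariant under node relabeling
  perm <- c(3L, 1L, 4L, 2L)
  nodes2 <- nodes
  nodes2$id <- perm
  edges2 <- edges
  edges2$from <- perm[edges$from]
  edges2$to <- perm[edges$to]
  net2 <- classify_nodes(vessel_network(nodes2, edges2, "a"), dom)
  expect_identical(
    net2$nodes$class[match(perm, net2$nodes$id)],
    net$nodes$class
  )
})

test_that("degenerate networks are rejected with informative errors", {
  g <- voxel_grid(c(32, 32, 1), c(1, 1, 1))
  dom <- tissue_domain(g, array(TRUE, c(32, 32, 1)))
  # single edge fully interior to the mask: no pressurized inlet/outlet
  interior_net <- vessel_network(
    data.frame(id = 1:2, x = c(10, 20), y = 16, z = 0.5),
    data.frame(from = 1, to = 2, length = 10, radius = 0.3), "a"
  )
  expect_error(classify_nodes(interior_net, dom), "no pressurized inlet/outlet")
  # triangle: every node has degree 2, no terminals at all
  tri <- vessel_network(
    data.frame(id = 1:3, x = c(5, 25, 15), y = c(5, 5, 25), z = 0.5),
    data.frame(
      from = c(1, 2, 3), to = c(2, 3, 1),
      length = c(20, 23, 23), radius = 0.3
    ), "a"
  )
  expect_error(classify_nodes(tri, dom), "no terminals")
  # disconnected graphs are rejected at construction
  expect_error(
    vessel_network(
      data.frame(id = 1:4, x = c(1, 2, 10, 11), y = 1, z = 0.5),
      data.frame(from = c(1, 3), to = c(2, 4), length = 1, radius = 0.1), "a"
    ),
    "connected"
  )
  expect_error(
    vessel_network(
      data.frame(id = 1, x = 1, y = 1, z = 0.5),
      data.frame(from = 1, to = 1, length = 1, radius = 0.1), "a"
    ),
    "self-loop"
  )
})

test_that("series and parallel edges reduce like resistor networks", {
  # series: root -- e1 -- mid -- e2 -- terminal behaves exactly like a
  # single edge with 1/k_eq = 1/k1 + 1/k2; parallel edges add conductances.
  g <- voxel_grid(c(24, 24, 1), c(1, 1, 1))
  dom <- tissue_domain(g, array(TRUE, c(24, 24, 1)))
  mku <- function(nodes, edges) {
    net <- classify_nodes(vessel_network(nodes, edges, "a"), dom)
    ker <- build_kernels(net, dom, epsilon = 8, dimension = 2)
    list(net = net, ker = ker)
  }
  ven <- mku(
    data.frame(id = 1:2, x = c(23.5, 16), y = 12, z = 0.5),
    data.frame(from = 1, to = 2, length = 7.5, radius = 0.4)
  )
  solve_q <- function(nodes, edges) {
    a <- mku(nodes, edges)
    sys <- assemble_flow_system(
      dom, a$net, ven$net, a$ker, ven$ker,
      1e-14, 1e-14, 10.6e3, 1.6e3
    )
    sol <- solve_pressure(sys)
    list(q = unname(sol$q_a[as.character(interior_terminals(a$net))]), sol = sol)
  }
  r1 <- 0.35
  r2 <- 0.25
  L1 <- 4
  L2 <- 3.5
  k1 <- edge_conductance(r1 * 1e-3, L1 * 1e-3, dom$mu)
  k2 <- edge_conductance(r2 * 1e-3, L2 * 1e-3, dom$mu)
  series <- solve_q(
    data.frame(id = 1:3, x = c(0.5, 4.5, 8), y = 12, z = 0.5),
    data.frame(
      from = c(1, 2), to = c(2, 3),
      length = c(L1, L2), radius = c(r1, r2)
    )
  )
  keq <- 1 / (1 / k1 + 1 / k2)
  # radius/length pair realizing the equivalent conductance
  req <- (keq * 8 * dom$mu * (L1 + L2) * 1e-3 / pi)^0.25 * 1e3
  equiv <- solve_q(
    data.frame(id = 1:2, x = c(0.5, 8), y = 12, z = 0.5),
    data.frame(from = 1, to = 2, length = L1 + L2, radius = req)
  )
  expect_equal(series$q, equiv$q, tolerance = 1e-10)

  # parallel middle pair against its conductance sum
  parallel <- solve_q(
    data.frame(id = 1:4, x = c(0.5, 3, 6, 8), y = 12, z = 0.5),
    data.frame(
      from = c(1, 2, 2, 3), to = c(2, 3, 3, 4),
      length = c(2.5, 3, 3, 2), radius = c(0.4, r1, r2, 0.4)
    )
  )
  kp <- edge_conductance(r1 * 1e-3, 3e-3, dom$mu) +
    edge_conductance(r2 * 1e-3, 3e-3, dom$mu)
  rp <- (kp * 8 * dom$mu * 3e-3 / pi)^0.25 * 1e3
  merged <- solve_q(
    data.frame(id = 1:4, x = c(0.5, 3, 6, 8), y = 12, z = 0.5),
    data.frame(
      from = c(1, 2, 3), to = c(2, 3, 4),
      length = c(2.5, 3, 2), radius = c(0.4, rp, 0.4)
    )
  )
  expect_equal(parallel$q, merged$q, tolerance = 1e-10)
})

test_that("two-node network solves the Hagen-Poiseuille relation exactly", {
  fx <- tiny_coupled_fixture()
  sol <- solve_pressure(fx$system)
  net <- sol$arterial
  kap <- net$edges$conductance[1]
  p <- setNames(net$nodes$pressure, net$nodes$id)
  expect_equal(unname(sol$q_a["2"]), unname(kap * (p["1"] - p["2"])),
    tolerance = 1e-12
  )
})

test_that("network JSON serialization round-trips", {
  sc <- frog_scenario()
  path <- tempfile(fileext = ".json")
  write_network_json(sc$arterial, path)
  back <- read_network_json(path)
  expect_equal(back$nodes$x, sc$arterial$nodes$x)
  expect_equal(back$nodes$class, sc$arterial$nodes$class)
  expect_equal(back$edges$length, sc$arterial$edges$length)
  expect_equal(back$edges$conductance, sc$arterial$edges$conductance)
  expect_identical(
    lapply(back$medial_axes, as.integer),
    lapply(sc$arterial$medial_axes, as.integer)
  )
  unlink(path)
})
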