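test_that("TPFA transmissibilities match the uniform-grid closed form", {
  # homogeneous k on isotropic h^3 voxels: t = (k/mu) h for every face
  g <- voxel_grid(c(6, 6, 6), c(2, 2, 2))
  dom <- tissue_domain(g, array(TRUE, c(6, 6, 6)), k_a = 4e-12, mu = 2e-3)
  fc <- tpfa_transmissibilities(dom, "a")
  expect_equal(nrow(fc), 3 * 5 * 36) # interior faces per axis
  expect_equal(unique(fc$t), (4e-12 / 2e-3) * 2e-3, tolerance = 1e-12)

  # harmonic mean across a k | 3k face
  kf <- array(1e-12, c(6, 6, 6))
  kf[4:6, , ] <- 3e-12
  dom2 <- tissue_domain(g, array(TRUE, c(6, 6, 6)), k_a = kf, mu = 2e-3)
  fc2 <- tpfa_transmissibilities(dom2, "a")
  mixed <- fc2[kf[fc2$i] != kf[fc2$j], ]
  expect_equal(unique(mixed$t), (1.5e-12 / 2e-3) * 2e-3, tolerance = 1e-12)

  # faces across the mask boundary carry no entry (no-flow condition)
  m <- array(TRUE, c(6, 6, 6))
  m[1:2, , ] <- FALSE
  dom3 <- tissue_domain(g, m)
  fc3 <- tpfa_transmissibilities(dom3, "a")
  expect_true(all(m[fc3$i] & m[fc3$j]))
})

test_that("solved pressures conserve mass globally and per node", {
  fl <- frog_flow()
  mb <- fl$balance
  expect_lt(mb$rel_err_in_perf, 1e-6)
  expect_lt(mb$rel_err_out_perf, 1e-6)
  expect_lt(mb$max_node_rel_imbalance, 1e-8)
  expect_lt(fl$solution$residual_norm, 1e-6)
})

test_that("sparse direct, dense direct and GMRES solutions agree", {
  fx <- tiny_coupled_fixture(n = 12)
  s_direct <- solve_pressure(fx$system, method = "direct")
  s_dense <- solve_pressure(fx$system, method = "dense")
  s_gmres <- solve_pressure(fx$system, method = "gmres", tol = 1e-12)
  m <- fx$domain$mask
  scale <- max(abs(s_dense$p_a[m]))
  expect_lt(max(abs(s_direct$p_a[m] - s_dense$p_a[m])) / scale, 1e-8)
  expect_lt(max(abs(s_direct$p_v[m] - s_dense$p_v[m])) / scale, 1e-8)
  expect_lt(max(abs(s_gmres$p_a[m] - s_dense$p_a[m])) / scale, 1e-8)
  expect_equal(s_direct$arterial$nodes$pressure, s_dense$arterial$nodes$pressure,
    tolerance = 1e-8
  )
})

test_that("mirror-symmetric compartments give antisymmetric pressures", {
  # same geometry and parameters for both compartments, boundary pressures
  # swapped: p_a(x) + p_v(mirror(x)) is the constant p_a0 + p_v0
  fx <- tiny_coupled_fixture(n = 16, k_a = 2e-12, k_v = 2e-12)
  sol <- solve_pressure(fx$system)
  pa <- sol$p_a[, , 1]
  pv <- sol$p_v[, , 1]
  pv_mirror <- pv[rev(seq_len(nrow(pv))), ]
  expect_equal(pa + pv_mirror,
    matrix(10.6e3 + 1.6e3, nrow(pa), ncol(pa)),
    tolerance = 1e-8
  )
})

test_that("raising the arterial boundary pressure does not decrease perfusion", {
  base <- frog_flow()$perfusion$mean_P
  sc <- frog_scenario()
  sc$config$p_root_a <- sc$config$p_root_a * 1.1
  up <- simulate_flow(sc)$perfusion$mean_P
  expect_gte(up, base)
})

test_that("perfusion map applies the pressure-difference law and units", {
  g <- voxel_grid(c(4, 4, 1), c(1, 1, 1))
  dom <- tissue_domain(g, array(TRUE, c(4, 4, 1)), alpha = 1e-6)
  fake <- list(
    p_a = array(1500, c(4, 4, 1)), p_v = array(500, c(4, 4, 1)),
    system = list(domain = dom)
  )
  pm <- perfusion_map(fake, dom)
  # alpha = 1e-6 m s/kg and 1000 Pa difference: P = 1e-3 1/s = 6 ml/min/100ml
  expect_equal(unique(pm$P[dom$mask]), 1e-3)
  expect_equal(pm$mean_P_ml_min_100ml, 6)
  # equal pressures: zero perfusion; doubled alpha: doubled perfusion
  fake0 <- fake
  fake0$p_v <- fake0$p_a
  expect_equal(unique(perfusion_map(fake0, dom)$P[dom$mask]), 0)
  dom2 <- tissue_domain(g, array(TRUE, c(4, 4, 1)), alpha = 2e-6)
  fake$system$domain <- dom2
  expect_equal(unique(perfusion_map(fake, dom2)$P[dom2$mask]), 2e-3)
})

test_that("perfusion scales linearly with the closure parameter gamma", {
  fx1 <- tiny_coupled_fixture(gamma = 1e-14)
  # with the tissue resistance dominated by gamma, doubling gamma should
  # nearly double the terminal flow; exact linearity holds at fixed drop
  s1 <- solve_pressure(fx1$system)
  q1 <- unname(s1$q_a["2"])
  pk <- s1$arterial$nodes$pressure[2]
  ker <- fx1$kernels_a[["2"]]
  pbar <- sum(ker$wgt * s1$p_a[ker$idx])
  gamma <- 1e-14
  expect_equal(q1, (gamma / fx1$domain$mu) * (pk - pbar), tolerance = 1e-10)
  expect_error(
    assemble_flow_system(
      fx1$domain, fx1$arterial, fx1$venous,
      fx1$kernels_a, fx1$kernels_v, -1e-14, 1e-14, 1e4, 1e3
    ),
    "gamma"
  )
})

test_that("near-zero perfusion coupling decouples the compartments", {
  # alpha -> 0: vanishing perfusion and network flows approaching the
  # independent single-compartment solution
  fx <- tiny_coupled_fixture(alpha = 1e-18)
  sol <- solve_pressure(fx$system)
  P <- fx$domain$alpha * (sol$p_a - sol$p_v)
  expect_lt(max(abs(P[fx$domain$mask])), 1e-12)
  expect_lt(abs(sum(sol$q_a)), 1e-18) # root inflow balances terminal outflow
})

test_that("a compartment with no root and no coupling is rejected", {
  g <- voxel_grid(c(16, 16, 1), c(1, 1, 1))
  dom <- tissue_domain(g, array(TRUE, c(16, 16, 1)), alpha = 0)
  net_a <- classify_nodes(vessel_network(
    data.frame(id = 1:2, x = c(0.5, 8), y = c(8, 8), z = 0.5),
    data.frame(from = 1, to = 2, length = 7.5, radius = 0.4), "a"
  ), dom)
  # venous tree floating in the interior: classify refuses it already
  expect_error(
    classify_nodes(vessel_network(
      data.frame(id = 1:2, x = c(8, 12), y = c(4, 4), z = 0.5),
      data.frame(from = 1, to = 2, length = 4, radius = 0.4), "v"
    ), dom),
    "no pressurized inlet/outlet"
  )
})
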