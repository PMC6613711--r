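test_that("gamma-variate input peaks at t0 + A*B and is causal", {
  t <- seq(0, 60, by = 0.001)
  c <- aif_gamma(t, C0 = 1, A = 3, B = 1, t0 = 7.5)
  expect_equal(t[which.max(c)], 7.5 + 3 * 1, tolerance = 1e-3)
  expect_true(all(c[t <= 7.5] == 0))
  expect_true(all(c >= 0))
  # amplitude scales linearly
  expect_equal(aif_gamma(12, C0 = 2.5), 2.5 * aif_gamma(12, C0 = 1))
})

test_that("edge discretization partitions volume and follows flow direction", {
  sc <- frog_scenario()
  sol <- frog_flow()$solution
  grid <- sc$domain$grid
  disc <- discretize_edges(sol$arterial, grid, sc$mask_a)
  # one subsegment per medial-axis voxel
  for (e in seq_along(disc$edges)) {
    expect_equal(disc$edges[[e]]$n, length(sol$arterial$medial_axes[[e]]))
  }
  # mask voxels are fully distributed over subsegments and node regions;
  # only the one-voxel floor applied to subsegments whose disc is claimed
  # by a junction region can add volume on top
  tot <- sum(unlist(lapply(disc$edges, function(d) d$volumes))) +
    sum(disc$node_volume)
  expected_vol <- sum(sc$mask_a) * voxel_volume(grid)
  expect_gte(tot, expected_vol - 1e-18)
  expect_lt((tot - expected_vol) / expected_vol, 0.2)
  # a straight tube has no junction overlap: the partition is exact there
  g1 <- voxel_grid(c(64, 64, 1), c(0.5, 0.5, 1))
  dom1 <- tissue_domain(g1, array(TRUE, c(64, 64, 1)))
  tube <- make_tree(list(
    root = c(16, 0.25, 0.5), dir = c(0, 1, 0), depth = 0, len0 = 20,
    len_decay = 1, radius0 = 1.2, radius_decay = 1, angle = 0,
    jitter = 0, seed = 1
  ), dom1)
  tnet <- tube$network
  tnet$edges$flow <- 1e-9
  tdisc <- discretize_edges(tnet, g1, tube$mask)
  ttot <- sum(tdisc$edges[[1]]$volumes) + sum(tdisc$node_volume)
  expect_equal(ttot, sum(tube$mask) * voxel_volume(g1), tolerance = 1e-12)
  # reversing the solved flow reverses the downstream order
  rev_net <- sol$arterial
  rev_net$edges$flow <- -rev_net$edges$flow
  disc_r <- discretize_edges(rev_net, grid, sc$mask_a)
  for (e in seq_along(disc$edges)) {
    expect_identical(disc_r$edges[[e]]$axis, rev(disc$edges[[e]]$axis))
    expect_identical(disc_r$edges[[e]]$up, disc$edges[[e]]$down)
  }
  # zero flow: from-to order kept, with a warning
  z_net <- sol$arterial
  z_net$edges$flow <- 0
  expect_warning(discretize_edges(z_net, grid, sc$mask_a), "zero flow")
})

test_that("time step is ten times the tightest CFL bound", {
  # single-control-volume toy: outflux q from volume phi*V gives the CFL
  # step phi*V/q, and the default step is 10 times that
  q <- 2e-9
  phiV <- 5e-10
  toy <- structure(
    list(B = Matrix::sparseMatrix(
      i = 1, j = 1, x = -q / phiV,
      dims = c(1, 1)
    )),
    class = "tracer_transport"
  )
  st <- tracer_timestep(toy, t_sim = 120, factor = 10)
  expect_equal(st$cfl_dt, phiV / q)
  expect_equal(st$dt, 10 * phiV / q)
  expect_equal(st$n_steps, floor(120 / st$dt))
  # halving all flows doubles the step
  toy2 <- toy
  toy2$B <- toy$B / 2
  expect_equal(tracer_timestep(toy2)$dt, 2 * st$dt)
  # stagnant systems are rejected
  toy0 <- toy
  toy0$B <- toy$B * 0
  expect_error(tracer_timestep(toy0), "stagnant")
})

test_that("upwind operator has the M-matrix sign pattern", {
  tr <- frog_tracer()$transport
  B <- tr$B
  expect_true(all(Matrix::diag(B) <= 0))
  off <- B - Matrix::Diagonal(x = Matrix::diag(B))
  expect_true(all(off@x >= 0))
  # column sums weighted by control volumes vanish except at the outlets
  # (internal exchanges conserve tracer exactly)
  colsum <- as.numeric(tr$vols %*% B)
  out_cols <- tr$outlets[, "row"]
  expect_equal(unname(colsum[out_cols]), unname(-tr$outlets[, "q"]),
    tolerance = 1e-10
  )
  expect_lt(max(abs(colsum[-out_cols])), 1e-18)
})

test_that("tracer stays nonnegative and mass is audited every step", {
  tr <- frog_tracer()
  cv <- tr$series$curves
  # positivity of every sampled state
  for (f in tr$series$frames) {
    m <- !is.na(f$c_a)
    expect_true(all(f$c_a[m] >= 0))
    expect_true(all(f$c_v[m] >= 0))
  }
  expect_true(all(tr$series$final_state >= 0))
  # discrete telescoping: mass gained each step equals dt * (in - out)
  dt <- tr$series$dt
  m_prev <- c(0, head(cv$mass, -1))
  expect_equal(cv$mass - m_prev, dt * (cv$inflow - cv$outflow),
    tolerance = 1e-10
  )
  # venous response is delayed and dispersed relative to the arterial one
  expect_gt(cv$t[which.max(cv$mean_cv)], cv$t[which.max(cv$mean_ca)])
  expect_gt(cv$t[which.max(cv$mean_ca)], cv$t[which.max(cv$aif)])
  expect_lt(max(cv$mean_cv), max(cv$mean_ca))
})

test_that("zero input gives an identically zero concentration field", {
  sc <- frog_scenario()
  fl <- frog_flow()
  sc0 <- sc
  sc0$config$C0 <- 1e-300 # amplitude scaling: linear in C0
  tr0 <- simulate_tracer(fl, sc0, t_sim = 30)
  expect_lt(max(abs(tr0$series$final_state)), 1e-280)
})

test_that("a single edge reproduces the plug-flow transit delay", {
  # constant flow q through a tube: the subsegment chain delays the front
  # by the fluid transit time L * A / q (full porosity), within one
  # subsegment's transit time
  fx <- tiny_coupled_fixture(n = 16, gamma = 1e-13)
  sol <- solve_pressure(fx$system)
  grid <- fx$domain$grid
  disc_a <- discretize_edges(sol$arterial, grid)
  disc_v <- discretize_edges(sol$venous, grid)
  tr <- assemble_transport(sol, disc_a, disc_v,
    aif = list(C0 = 1, A = 3, B = 1, t0 = 0)
  )
  q <- abs(unname(sol$q_a["2"]))
  vol_edge <- sum(disc_a$edges[[1]]$volumes)
  delay <- vol_edge / q
  st <- tracer_timestep(tr, t_sim = 6 * delay, factor = 1)
  lay <- tr$layout
  # compare centroid times of the concentration curves at the inlet root
  # node and at the last arterial subsegment
  n_last <- lay$off_ea + sum(vapply(disc_a$edges, function(e) e$n, integer(1)))
  root_row <- lay$off_na + 1L
  M <- Matrix::Diagonal(lay$n) - st$dt * tr$B
  fac <- Matrix::lu(M)
  cvec <- numeric(lay$n)
  t_in <- t_out <- 0
  w_in <- w_out <- 0
  for (i in seq_len(st$n_steps)) {
    b <- tr$bcoef * aif_gamma((i - 1) * st$dt, 1, 3, 1, 0)
    cvec <- as.numeric(Matrix::solve(fac, cvec + st$dt * b))
    t_i <- i * st$dt
    w1 <- cvec[root_row]
    w2 <- cvec[n_last]
    t_in <- t_in + t_i * w1
    w_in <- w_in + w1
    t_out <- t_out + t_i * w2
    w_out <- w_out + w2
  }
  measured_delay <- t_out / w_out - t_in / w_in
  expect_equal(measured_delay, delay,
    tolerance = (delay / disc_a$edges[[1]]$n + st$dt) / delay
  )
})

test_that("kinetic maps implement the observable-concentration identities", {
  g <- voxel_grid(c(6, 6, 1), c(1, 1, 1))
  dom <- tissue_domain(g, array(TRUE, c(6, 6, 1)),
    phi_a = 0.05, phi_v = 0.10, alpha = 1e-6
  )
  ca <- array(1, c(6, 6, 1))
  series <- list(
    times = c(0, 5, 10),
    frames = list(
      list(c_a = ca * 0, c_v = ca * 0),
      list(c_a = ca, c_v = ca),
      list(c_a = ca * 0.5, c_v = ca * 0.5)
    )
  )
  fake_sol <- list(
    p_a = array(1500, c(6, 6, 1)), p_v = array(500, c(6, 6, 1)),
    system = list(domain = dom)
  )
  pm <- perfusion_map(fake_sol, dom)
  km <- kinetic_maps(series, dom, pm, hct = 0.40)
  # C = (ca*phi_a + cv*phi_v)(1 - Hct) = 0.09 for unit concentrations
  expect_equal(unique(km$C[[2]][dom$mask]), 0.09)
  # TTP is the sample time of the peak
  expect_equal(unique(km$TTP[dom$mask]), 5)
  # MTT = (phi_a + phi_v) / P pointwise: 0.15 / 1e-3 = 150 s
  expect_equal(unique(km$MTT[dom$mask]), 150)
  # flat curves yield an undefined (NA) TTP and are flagged
  flat <- list(
    times = c(0, 5),
    frames = list(
      list(c_a = ca * 0, c_v = ca * 0),
      list(c_a = ca * 0, c_v = ca * 0)
    )
  )
  kf <- kinetic_maps(flat, dom, pm, hct = 0.40)
  expect_true(all(is.na(kf$TTP[dom$mask])))
  expect_true(all(kf$flat[dom$mask]))
  # MTT spot check: phi sum 0.15 at P = 0.005 1/s gives 30 s
  expect_equal(0.15 / 0.005, 30)
})

test_that("mean transit time follows CBV/CBF on the solved fixture", {
  tr <- frog_tracer()
  sc <- frog_scenario()
  fl <- frog_flow()
  m <- sc$domain$mask & fl$perfusion$P > 0
  lhs <- tr$maps$MTT[m]
  rhs <- (sc$domain$phi_a[m] + sc$domain$phi_v[m]) / fl$perfusion$P[m]
  expect_equal(lhs, rhs, tolerance = 1e-12)
})
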