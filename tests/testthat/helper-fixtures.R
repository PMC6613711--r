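# Shared fixtures. Expensive objects (the reference scenario and its flow/
# tracer solutions) are built once per test run and cached.

.fix <- new.env(parent = emptyenv())

frog_scenario <- function() {
  if (is.null(.fix$scenario)) .fix$scenario <- make_paired_scenario(seed = 7)
  .fix$scenario
}

frog_flow <- function() {
  if (is.null(.fix$flow)) .fix$flow <- simulate_flow(frog_scenario())
  .fix$flow
}

frog_tracer <- function() {
  if (is.null(.fix$tracer)) {
    .fix$tracer <- simulate_tracer(frog_flow(), frog_scenario())
  }
  .fix$tracer
}

# small fully masked quasi-2D domain with one arterial and one venous
# stub network (1 root + 1 interior terminal each), solvable in ~0.1 s
tiny_coupled_fixture <- function(n = 16, alpha = 1e-6, gamma = 1e-14,
                                 p_a0 = 10.6e3, p_v0 = 1.6e3,
                                 k_a = 1e-12, k_v = 5e-12, epsilon = n / 3) {
  g <- voxel_grid(c(n, n, 1), c(1, 1, 1))
  dom <- tissue_domain(g, array(TRUE, c(n, n, 1)),
    alpha = alpha, k_a = k_a, k_v = k_v
  )
  mid <- n / 2
  net_a <- classify_nodes(vessel_network(
    data.frame(id = 1:2, x = c(0.5, mid), y = c(mid, mid), z = 0.5),
    data.frame(from = 1, to = 2, length = mid - 0.5, radius = 0.4), "a"
  ), dom)
  net_v <- classify_nodes(vessel_network(
    data.frame(id = 1:2, x = c(n - 0.5, mid), y = c(mid, mid), z = 0.5),
    data.frame(from = 1, to = 2, length = mid - 0.5, radius = 0.4), "v"
  ), dom)
  ka <- build_kernels(net_a, dom, epsilon = epsilon, dimension = 2)
  kv <- build_kernels(net_v, dom, epsilon = epsilon, dimension = 2)
  sys <- assemble_flow_system(
    dom, net_a, net_v, ka, kv, gamma, gamma, p_a0, p_v0
  )
  list(
    domain = dom, arterial = net_a, venous = net_v,
    kernels_a = ka, kernels_v = kv, system = sys
  )
}

# elliptical 2D tissue domain used by extraction phantoms
phantom_domain <- function(shape = c(160, 160, 1), h = c(0.5, 0.5, 1),
                           semi = c(36, 34)) {
  g <- voxel_grid(shape, h)
  ctr <- shape[1:2] * h[1:2] / 2
  idx <- seq_len(prod(shape))
  pos <- voxel_centers(g, idx)
  m <- array(FALSE, shape)
  m[idx[((pos[, 1] - ctr[1]) / semi[1])^2 +
    ((pos[, 2] - ctr[2]) / semi[2])^2 <= 1]] <- TRUE
  tissue_domain(g, m)
}
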