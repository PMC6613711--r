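test_that("fast marching with unit speed reproduces Euclidean distance", {
  n <- 50L
  g <- voxel_grid(c(n, n, n), c(1, 1, 1))
  seed <- array(FALSE, c(n, n, n))
  seed[25, 25, 25] <- TRUE
  T <- fast_march(array(1, c(n, n, n)), seed, g)
  idx <- seq_len(n^3)
  pos <- voxel_centers(g, idx)
  ctr <- as.numeric(voxel_centers(g, which(seed)))
  D <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
  expect_lt(max(abs(T - D)), 1) # within one voxel on a 50^3 grid
  # arrival times are nonnegative and zero exactly on the seed
  expect_true(all(T >= 0))
  expect_identical(which(T == 0), which(seed))
})

test_that("adaptive thresholding keeps bright tubes and drops background", {
  set.seed(3)
  img <- array(rnorm(100 * 100, 1, 0.5), c(100, 100, 1))
  truth <- array(FALSE, c(100, 100, 1))
  truth[10:90, 30, 1] <- TRUE
  truth[10:90, 70, 1] <- TRUE
  img[truth] <- 10
  seg <- adaptive_threshold(img, window = 15, k = 3)
  expect_gte(mean(seg[truth]), 0.99) # tube voxels retained
  expect_lte(mean(seg[!truth]), 0.01) # background false positives
  # constant image: empty mask with a warning; huge k: empty by monotonicity
  expect_warning(cc <- adaptive_threshold(array(2, c(40, 40, 1))), "empty")
  expect_equal(sum(cc), 0)
  expect_warning(k9 <- adaptive_threshold(img, window = 15, k = 1e6), "empty")
  expect_equal(sum(k9), 0)
})

test_that("satellite components get reconnected along bright structure", {
  g <- voxel_grid(c(100, 40, 1), c(1, 1, 1))
  img <- array(0.5, c(100, 40, 1))
  m <- array(FALSE, c(100, 40, 1))
  m[10:40, 18:22, 1] <- TRUE # root structure
  m[46:90, 18:22, 1] <- TRUE # satellite across a gap
  img[10:90, 18:22, 1] <- 5 # bright corridor spans the gap
  out <- connect_components(img, m, g)
  lab <- .cpp_label_components(out, g$shape, 26L)
  expect_equal(max(lab), 1L)
  expect_true(all(out[m]))
  # already-connected masks pass through unchanged
  expect_identical(connect_components(img, out, g), out)
  # no admissible path when the speed vanishes everywhere
  expect_error(connect_components(array(0, c(100, 40, 1)), m, g), "zero")
})

test_that("a straight tube extracts as one edge with correct geometry", {
  g <- voxel_grid(c(64, 64, 1), c(0.5, 0.5, 1))
  dom <- tissue_domain(g, array(TRUE, c(64, 64, 1)))
  spec <- list(
    root = c(16, 0.25, 0.5), dir = c(0, 1, 0), depth = 0, len0 = 20,
    len_decay = 1, radius0 = 1.2, radius_decay = 1, angle = 0,
    jitter = 0, seed = 1
  )
  tube <- make_tree(spec, dom)
  net <- extract_graph(tube$mask, dom)
  expect_equal(nrow(net$edges), 1L)
  expect_setequal(net$nodes$class, c("root_terminal", "terminal"))
  expect_equal(net$edges$length, 20, tolerance = 0.5 / 20 * 2) # +- 1 voxel
  expect_equal(net$edges$radius, 1.2, tolerance = 0.25 / 1.2) # +- 0.5 voxel
})

test_that("a symmetric Y extracts as 4 nodes and 3 edges", {
  dom <- phantom_domain()
  spec <- list(
    root = c(40, 6.2, 0.5), dir = c(0, 1, 0), depth = 1, len0 = 20,
    len_decay = 0.8, radius0 = 1.5, radius_decay = 0.8, angle = 35,
    jitter = 0, seed = 3
  )
  tr <- make_tree(spec, dom)
  net <- extract_graph(tr$mask, dom)
  expect_equal(nrow(net$nodes), 4L)
  expect_equal(nrow(net$edges), 3L)
  expect_equal(sum(net$nodes$class == "root_terminal"), 1L)
  expect_equal(sum(net$nodes$class == "terminal"), 2L)
  expect_equal(sum(net$nodes$class == "interior"), 1L)
})

test_that("graph extraction round-trips rasterized trees", {
  # tree obeying the raster contract (every branch at least one voxel in
  # radius): leaf and root counts recover exactly, total medial-axis
  # length within two voxel diagonals per branch
  dom <- phantom_domain()
  spec <- list(
    root = c(40, 6.2, 0.5), dir = c(0, 1, 0), depth = 3, len0 = 18,
    len_decay = 0.6, radius0 = 2, radius_decay = 0.7, angle = 30,
    jitter = 0, seed = 3
  )
  tr <- make_tree(spec, dom)
  net <- extract_graph(tr$mask, dom)
  gt <- tr$network
  deg_gt <- node_degree(gt)
  expect_equal(sum(net$nodes$class == "terminal"), 8L) # 2^3 leafs
  expect_equal(sum(net$nodes$class == "root_terminal"), 1L)
  expect_equal(nrow(net$edges), nrow(gt$edges))
  budget <- 2 * sqrt(sum(dom$grid$h^2)) * nrow(gt$edges)
  expect_lt(abs(sum(net$edges$length) - sum(gt$edges$length)), budget)
  # extracted medial axes lie (essentially) inside the vessel mask; the
  # short junction bridges may cut a corner voxel
  expect_gt(mean(tr$mask[unlist(net$medial_axes)]), 0.98)
  # masks not touching the boundary or disconnected masks are rejected
  blob <- array(FALSE, dom$grid$shape)
  blob[70:90, 70:90, 1] <- TRUE
  expect_error(extract_graph(blob, dom), "no root points")
  two <- tr$mask
  two[150:155, 150:155, 1] <- TRUE
  expect_error(extract_graph(two, dom), "single connected component")
})
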