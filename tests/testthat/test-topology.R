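test_that("an unbranched projection yields the single bar (0, path length)", {
  cell <- straight_cell(n_nodes = 100, spacing = 1, soma_r = 2, r = 0.5)
  b <- tmd_barcode(cell)
  expect_equal(nrow(b), 1)
  expect_equal(b$birth, 0)
  expect_equal(b$death, 100, tolerance = 1e-6)
})

test_that("the two-terminal Y matches the hand-worked elimination", {
  # trunk 50 from the soma surface, daughters reach path lengths 90 and 80
  cell <- y_cell(trunk = 50, arm_a = 40, arm_b = 30, soma_r = 1)
  b <- dplyr::arrange(tmd_barcode(cell), birth)
  expect_equal(nrow(b), 2)
  expect_equal(b$birth, c(0, 50), tolerance = 1e-9)
  expect_equal(b$death, c(90, 80), tolerance = 1e-9)
})

test_that("a depth-3 binary tree yields one bar per terminal, bifurcations as births", {
  cell <- binary_tree_cell(depth = 3, branch_len = 20)
  b <- tmd_barcode(cell)
  expect_equal(nrow(b), 8) # 2^3 terminals
  # all terminals share the same path length, bifurcations at 20, 40, 60 (+1 stub)
  expect_equal(sum(b$birth == 0), 1)
  deaths <- sort(unique(round(b$death, 3)))
  expect_equal(length(deaths), 1) # symmetric tree: equal terminal path lengths
  births <- sort(b$birth)
  # one root bar, one bar born at each of the 7 bifurcations
  expect_equal(sum(births > 0), 7)
})

test_that("bar count equals terminal count on random generator trees", {
  for (seed in 1:10) {
    spec <- synthetic_cell_spec(
      n_projections = sample(2:5, 1), branching_depth = sample(0:2, 1),
      branch_length_median = 20, undulation_amplitude = 1
    )
    g <- generate_cell(spec, seed)
    b <- tmd_barcode(g$cell)
    branches <- decompose_branches(g$cell)
    expect_equal(nrow(b), sum(branches$terminal))
    expect_true(all(b$birth < b$death))
    expect_true(all(b$birth >= 0))
  }
})

test_that("barcodes are rigid-motion invariant and scale linearly", {
  g <- generate_cell(synthetic_cell_spec(branching_depth = 2,
    undulation_amplitude = 1), seed = 6)
  b0 <- dplyr::arrange(tmd_barcode(g$cell), birth, death)
  # rotate 90 degrees about z and translate
  rot <- g$cell
  xr <- -rot$y; yr <- rot$x
  rot$x <- xr + 10; rot$y <- yr - 4; rot$z <- rot$z + 3
  b1 <- dplyr::arrange(tmd_barcode(rot), birth, death)
  expect_equal(b1$birth, b0$birth, tolerance = 1e-9)
  expect_equal(b1$death, b0$death, tolerance = 1e-9)
  # uniform scaling scales births and deaths
  b2 <- dplyr::arrange(tmd_barcode(rescale_cell(g$cell, 2)), birth, death)
  expect_equal(b2$birth, 2 * b0$birth, tolerance = 1e-6)
  expect_equal(b2$death, 2 * b0$death, tolerance = 1e-6)
})

test_that("persistence images are unit-sum KDEs with mass at the bars", {
  bars <- tibble::tibble(birth = 30, death = 80, projection = 1L)
  img <- persistence_image(bars, grid_extent = c(0, 100), resolution = 50,
    bandwidth = 5)
  expect_equal(sum(img$z), 1, tolerance = 1e-12)
  peak <- which(img$z == max(img$z), arr.ind = TRUE)
  expect_equal(img$x[peak[1]], 30, tolerance = 2) # grid cell of the bar
  expect_equal(img$y[peak[2]], 80, tolerance = 2)
  # duplicating the bar multiset leaves the normalized image unchanged
  img2 <- persistence_image(dplyr::bind_rows(bars, bars),
    grid_extent = c(0, 100), resolution = 50, bandwidth = 5)
  expect_equal(img2$z, img$z, tolerance = 1e-12)
  expect_error(persistence_image(bars[0, ]), class = "morphdmri_error_empty")
})

test_that("topological distance satisfies the pseudo-metric axioms", {
  mk <- function(bars, bw = 4) {
    persistence_image(bars, grid_extent = c(0, 100), resolution = 40,
      bandwidth = bw)
  }
  a <- mk(tibble::tibble(birth = c(0, 10), death = c(60, 30)))
  expect_equal(topological_distance(a, a), 0)
  # disjoint support: far-apart tight kernels
  d1 <- mk(tibble::tibble(birth = 5, death = 10), bw = 0.5)
  d2 <- mk(tibble::tibble(birth = 80, death = 95), bw = 0.5)
  expect_equal(topological_distance(d1, d2), 2, tolerance = 1e-6)
  # symmetry and triangle inequality over random triples
  set.seed(9)
  for (i in 1:10) {
    imgs <- lapply(1:3, function(j) {
      mk(tibble::tibble(
        birth = stats::runif(4, 0, 50),
        death = stats::runif(4, 50, 100)
      ))
    })
    dab <- topological_distance(imgs[[1]], imgs[[2]])
    dba <- topological_distance(imgs[[2]], imgs[[1]])
    dac <- topological_distance(imgs[[1]], imgs[[3]])
    dcb <- topological_distance(imgs[[3]], imgs[[2]])
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-12)
    expect_lte(dab, 2)
  }
  # grid mismatch is an error
  other <- persistence_image(tibble::tibble(birth = 5, death = 10),
    grid_extent = c(0, 50), resolution = 40, bandwidth = 1)
  expect_error(topological_distance(a, other), class = "morphdmri_error_grid")
})

test_that("bootstrap distance separates distinct populations and not identical ones", {
  spec_long <- synthetic_cell_spec(n_projections = 3, branching_depth = 1,
    branch_length_median = 150, branch_length_sigma = 0.3)
  spec_short <- synthetic_cell_spec(n_projections = 3, branching_depth = 1,
    branch_length_median = 30, branch_length_sigma = 0.3)
  bars_long <- lapply(generate_population(spec_long, 12, seed = 51),
    function(g) tmd_barcode(g$cell))
  bars_short <- lapply(generate_population(spec_short, 12, seed = 52),
    function(g) tmd_barcode(g$cell))
  res <- bootstrap_distance(bars_long, bars_short, n_boot = 499, seed = 7)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$D, 0)
  # identical groups: observed D = 0, p = 1
  res0 <- bootstrap_distance(bars_long, bars_long, n_boot = 99, seed = 7)
  expect_equal(res0$D, 0)
  expect_equal(res0$p_value, 1)
  expect_error(bootstrap_distance(bars_long[1], bars_short, n_boot = 10),
    class = "morphdmri_error_degenerate")
})
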