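test_that("soma separation assigns nodes by the root-radius threshold", {
  txt <- c("1 1 0 0 0 5 -1", "2 3 3 0 0 1 1", "3 3 10 0 0 1 2")
  cell <- read_swc(txt)
  s <- separate_soma(cell)
  expect_equal(length(s$soma_rows), 2) # root + child at distance 3
  expect_equal(nrow(s$projections), 1)
  expect_equal(s$projections$child_row, 3L)
  # the split point lies on the soma sphere
  expect_equal(sqrt(sum(s$projections$entry[[1]]^2)), 5, tolerance = 1e-9)

  all_inside <- read_swc(c("1 1 0 0 0 5 -1", "2 3 3 0 0 1 1"))
  expect_error(separate_soma(all_inside),
    class = "morphdmri_error_no_projections")
})

test_that("branch decomposition counts branches as terminals plus bifurcations", {
  straight <- straight_cell(n_nodes = 10)
  expect_equal(nrow(decompose_branches(straight)), 1)

  y <- y_cell()
  by <- decompose_branches(y)
  expect_equal(nrow(by), 3)
  expect_equal(sort(by$order), c(1L, 2L, 2L))

  tree <- binary_tree_cell(depth = 3)
  bt <- decompose_branches(tree)
  n_terminals <- sum(bt$terminal)
  n_bifs <- sum(!bt$terminal)
  expect_equal(nrow(bt), n_terminals + n_bifs)
  expect_equal(n_terminals, 8) # 2^3 leaves
  expect_equal(max(bt$order), 4) # depth 3 -> max order 4
})

test_that("branch length matches straight and analytic arc-length cases", {
  straight <- path_matrix(seq(0, 45, by = 5), 0, 0, rep(1, 10))
  expect_equal(branch_length(straight), 45)
  semi <- semicircle_path(R = 20)
  expect_equal(branch_length(semi), pi * 20, tolerance = 1e-3)
})

test_that("tau is 1 for straight branches and 2/pi for a semicircle", {
  straight <- path_matrix(seq(0, 45, by = 5), 0, 0, rep(1, 10))
  expect_equal(branch_tortuosity(straight)$tau, 1)
  semi <- semicircle_path(R = 20)
  expect_equal(branch_tortuosity(semi)$tau, 2 / pi, tolerance = 1e-4)
  expect_equal(branch_tortuosity(semi)$tortuosity, pi / 2, tolerance = 1e-4)
})

test_that("beading CV matches hand arithmetic and the sinusoid closed form", {
  # endpoint radii (0.5, 0.5, 2.5) give sub-segment radii {0.5, 1.5}:
  # std/mean = 0.5/1.0
  expect_equal(branch_beading_cv(path_matrix(c(0, 1, 2), 0, 0, c(0.5, 0.5, 2.5))),
    0.5)
  p2 <- path_matrix(c(0, 1), 0, 0, c(0.5, 0.5))
  expect_equal(branch_beading_cv(p2), 0)
  # sinusoidal beading: CV ~= a / (r sqrt(2))
  s <- seq(0, 100, by = 0.1)
  r <- 1 + 0.3 * sin(2 * pi * s / 10)
  p3 <- path_matrix(s, 0, 0, r)
  expect_equal(branch_beading_cv(p3), 0.3 / (1 * sqrt(2)), tolerance = 0.01)
})

test_that("branch S/V follows the cylinder closed forms", {
  p <- path_matrix(seq(0, 50, by = 1), 0, 0, rep(0.5, 51))
  expect_equal(branch_sv(p), 2 / 0.5)
  p06 <- path_matrix(seq(0, 50, by = 1), 0, 0, rep(0.6, 51))
  expect_equal(branch_sv(p06), 2 / 0.6, tolerance = 1e-12)
  # two sub-segments r = 0.5 and r = 1, equal lengths
  p2 <- path_matrix(c(0, 1, 2), 0, 0, c(0.5, 0.5, 1.5))
  # sub-segment radii 0.5 and 1.0
  expect_equal(branch_sv(p2), (2 * pi * 0.5 + 2 * pi * 1) / (pi * 0.25 + pi * 1))
})

test_that("undulation is 0 for straight paths and alpha for a zigzag", {
  straight <- path_matrix(seq(0, 45, by = 5), 0, 0, rep(1, 10))
  expect_equal(branch_undulation(straight), 0)
  alpha <- 0.3
  n <- 20
  dx <- cos(alpha)
  dy <- sin(alpha) * rep(c(1, -1), n / 2)
  x <- cumsum(c(0, rep(dx, n)))
  y <- cumsum(c(0, dy, 0))[seq_len(n + 1)]
  zig <- path_matrix(x, y, 0, rep(0.5, n + 1))
  expect_equal(branch_undulation(zig), alpha, tolerance = 1e-6)
})

test_that("curvature radius recovers circles and helices, straight is missing", {
  circ <- semicircle_path(R = 10)
  expect_equal(branch_curvature_radius(circ), 10, tolerance = 1e-6)
  straight <- path_matrix(seq(0, 45, by = 5), 0, 0, rep(1, 10))
  expect_true(is.na(branch_curvature_radius(straight)))
  hel <- helix_path(a = 10, b = 2)
  expect_equal(branch_curvature_radius(hel), (10^2 + 2^2) / 10, tolerance = 0.02)
})

test_that("bifurcation angle is read from 5-um daughter chords", {
  d1 <- path_matrix(seq(0, 20, by = 1) / sqrt(2), seq(0, 20, by = 1) / sqrt(2),
    0, rep(0.5, 21))
  d2 <- path_matrix(seq(0, 20, by = 1) / sqrt(2), -seq(0, 20, by = 1) / sqrt(2),
    0, rep(0.5, 21))
  expect_equal(branch_angle(d1, d2), pi / 2, tolerance = 1e-9)
  d3 <- path_matrix(seq(0, 20, by = 1), 0, 0, rep(0.5, 21))
  d4 <- path_matrix(rep(0, 21), seq(0, 20, by = 1), 0, rep(0.5, 21))
  expect_equal(branch_angle(d3, d4), pi / 2, tolerance = 1e-9)
})

test_that("effective MR radius matches direct arithmetic and the power-mean bound", {
  expect_equal(mr_effective_radius(c(3, 10), p = 7, q = 3),
    ((3^7 + 10^7) / (3^3 + 10^3))^(1 / 4))
  expect_equal(mr_effective_radius(c(0.5, 1), p = 6, q = 2),
    ((0.5^6 + 1) / (0.5^2 + 1))^(1 / 4))
  expect_equal(mr_effective_radius(c(2, 2, 2), p = 6, q = 2), 2)
  expect_error(mr_effective_radius(numeric(0)), class = "morphdmri_error_empty")
  # R_MR >= arithmetic mean, equality iff all equal
  set.seed(1)
  for (i in 1:20) {
    r <- stats::runif(10, 0.2, 3)
    expect_gte(mr_effective_radius(r, 6, 2) + 1e-12, mean(r))
  }
})

test_that("eta_soma is the projection cross-section over the soma surface", {
  expect_equal(eta_soma(4 * pi * 25, 1), pi / (4 * pi * 25))
  expect_equal(eta_soma(4 * pi * 25, numeric(0)), 0)
  expect_lte(eta_soma(1, c(5, 5)), 1) # clipped
})

test_that("domain S/V reduces to closed-form assemblies", {
  # soma sphere R = 5 plus one straight cylinder r = 0.5, L = 100
  lines <- "1 1 0 0 0 5 -1"
  prev <- 1L; id <- 2L
  for (x in seq(5.5, 105, by = 0.5)) {
    lines <- c(lines, swc_line(id, x, 0, 0, 0.5, prev)); prev <- id; id <- id + 1L
  }
  cell <- read_swc(lines)
  m <- cell_morphometry(cell)
  s_cyl <- m$branches$surface[1]
  v_cyl <- m$branches$volume[1]
  eta <- eta_soma(4 * pi * 25, 0.5)
  expected <- (4 * pi * 25 * (1 - eta) + s_cyl) / (4 / 3 * pi * 125 + v_cyl)
  expect_equal(m$summary$SV_domain, expected, tolerance = 1e-9)
  # cylinder closed forms (up to the small entry stub)
  expect_equal(s_cyl, 2 * pi * 0.5 * 100, tolerance = 0.01)
  expect_equal(v_cyl, pi * 0.25 * 100, tolerance = 0.01)
})

test_that("uniform rescaling scales lengths by c, S/V by 1/c, leaves shape alone", {
  g <- generate_cell(synthetic_cell_spec(branching_depth = 1,
    undulation_amplitude = 1.5, beading_amplitude = 0.05), seed = 13)
  m1 <- glance(cell_morphometry(g$cell))
  c_ <- 2.5
  m2 <- glance(cell_morphometry(rescale_cell(g$cell, c_)))
  expect_equal(m2$R_domain, c_ * m1$R_domain, tolerance = 1e-6)
  expect_equal(m2$R_soma, c_ * m1$R_soma, tolerance = 1e-6)
  expect_equal(m2$L_branch, c_ * m1$L_branch, tolerance = 1e-6)
  expect_equal(m2$SV_domain, m1$SV_domain / c_, tolerance = 1e-6)
  expect_equal(m2$SV_branch, m1$SV_branch / c_, tolerance = 1e-6)
  expect_equal(m2$tau_branch, m1$tau_branch, tolerance = 1e-9)
  expect_equal(m2$CV_branch, m1$CV_branch, tolerance = 1e-9)
  expect_equal(m2$muOD_branch, m1$muOD_branch, tolerance = 1e-9)
  expect_equal(m2$BO, m1$BO)
  expect_equal(m2$N_proj, m1$N_proj)
  # curvature radius scales with c at the branch level
  semi <- semicircle_path(R = 10)
  semi_scaled <- semi
  semi_scaled[, 1:3] <- semi_scaled[, 1:3] * c_
  expect_equal(branch_curvature_radius(semi_scaled),
    c_ * branch_curvature_radius(semi), tolerance = 1e-9)
  # theta is invariant when daughters are straight over the 5-um chord
  g0 <- generate_cell(synthetic_cell_spec(branching_depth = 1), seed = 13)
  t1 <- glance(cell_morphometry(g0$cell))$theta_branch
  t2 <- glance(cell_morphometry(rescale_cell(g0$cell, c_)))$theta_branch
  expect_equal(t2, t1, tolerance = 1e-6)
})

test_that("branch paths cover every projection node exactly once", {
  g <- generate_cell(synthetic_cell_spec(branching_depth = 2), seed = 17)
  s <- separate_soma(g$cell)
  b <- decompose_branches(g$cell, s)
  # each path carries one start point (soma entry or its parent's bifurcation
  # node) plus its own projection nodes, so total path rows exceed the
  # projection node count by exactly the branch count
  n_proj_nodes <- nrow(g$cell) - length(s$soma_rows)
  expect_equal(sum(vapply(b$path, nrow, integer(1))), n_proj_nodes + nrow(b))
})

test_that("structural descriptors recover generator ground truth", {
  # gentle undulation so 5-um daughter chords track the true initial directions
  spec <- synthetic_cell_spec(
    branching_depth = 2, undulation_amplitude = 0.3,
    undulation_wavelength = 40,
    beading_amplitude = 0.06, bifurcation_angle = pi / 4
  )
  g <- generate_cell(spec, seed = 101)
  m <- cell_morphometry(g$cell)
  gl <- m$summary
  tr <- g$truth
  expect_equal(gl$N_proj, tr$n_projections)
  expect_equal(gl$BO, tr$max_branch_order)
  expect_equal(gl$R_domain, tr$R_domain, tolerance = 0.01)
  expect_equal(gl$R_soma, tr$soma_radius, tolerance = 0.02)
  expect_equal(gl$L_branch, mean(tr$branches$L_branch), tolerance = 0.01)
  expect_equal(gl$R_branch, mean(tr$branches$R_branch), tolerance = 0.02)
  expect_equal(gl$tau_branch, mean(tr$branches$tau_branch), tolerance = 0.01)
  expect_equal(gl$SV_branch, mean(tr$branches$SV_branch), tolerance = 0.02)
  expect_equal(gl$theta_branch, spec$bifurcation_angle, tolerance = 0.05)
})
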