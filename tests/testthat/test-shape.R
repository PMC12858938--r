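test_that("segmentation yields the expected chunk counts and conserves volume", {
  # single straight 50 um branch -> 5 identical-orientation segments
  cell50 <- straight_cell(n_nodes = 50, spacing = 1, soma_r = 2, r = 0.5)
  segs <- segment_cell(cell50)
  expect_equal(nrow(segs), 5)
  U <- as.matrix(segs[, c("ux", "uy", "uz")])
  expect_true(all(abs(U %*% c(1, 0, 0)) > 0.9999))

  cell10 <- straight_cell(n_nodes = 10, spacing = 1, soma_r = 2, r = 0.5)
  expect_equal(nrow(segment_cell(cell10)), 1)

  g <- generate_cell(synthetic_cell_spec(branching_depth = 2,
    undulation_amplitude = 1.5), seed = 8)
  segs_g <- segment_cell(g$cell)
  m <- cell_morphometry(g$cell)
  expect_equal(sum(segs_g$weight), sum(m$branches$volume), tolerance = 0.02)
})

test_that("scatter eigenvalues match parallel, planar and isotropic archetypes", {
  # parallel
  U <- matrix(rep(c(0, 0, 1), 50), ncol = 3, byrow = TRUE)
  sc <- scatter_eigenvalues(U, rep(1, 50))
  expect_equal(sc$tau, c(0, 0, 1), tolerance = 1e-12)
  # uniform in the XY plane
  th <- seq(0, pi, length.out = 721)[-721]
  Up <- cbind(cos(th), sin(th), 0)
  scp <- scatter_eigenvalues(Up, rep(1, nrow(Up)))
  expect_equal(scp$tau, c(0, 0.5, 0.5), tolerance = 1e-3)
  # isotropic
  set.seed(5)
  Ui <- morphdmri:::runif_sphere(20000)
  sci <- scatter_eigenvalues(Ui, rep(1, 20000))
  expect_equal(sci$tau, rep(1 / 3, 3), tolerance = 0.02)
})

test_that("FA reproduces the closed forms and printed eigenvalue triples", {
  expect_equal(fractional_anisotropy(c(1, 1, 1) / 3), 0)
  expect_equal(fractional_anisotropy(c(0, 0, 1)), 1)
  expect_equal(round(fractional_anisotropy(c(0.04, 0.15, 0.81)), 2), 0.87)
  expect_equal(round(fractional_anisotropy(c(0.14, 0.27, 0.59)), 2), 0.60)
  # scale invariance
  set.seed(2)
  for (i in 1:20) {
    tau <- sort(stats::runif(3))
    c_ <- stats::runif(1, 0.1, 10)
    expect_equal(fractional_anisotropy(c_ * tau), fractional_anisotropy(tau),
      tolerance = 1e-12)
  }
})

test_that("adjusted FA assumes tau1 = tau2 and never exceeds FA", {
  expect_equal(adjusted_fa(c(0, 0, 1)), 1)
  expect_equal(adjusted_fa(c(1, 1, 1) / 3), 0)
  set.seed(3)
  for (i in 1:50) {
    tau <- sort(stats::runif(3, 0.01, 1))
    expect_lte(adjusted_fa(tau), fractional_anisotropy(tau) + 1e-12)
  }
})

test_that("Watson MLE recovers concentration within the expected bands", {
  set.seed(11)
  U4 <- rwatson_axis(1000, 4)
  k4 <- fit_watson_kappa(U4)$kappa
  expect_gte(k4, 3.2)
  expect_lte(k4, 4.8)

  # isotropy: kappa-hat is a half-normal shrinking as 1/sqrt(n); the median
  # over independent samples at n = 1000 sits well below 0.2
  k_iso <- vapply(1:5, function(s) {
    set.seed(s)
    fit_watson_kappa(morphdmri:::runif_sphere(1000))$kappa
  }, numeric(1))
  expect_lte(stats::median(k_iso), 0.2)

  # perfectly parallel with tiny jitter -> reported at the cap
  Up <- rbind(
    matrix(rep(c(0, 0, 1), 30), ncol = 3, byrow = TRUE),
    c(1e-4, 0, 1), c(0, 1e-4, 1)
  )
  Up <- Up / sqrt(rowSums(Up^2))
  expect_equal(fit_watson_kappa(Up)$kappa, 1e4)

  expect_error(fit_watson_kappa(matrix(rep(c(0, 0, 1), 5), ncol = 3, byrow = TRUE)),
    class = "morphdmri_error_degenerate")
})

test_that("Watson recovery holds across kappa 1, 4, 8 at 500 axes", {
  for (k_true in c(1, 4, 8)) {
    set.seed(100 + k_true)
    U <- rwatson_axis(500, k_true)
    k_hat <- fit_watson_kappa(U)$kappa
    expect_lt(abs(k_hat - k_true) / k_true, 0.2)
  }
})

test_that("Bingham concentrations separate axial, planar and isotropic samples", {
  set.seed(21)
  # axially symmetric: kappa1 ~ kappa2
  Ua <- rwatson_axis(1000, 4)
  bfa <- fit_bingham(Ua)
  expect_lt(bfa$kappa1 / max(bfa$kappa2, 1e-8), 1.5)
  # planar (strong Z compression of an isotropic cloud)
  Up <- morphdmri:::runif_sphere(1000)
  Up[, 3] <- Up[, 3] * 0.1
  Up <- Up / sqrt(rowSums(Up^2))
  bfp <- fit_bingham(Up)
  expect_gt(bfp$kappa1 / max(bfp$kappa2, 1e-8), 10)
  # isotropic: both near zero
  Ui <- morphdmri:::runif_sphere(1000)
  bfi <- fit_bingham(Ui)
  expect_lte(bfi$kappa1, 0.5)
})

test_that("kappa selection follows the planarity rule", {
  expect_equal(select_kappa(100, 2), 2)
  expect_equal(select_kappa(4, 3), 3.5)
  expect_equal(select_kappa(0, 0), 0)
})

test_that("orientation dispersion maps kappa through 2/pi atan(1/kappa)", {
  expect_equal(od_from_kappa(1), 0.5)
  expect_equal(od_from_kappa(1e12), 0, tolerance = 1e-11)
  expect_equal(od_from_kappa(0), 1)
  ks <- c(0.1, 0.5, 1, 2, 5, 20)
  expect_true(all(diff(vapply(ks, od_from_kappa, numeric(1))) < 0))
})

test_that("Z compression inflates FA and triggers the planar kappa rule", {
  # enough projections that the uncompressed cell is near axial symmetry
  # (tau1 ~ tau2), the regime the adjusted FA is built for
  spec <- synthetic_cell_spec(n_projections = 12, branching_depth = 1,
    undulation_amplitude = 1)
  g <- generate_cell(spec, seed = 31)
  sh0 <- cell_shape(g$cell)
  shc <- cell_shape(z_compress(g$cell, 0.3))
  expect_gt(shc$FA, sh0$FA)
  expect_lt(shc$tau[1], sh0$tau[1])
  # adjusted FA compensates: closer to the uncompressed FA than raw FA is
  expect_lt(abs(shc$adjFA - sh0$FA), abs(shc$FA - sh0$FA))
  # compressed population is planar: kappa1 >> kappa2, so kappa2 is selected
  bf <- fit_bingham(segment_cell(z_compress(g$cell, 0.3)))
  expect_gt(bf$kappa1 / max(bf$kappa2, 1e-8), 10)
  expect_equal(select_kappa(bf$kappa1, bf$kappa2), bf$kappa2)
})

test_that("cell-level Watson kappa recovers the generator's concentration", {
  # many single-branch projections, straight: segment axes ~ Watson(kappa)
  spec <- synthetic_cell_spec(
    n_projections = 40, branching_depth = 0, branch_length_median = 30,
    branch_length_sigma = 0.2, kappa = 4
  )
  g <- generate_cell(spec, seed = 41)
  segs <- segment_cell(g$cell)
  expect_gte(nrow(segs), 100)
  wf <- fit_watson_kappa(segs)
  expect_lt(abs(wf$kappa - 4) / 4, 0.35) # 40 projections, correlated segments
})
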