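test_that("a small SWC file parses into the expected tree", {
  txt <- c(
    "# comment line",
    "1 1 0 0 0 5 -1",
    "2 3 6 0 0 1 1",
    "3 3 12 0 0 1 2"
  )
  cell <- read_swc(txt)
  expect_s3_class(cell, "swc_cell")
  expect_equal(nrow(cell), 3)
  expect_equal(root_id(cell), 1L)
  expect_equal(cell$radius[1], 5)
  expect_true(is.na(cell$parent[1]))
})

test_that("tab separators, blank lines and extra columns are tolerated", {
  txt <- c("", "1\t1\t0\t0\t0\t5\t-1", "2 3 6 0 0 1 1 99")
  expect_warning(cell <- read_swc(txt), "more than 7")
  expect_equal(nrow(cell), 2)
})

test_that("malformed SWC input raises distinct named errors", {
  expect_error(read_swc(c("1 1 0 0 0 5 -1", "1 3 5 0 0 1 1")),
    class = "morphdmri_error_duplicate_id")
  expect_error(read_swc(c("1 1 0 0 0 5 -1", "2 3 5 0 0 1 9")),
    class = "morphdmri_error_dangling_parent")
  expect_error(read_swc("1 1 0 0 0 5"),
    class = "morphdmri_error_columns")
  expect_error(read_swc(c("1 1 0 0 0 5 -1", "2 3 x 0 0 1 1")),
    class = "morphdmri_error_nonnumeric")
  # mutual parents leave no root
  expect_error(read_swc(c("1 1 0 0 0 5 2", "2 3 5 0 0 1 1")),
    class = "morphdmri_error_root")
  # a cycle detached from the root
  expect_error(read_swc(c("1 1 0 0 0 5 -1", "2 3 5 0 0 1 3", "3 3 9 0 0 1 2")),
    class = "morphdmri_error_cycle")
})

test_that("write_swc renumbers ids parent-before-child from 1", {
  txt <- c("10 1 0 0 0 5 -1", "30 3 12 0 0 1 20", "20 3 6 0 0 1 10")
  out <- write_swc(read_swc(txt))
  ids <- as.integer(vapply(strsplit(out, " "), `[`, character(1), 1))
  parents <- as.integer(vapply(strsplit(out, " "), `[`, character(1), 7))
  expect_equal(ids, 1:3)
  expect_equal(parents[1], -1L)
  expect_true(all(parents[-1] < ids[-1]))
})

test_that("read/write round trip preserves geometry", {
  g <- generate_cell(synthetic_cell_spec(branching_depth = 1,
    undulation_amplitude = 1, beading_amplitude = 0.05), seed = 3)
  cell <- g$cell
  rt <- read_swc(write_swc(cell))
  ord <- morphdmri:::topo_order(cell)
  expect_equal(rt$x, cell$x[ord], tolerance = 1e-7)
  expect_equal(rt$y, cell$y[ord], tolerance = 1e-7)
  expect_equal(rt$z, cell$z[ord], tolerance = 1e-7)
  expect_equal(rt$radius, cell$radius[ord], tolerance = 1e-7)
  expect_equal(rt$type, cell$type[ord])
  # and a second round trip is byte-identical
  expect_identical(write_swc(rt), write_swc(read_swc(write_swc(rt))))
})

test_that("strip_axon removes type-2 subtrees and conserves node counts", {
  g <- generate_cell(synthetic_cell_spec(branching_depth = 1, axon = TRUE),
    seed = 11)
  n0 <- nrow(g$cell)
  res <- strip_axon(g$cell)
  expect_gt(res$n_nodes_removed, 0)
  expect_equal(nrow(res$cell), n0 - res$n_nodes_removed)
  expect_false(any(res$cell$type == 2))
  # no axon: unchanged
  g2 <- generate_cell(synthetic_cell_spec(branching_depth = 1), seed = 11)
  res2 <- strip_axon(g2$cell)
  expect_equal(res2$n_nodes_removed, 0L)
  expect_identical(write_swc(res2$cell), write_swc(g2$cell))
})

test_that("post-strip features match the axon-free generator spec", {
  spec_axon <- synthetic_cell_spec(branching_depth = 1, axon = TRUE)
  spec_plain <- synthetic_cell_spec(branching_depth = 1, axon = FALSE)
  ga <- generate_cell(spec_axon, seed = 5)
  gp <- generate_cell(spec_plain, seed = 5)
  stripped <- strip_axon(ga$cell)$cell
  # same RNG stream order for the dendritic projections: identical geometry
  expect_identical(write_swc(stripped), write_swc(gp$cell))
})

test_that("strip_spines removes generated spines and leaves dendrites intact", {
  g <- generate_cell(synthetic_cell_spec(branching_depth = 1,
    spine_density = 0.05), seed = 9)
  expect_gt(g$truth$n_spines, 0)
  res <- strip_spines(g$cell)
  expect_equal(res$n_spines_removed, g$truth$n_spines)
  # spineless cell untouched
  g0 <- generate_cell(synthetic_cell_spec(branching_depth = 1), seed = 9)
  expect_equal(strip_spines(g0$cell)$n_spines_removed, 0L)
  # a long terminal dendritic branch is not eaten by the defaults
  cell <- straight_cell(n_nodes = 10, spacing = 3, r = 0.25)
  expect_equal(strip_spines(cell)$n_spines_removed, 0L)
})

test_that("strip_axon then strip_spines is idempotent", {
  g <- generate_cell(synthetic_cell_spec(branching_depth = 1,
    spine_density = 0.03, axon = TRUE), seed = 21)
  once <- strip_spines(strip_axon(g$cell)$cell)$cell
  twice <- strip_spines(strip_axon(once)$cell)$cell
  expect_identical(write_swc(once), write_swc(twice))
})

test_that("validation flags constant radii and flat reconstructions", {
  flat <- read_swc(c("1 1 0 0 0 5 -1", "2 3 6 0 0 0.5 1", "3 3 12 3 0 0.5 2"))
  rep_flat <- validate_cell(flat)
  expect_false(rep_flat$passed)
  expect_true("not_3d" %in% rep_flat$issues$code)
  expect_true(rep_flat$constant_radius_flag)

  g <- generate_cell(synthetic_cell_spec(branching_depth = 1,
    undulation_amplitude = 1, beading_amplitude = 0.05), seed = 2)
  rep_ok <- validate_cell(g$cell)
  expect_true(rep_ok$passed)
  expect_false(rep_ok$constant_radius_flag)
  # report serializes
  expect_true(jsonlite::validate(validation_report_json(rep_flat)))
})
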