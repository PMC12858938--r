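#' Specification for a synthetic cell
#'
#' Defines the ground-truth morphology of a generated cell: a spherical soma
#' with `n_projections` primary projections; binary trees of
#' `branching_depth` bifurcation levels; branch lengths drawn lognormally;
#' radii with optional linear taper and sinusoidal beading; planar sinusoidal
#' undulation rotated randomly about the chord; projection orientations drawn
#' from a Watson distribution of concentration `kappa` about `axis`
#' (isotropic when `kappa = 0`); optional Z-axis compression (the
#' depth-of-field artifact of optical reconstructions) and explicit dendritic
#' spines at a linear density.
#'
#' @param soma_radius Soma radius in um (default 5).
#' @param n_projections Number of primary projections (default 7).
#' @param branching_depth Number of bifurcation levels (0 = unbranched;
#'   maximum branch order is `branching_depth + 1`). Default 2.
#' @param branch_length_median Median branch length in um (default 54).
#' @param branch_length_sigma Lognormal sigma of branch lengths (default 0.4).
#' @param base_radius Branch radius at the soma in um (default 0.6).
#' @param taper_rate Fractional radius loss over one branch (default 0).
#' @param beading_amplitude,beading_wavelength Sinusoidal radius modulation
#'   in um (defaults 0 and 10).
#' @param undulation_amplitude,undulation_wavelength Planar sinusoidal
#'   centreline displacement in um (defaults 0 and 20).
#' @param kappa Watson concentration of projection orientations (0 =
#'   isotropic; default 0).
#' @param axis Mean orientation axis (default Z).
#' @param bifurcation_angle Angle between daughter branches in radians
#'   (default pi/4).
#' @param node_spacing Node spacing along branches in um (default 1).
#' @param z_compression Z-scale factor in (0, 1]; 1 = no artifact.
#' @param spine_density Spines per um of branch length (default 0).
#' @param spine_head_radius,spine_neck_radius,spine_neck_length Spine
#'   geometry in um (defaults 0.30, 0.10, 0.8).
#' @param axon Add one axonal (type 2) projection? Default `FALSE`.
#' @return A `synthetic_cell_spec` list.
#' @export
synthetic_cell_spec <- function(soma_radius = 5, n_projections = 7,
                                branching_depth = 2,
                                branch_length_median = 54,
                                branch_length_sigma = 0.4,
                                base_radius = 0.6, taper_rate = 0,
                                beading_amplitude = 0, beading_wavelength = 10,
                                undulation_amplitude = 0,
                                undulation_wavelength = 20,
                                kappa = 0, axis = c(0, 0, 1),
                                bifurcation_angle = pi / 4,
                                node_spacing = 1,
                                z_compression = 1,
                                spine_density = 0,
                                spine_head_radius = 0.30,
                                spine_neck_radius = 0.10,
                                spine_neck_length = 0.8,
                                axon = FALSE) {
  stopifnot(
    soma_radius > 0, n_projections >= 1, branching_depth >= 0,
    branch_length_median > 0, branch_length_sigma >= 0, base_radius > 0,
    taper_rate >= 0, taper_rate < 1, beading_amplitude >= 0,
    undulation_amplitude >= 0, kappa >= 0, node_spacing > 0,
    z_compression > 0, z_compression <= 1, spine_density >= 0
  )
  if (branch_length_median < node_spacing) {
    rlang::abort("branch length below node spacing: infeasible spec",
      class = "morphdmri_error_spec")
  }
  spec <- as.list(environment())
  spec$axis <- axis / sqrt(sum(axis^2))
  structure(spec, class = "synthetic_cell_spec")
}

#' Generate a synthetic cell with known ground truth
#'
#' Deterministic given `(spec, seed)`. The RNG stream is consumed in a fixed
#' order (per projection: orientation; then per branch, depth-first: length,
#' undulation azimuth, beading phase, daughter azimuth; spines last), so the
#' same seed reproduces the same cell byte-for-byte through [write_swc()].
#'
#' @param spec A [synthetic_cell_spec()].
#' @param seed Integer seed.
#' @return A list with `cell` (a `swc_cell`) and `truth` (a `ground_truth`
#'   list: spec, per-branch realized values, and closed-form cell values).
#' @export
generate_cell <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_cell_spec"))
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed))

  env <- new.env()
  env$rows <- list()
  env$truth_branches <- list()
  env$next_id <- 1L
  add_node <- function(type, p, radius, parent) {
    id <- env$next_id
    env$next_id <- id + 1L
    env$rows[[id]] <- tibble::tibble(
      id = id, type = as.integer(type),
      x = p[1], y = p[2], z = p[3], radius = radius,
      parent = as.integer(parent)
    )
    id
  }
  root <- add_node(1L, c(0, 0, 0), spec$soma_radius, NA_integer_)

  n_proj_total <- spec$n_projections + as.integer(spec$axon)
  for (p in seq_len(n_proj_total)) {
    is_axon <- spec$axon && p > spec$n_projections
    dir0 <- if (spec$kappa > 0) {
      rwatson_axis(1, spec$kappa, spec$axis)[1, ]
    } else {
      runif_sphere(1)[1, ]
    }
    start <- dir0 * (spec$soma_radius + 0.05)
    start_id <- add_node(if (is_axon) 2L else 3L, start, spec$base_radius, root)
    grow_branch(env, spec, start, dir0, start_id, depth = 0L,
      type = if (is_axon) 2L else 3L, projection = p)
  }

  nodes <- dplyr::bind_rows(env$rows)
  if (spec$z_compression < 1) nodes$z <- nodes$z * spec$z_compression

  # spines as explicit side branches on dendritic mid-branch nodes
  n_spines <- 0L
  if (spec$spine_density > 0) {
    nodes_env <- new.env()
    nodes_env$nodes <- nodes
    n_spines <- add_spines(nodes_env, spec)
    nodes <- nodes_env$nodes
  }

  cell <- swc_cell(nodes, metadata = list(seed = seed, synthetic = TRUE))
  tb <- dplyr::bind_rows(env$truth_branches)
  truth <- structure(
    list(
      spec = spec, seed = seed,
      n_projections = spec$n_projections,
      soma_radius = spec$soma_radius,
      soma_volume = 4 / 3 * pi * spec$soma_radius^3,
      soma_surface = 4 * pi * spec$soma_radius^2,
      max_branch_order = spec$branching_depth + 1L,
      n_spines = n_spines,
      branches = tb,
      R_domain = max(dist_from_point(nodes, c(0, 0, 0)))
    ),
    class = "ground_truth"
  )
  list(cell = cell, truth = truth)
}

# depth-first growth of one branch and its daughters; records realized truth
grow_branch <- function(env, spec, start, dir, start_id, depth, type, projection) {
  L <- stats::rlnorm(1, meanlog = log(spec$branch_length_median),
    sdlog = spec$branch_length_sigma)
  L <- max(L, 2 * spec$node_spacing)
  und_az <- stats::runif(1, 0, 2 * pi)
  bead_phase <- stats::runif(1, 0, 2 * pi)
  frame <- orthonormal_frame(dir)
  n_perp <- cos(und_az) * frame$e1 + sin(und_az) * frame$e2
  n_nodes <- max(2L, ceiling(L / spec$node_spacing))
  s <- seq(0, L, length.out = n_nodes + 1)[-1] # start point already placed
  radius_at <- function(sv) {
    r <- spec$base_radius * (1 - spec$taper_rate * sv / L) +
      spec$beading_amplitude * sin(2 * pi * sv / spec$beading_wavelength + bead_phase)
    pmax(r, 0.05)
  }
  offset <- if (spec$undulation_amplitude > 0) {
    spec$undulation_amplitude * sin(2 * pi * s / spec$undulation_wavelength)
  } else {
    rep(0, length(s))
  }
  pts <- t(vapply(seq_along(s), function(i) {
    start + s[i] * dir + offset[i] * n_perp
  }, numeric(3)))
  prev <- start_id
  prev_p <- start
  arc <- 0
  sum_S <- 0; sum_V <- 0; r_sum <- 0
  for (i in seq_len(nrow(pts))) {
    r_i <- radius_at(s[i])
    id <- add_node_env(env, type, pts[i, ], r_i, prev)
    dseg <- sqrt(sum((pts[i, ] - prev_p)^2))
    arc <- arc + dseg
    rbar <- if (i == 1) r_i else (r_i + radius_at(s[i - 1])) / 2
    sum_S <- sum_S + 2 * pi * rbar * dseg
    sum_V <- sum_V + pi * rbar^2 * dseg
    r_sum <- r_sum + rbar
    prev <- id
    prev_p <- pts[i, ]
  }
  chord <- sqrt(sum((prev_p - start)^2))
  env$truth_branches[[length(env$truth_branches) + 1]] <- tibble::tibble(
    projection = projection, order = depth + 1L,
    L_branch = arc, tau_branch = chord / arc,
    R_branch = r_sum / nrow(pts),
    SV_branch = sum_S / sum_V,
    theta = if (depth < spec$branching_depth) spec$bifurcation_angle else NA_real_
  )
  if (depth < spec$branching_depth) {
    end_dir <- (prev_p - start) / chord # chord direction carries forward
    daughter_az <- stats::runif(1, 0, 2 * pi)
    f <- orthonormal_frame(end_dir)
    w <- cos(daughter_az) * f$e1 + sin(daughter_az) * f$e2
    half <- spec$bifurcation_angle / 2
    d1 <- cos(half) * end_dir + sin(half) * w
    d2 <- cos(half) * end_dir - sin(half) * w
    for (d in list(d1, d2)) {
      kid_start <- prev_p + d * 0.05 # just off the bifurcation node
      kid_id <- add_node_env(env, type, kid_start, radius_at(L), prev)
      grow_branch(env, spec, kid_start, d, kid_id, depth + 1L, type, projection)
    }
  }
}

add_node_env <- function(env, type, p, radius, parent) {
  id <- env$next_id
  env$next_id <- id + 1L
  env$rows[[id]] <- tibble::tibble(
    id = id, type = as.integer(type),
    x = p[1], y = p[2], z = p[3], radius = radius,
    parent = as.integer(parent)
  )
  id
}

# explicit spine side-branches (neck node + head node) on interior dendrite
# nodes; returns the number of spines added
add_spines <- function(env, spec) {
  nodes <- env$nodes
  ch_counts <- table(factor(nodes$parent, levels = nodes$id))
  interior <- which(nodes$type == 3L & as.vector(ch_counts[as.character(nodes$id)]) == 1 &
    !is.na(nodes$parent))
  if (length(interior) == 0) return(0L)
  total_len <- sum(vapply(interior, function(i) {
    pr <- which(nodes$id == nodes$parent[i])
    sqrt(sum((c(nodes$x[i], nodes$y[i], nodes$z[i]) -
      c(nodes$x[pr], nodes$y[pr], nodes$z[pr]))^2))
  }, numeric(1)))
  n_spines <- round(spec$spine_density * total_len)
  if (n_spines == 0) return(0L)
  host_rows <- sample(interior, min(n_spines, length(interior)), replace = FALSE)
  next_id <- max(nodes$id) + 1L
  new_rows <- list()
  for (h in host_rows) {
    p0 <- c(nodes$x[h], nodes$y[h], nodes$z[h])
    pr <- which(nodes$id == nodes$parent[h])
    axis <- p0 - c(nodes$x[pr], nodes$y[pr], nodes$z[pr])
    na <- sqrt(sum(axis^2))
    axis <- if (na > 1e-9) axis / na else c(0, 0, 1)
    f <- orthonormal_frame(axis)
    az <- stats::runif(1, 0, 2 * pi)
    d <- cos(az) * f$e1 + sin(az) * f$e2
    neck_p <- p0 + d * (nodes$radius[h] + spec$spine_neck_length)
    head_p <- neck_p + d * spec$spine_head_radius
    new_rows[[length(new_rows) + 1]] <- tibble::tibble(
      id = c(next_id, next_id + 1L), type = 3L,
      x = c(neck_p[1], head_p[1]), y = c(neck_p[2], head_p[2]),
      z = c(neck_p[3], head_p[3]),
      radius = c(spec$spine_neck_radius, spec$spine_head_radius),
      parent = c(nodes$id[h], next_id)
    )
    next_id <- next_id + 2L
  }
  env$nodes <- dplyr::bind_rows(nodes, dplyr::bind_rows(new_rows))
  length(host_rows)
}

# right-handed orthonormal frame completing a unit vector
orthonormal_frame <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- crossprod3(u, a)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- crossprod3(u, e1)
  list(e1 = e1, e2 = e2)
}

# uniform axes on the sphere
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  m <- cbind(s * cos(phi), s * sin(phi), z)
  dimnames(m) <- NULL
  m
}

#' Sample axes from a Watson distribution
#'
#' Rejection sampling of the axial Watson density proportional to
#' `exp(kappa (u . mu)^2)` (bipolar, kappa > 0).
#'
#' @param n Number of axes.
#' @param kappa Concentration (> 0).
#' @param mu Mean axis (unit vector).
#' @return n x 3 matrix of unit axes.
#' @export
rwatson_axis <- function(n, kappa, mu = c(0, 0, 1)) {
  stopifnot(kappa > 0)
  mu <- mu / sqrt(sum(mu^2))
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    m <- (n - got) * 4L
    t <- stats::runif(m, -1, 1)
    acc <- stats::runif(m) < exp(kappa * (t^2 - 1))
    t <- t[acc]
    if (length(t) == 0) next
    take <- min(length(t), n - got)
    t <- t[seq_len(take)]
    phi <- stats::runif(take, 0, 2 * pi)
    s <- sqrt(1 - t^2)
    local_axes <- cbind(s * cos(phi), s * sin(phi), t)
    out[got + seq_len(take), ] <- local_axes
    got <- got + take
  }
  # rotate z to mu
  f <- orthonormal_frame(mu)
  R <- cbind(f$e1, f$e2, mu)
  out %*% t(R)
}

#' Generate a population of synthetic cells
#'
#' Per-cell seeds are derived reproducibly from the master seed; two master
#' seeds give disjoint streams.
#'
#' @param spec A [synthetic_cell_spec()].
#' @param n Number of cells.
#' @param seed Master seed.
#' @return List of `list(cell, truth)` pairs.
#' @export
generate_population <- function(spec, n, seed = 1) {
  if (n == 0) return(list())
  old_seed <- set_local_seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n)
  restore_seed(old_seed)
  lapply(cell_seeds, function(s) generate_cell(spec, s))
}

#' Compress a cell along the Z axis
#'
#' Emulates the depth-of-field artifact of optical reconstructions: all
#' z-coordinates are scaled by `factor`; radii are untouched.
#'
#' @param cell A `swc_cell`.
#' @param factor Scale in (0, 1].
#' @return The compressed cell.
#' @export
z_compress <- function(cell, factor) {
  stopifnot(factor > 0, factor <= 1)
  out <- cell
  out$z <- out$z * factor
  out
}

#' Uniformly rescale a cell
#'
#' Scales all coordinates and radii by `factor` about the root. Lengths and
#' radii scale by `factor`, surface-to-volume ratios by `1/factor`;
#' dimensionless descriptors (tau, CV, undulation, FA, OD, branch order) are
#' invariant.
#'
#' @param cell A `swc_cell`.
#' @param factor Positive scale.
#' @return The rescaled cell.
#' @export
rescale_cell <- function(cell, factor) {
  stopifnot(factor > 0)
  rr <- which(is.na(cell$parent))[1]
  p0 <- c(cell$x[rr], cell$y[rr], cell$z[rr])
  out <- cell
  out$x <- p0[1] + (out$x - p0[1]) * factor
  out$y <- p0[2] + (out$y - p0[2]) * factor
  out$z <- p0[3] + (out$z - p0[3]) * factor
  out$radius <- out$radius * factor
  out
}
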