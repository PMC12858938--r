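#' Separate the soma from the projections
#'
#' All nodes within the nominal soma radius (the radius of the root node) of
#' the root, and connected to the root through such nodes, are assigned to the
#' soma; the rest form the projection forest. Edges crossing the soma sphere
#' are split at the sphere so each primary projection starts exactly on the
#' soma surface.
#'
#' @param cell A `swc_cell` (stripped of axons/spines).
#' @return A list with `soma_rows` (row indices of soma nodes),
#'   `threshold` (soma radius in um), `root_point` (xyz of root), and
#'   `projections`: a tibble with one row per primary projection: `entry`
#'   (xyz on the sphere), `entry_radius` (interpolated radius at the
#'   crossing), `child_row` (first node outside the soma).
#' @export
separate_soma <- function(cell) {
  rr <- which(is.na(cell$parent))[1]
  p0 <- c(cell$x[rr], cell$y[rr], cell$z[rr])
  r0 <- cell$radius[rr]
  d <- dist_from_point(cell, p0)
  ch <- children_index(cell)
  # soma = connected component of the root within the threshold
  soma <- logical(nrow(cell))
  stack <- rr
  while (length(stack) > 0) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    soma[cur] <- TRUE
    kids <- ch[[cur]]
    inside <- kids[d[kids] <= r0]
    stack <- c(stack, inside[!soma[inside]])
  }
  crossings <- list()
  for (row in which(soma)) {
    for (kid in ch[[row]]) {
      if (soma[kid]) next
      a <- c(cell$x[row], cell$y[row], cell$z[row])
      b <- c(cell$x[kid], cell$y[kid], cell$z[kid])
      # intersection of segment a->b with the sphere |p - p0| = r0
      u <- b - a
      f <- a - p0
      A <- sum(u^2)
      B <- 2 * sum(f * u)
      C <- sum(f^2) - r0^2
      disc <- B^2 - 4 * A * C
      t <- if (disc >= 0 && A > 0) {
        ts <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
        ts <- ts[ts >= 0 & ts <= 1]
        if (length(ts) > 0) max(ts) else 0
      } else 0
      entry <- a + t * u
      # the root's radius is the nominal soma radius, not a neurite caliber:
      # do not blend it into the projection's starting radius
      r_parent <- if (row == rr) cell$radius[kid] else cell$radius[row]
      entry_radius <- r_parent + t * (cell$radius[kid] - r_parent)
      crossings[[length(crossings) + 1]] <- tibble::tibble(
        entry = list(entry), entry_radius = entry_radius, child_row = kid
      )
    }
  }
  if (length(crossings) == 0) {
    rlang::abort("no nodes outside the soma threshold: cell has no projections",
      class = "morphdmri_error_no_projections"
    )
  }
  list(
    soma_rows = which(soma),
    threshold = r0,
    root_point = p0,
    projections = dplyr::bind_rows(crossings)
  )
}

#' Decompose the projection forest into branches
#'
#' A branch is the maximal unbranched path delimited by branching or
#' termination nodes. Primary branches start on the soma sphere (order 1);
#' each bifurcation increments the order of its daughters. A node with k > 2
#' children is handled as k-1 stacked virtual bifurcations (with a warning):
#' all daughters take order parent + 1.
#'
#' @param cell A `swc_cell`.
#' @param soma Output of [separate_soma()]; computed if `NULL`.
#' @return A tibble with one row per branch: `branch_id`, `projection`,
#'   `order`, `parent_branch`, `terminal` (logical), and `path` (a list column
#'   of n x 4 matrices: x, y, z, radius along the branch).
#' @export
decompose_branches <- function(cell, soma = NULL) {
  if (is.null(soma)) soma <- separate_soma(cell)
  ch <- children_index(cell)
  in_soma <- logical(nrow(cell))
  in_soma[soma$soma_rows] <- TRUE
  # children counted within the projection forest only
  n_child <- vapply(seq_len(nrow(cell)), function(i) {
    sum(!in_soma[ch[[i]]])
  }, integer(1))

  branches <- list()
  make_branch <- function(start_pt, start_r, first_row, projection, order,
                          parent_branch) {
    pts <- list(c(start_pt, start_r))
    cur <- first_row
    repeat {
      pts[[length(pts) + 1]] <- c(cell$x[cur], cell$y[cur], cell$z[cur],
        cell$radius[cur])
      kids <- ch[[cur]]
      kids <- kids[!in_soma[kids]]
      if (length(kids) != 1) break
      cur <- kids
    }
    path <- do.call(rbind, pts)
    colnames(path) <- c("x", "y", "z", "radius")
    id <- length(branches) + 1L
    branches[[id]] <<- tibble::tibble(
      branch_id = id, projection = projection, order = order,
      parent_branch = parent_branch,
      terminal = length(ch[[cur]][!in_soma[ch[[cur]]]]) == 0,
      end_row = cur,
      path = list(path)
    )
    kids <- ch[[cur]][!in_soma[ch[[cur]]]]
    if (length(kids) > 2) {
      rlang::warn(sprintf(
        "node %d has %d daughters; handled as stacked bifurcations",
        cell$id[cur], length(kids)
      ))
    }
    for (k in kids) {
      make_branch(
        c(cell$x[cur], cell$y[cur], cell$z[cur]), cell$radius[cur],
        k, projection, order + 1L, id
      )
    }
  }
  for (p in seq_len(nrow(soma$projections))) {
    make_branch(
      soma$projections$entry[[p]], soma$projections$entry_radius[p],
      soma$projections$child_row[p], p, 1L, NA_integer_
    )
  }
  dplyr::bind_rows(branches)
}

# ---- sub-segment geometry -------------------------------------------------

# sub-segment table of a branch path: length, mean radius, lateral surface,
# volume. Cylinder convention at mean endpoint radius by default; frustum mode
# uses the exact conical frustum lateral surface and volume.
subsegments <- function(path, mode = c("cylinder", "frustum")) {
  mode <- match.arg(mode)
  n <- nrow(path)
  if (n < 2) {
    return(tibble::tibble(length = numeric(0), radius = numeric(0),
      surface = numeric(0), volume = numeric(0)))
  }
  d <- path[-1, 1:3, drop = FALSE] - path[-n, 1:3, drop = FALSE]
  len <- sqrt(rowSums(d^2))
  r1 <- path[-n, 4]
  r2 <- path[-1, 4]
  keep <- len > 1e-12
  len <- len[keep]; r1 <- r1[keep]; r2 <- r2[keep]
  rbar <- (r1 + r2) / 2
  if (mode == "cylinder") {
    surface <- 2 * pi * rbar * len
    volume <- pi * rbar^2 * len
  } else {
    slant <- sqrt(len^2 + (r2 - r1)^2)
    surface <- pi * (r1 + r2) * slant
    volume <- pi * len * (r1^2 + r1 * r2 + r2^2) / 3
  }
  tibble::tibble(length = len, radius = rbar, surface = surface, volume = volume)
}

#' Branch length
#' @param path An n x 4 branch path matrix (x, y, z, radius).
#' @return Path length in micrometres (sum of sub-segment lengths).
#' @export
branch_length <- function(path) {
  sum(subsegments(path)$length)
}

#' Branch straightness ratio (tau) and tortuosity
#'
#' `tau` is the end-to-end distance divided by the path length, in (0, 1];
#' conventional tortuosity is its inverse.
#'
#' @param path Branch path matrix.
#' @return Named list with `tau` and `tortuosity`.
#' @export
branch_tortuosity <- function(path) {
  L <- branch_length(path)
  if (L <= 0) {
    rlang::abort("zero path length", class = "morphdmri_error_degenerate")
  }
  chord <- sqrt(sum((path[nrow(path), 1:3] - path[1, 1:3])^2))
  tau <- min(chord / L, 1)
  list(tau = tau, tortuosity = 1 / tau)
}

#' Branch beading (coefficient of variation of radius)
#' @param path Branch path matrix.
#' @return Population std / mean of sub-segment radii.
#' @export
branch_beading_cv <- function(path) {
  r <- subsegments(path)$radius
  if (length(r) == 0) return(NA_real_)
  m <- mean(r)
  sqrt(mean((r - m)^2)) / m
}

#' Branch surface-to-volume ratio
#' @param path Branch path matrix.
#' @param mode Sub-segment convention, `"cylinder"` (default) or `"frustum"`.
#' @return S/V in 1/micrometre (lateral surfaces only, no end caps).
#' @export
branch_sv <- function(path, mode = "cylinder") {
  ss <- subsegments(path, mode)
  sum(ss$surface) / sum(ss$volume)
}

#' Branch undulation
#'
#' Mean angle (radians) subtended by each sub-segment direction and the
#' branch chord (start-to-end vector).
#'
#' @param path Branch path matrix.
#' @return Mean angle in radians.
#' @export
branch_undulation <- function(path) {
  n <- nrow(path)
  chord <- path[n, 1:3] - path[1, 1:3]
  nc <- sqrt(sum(chord^2))
  if (nc < 1e-12) return(NA_real_)
  chord <- chord / nc
  d <- path[-1, 1:3, drop = FALSE] - path[-n, 1:3, drop = FALSE]
  len <- sqrt(rowSums(d^2))
  keep <- len > 1e-12
  u <- d[keep, , drop = FALSE] / len[keep]
  cosang <- pmin(1, pmax(-1, as.vector(u %*% chord)))
  mean(acos(cosang))
}

#' Mean branch curvature radius
#'
#' Mean circumscribed-circle radius over interior node triplets; collinear
#' triplets (circumradius above `cap`) are excluded from the mean.
#'
#' @param path Branch path matrix.
#' @param cap Circumradius cap in micrometres (default 1e4).
#' @return Mean curvature radius in micrometres, or `NA` if fewer than 3
#'   nodes or all triplets collinear.
#' @export
branch_curvature_radius <- function(path, cap = 1e4) {
  n <- nrow(path)
  if (n < 3) return(NA_real_)
  rcs <- vapply(seq_len(n - 2), function(i) {
    circumradius(path[i, 1:3], path[i + 1, 1:3], path[i + 2, 1:3])
  }, numeric(1))
  rcs <- rcs[is.finite(rcs) & rcs < cap]
  if (length(rcs) == 0) return(NA_real_)
  mean(rcs)
}

# circumradius of the circle through three 3-D points: R = abc / (4 * area)
circumradius <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  c <- sqrt(sum((p1 - p2)^2))
  cr <- crossprod3(p2 - p1, p3 - p1)
  area2 <- sqrt(sum(cr^2)) # = 2 * triangle area
  if (area2 < 1e-14) return(Inf)
  a * b * c / (2 * area2)
}

crossprod3 <- function(u, v) {
  c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
}

#' Bifurcation angle between two daughter branches
#'
#' The daughter initial directions are estimated as the chord from the
#' bifurcation point over the first `min(chord_length, branch length)` of
#' path, which is robust to node jitter.
#'
#' @param path_a,path_b Daughter branch path matrices (both starting at the
#'   bifurcation point).
#' @param chord_length Chord length in micrometres (default 5).
#' @return Angle in radians.
#' @export
branch_angle <- function(path_a, path_b, chord_length = 5) {
  dir_a <- initial_direction(path_a, chord_length)
  dir_b <- initial_direction(path_b, chord_length)
  acos(pmin(1, pmax(-1, sum(dir_a * dir_b))))
}

# unit chord over the first `chord_length` um of path
initial_direction <- function(path, chord_length = 5) {
  n <- nrow(path)
  d <- path[-1, 1:3, drop = FALSE] - path[-n, 1:3, drop = FALSE]
  cum <- cumsum(sqrt(rowSums(d^2)))
  stop_i <- which(cum >= chord_length)[1]
  end <- if (is.na(stop_i)) n else stop_i + 1
  v <- path[end, 1:3] - path[1, 1:3]
  v / sqrt(sum(v^2))
}

#' Moment-weighted effective MR radius
#'
#' `(<R^p> / <R^q>)^(1/4)`: the volume-weighted radius a diffusion-MRI signal
#' is sensitive to for a population of radii. Exponents (7, 3) apply to soma
#' populations, (6, 2) to branch (cylinder) populations.
#'
#' @param radii Positive radii in micrometres.
#' @param p,q Moment exponents.
#' @return Effective MR radius in micrometres.
#' @export
mr_effective_radius <- function(radii, p = 6, q = 2) {
  if (length(radii) == 0) {
    rlang::abort("empty radius list", class = "morphdmri_error_empty")
  }
  stopifnot(all(radii > 0))
  (mean(radii^p) / mean(radii^q))^(1 / 4)
}

#' Soma surface fraction covered by projections
#'
#' Ratio between the total cross-sectional area of the primary projections
#' and the soma surface area, clipped to [0, 1].
#'
#' @param s_soma Soma surface area in um^2.
#' @param primary_radii Radii of the primary projections where they meet the
#'   soma, in micrometres.
#' @return Fraction in [0, 1].
#' @export
eta_soma <- function(s_soma, primary_radii) {
  if (length(primary_radii) == 0) return(0)
  min(1, sum(pi * primary_radii^2) / s_soma)
}

# ---- whole-cell morphometry ----------------------------------------------

#' Compute the full structural descriptor record of a cell
#'
#' Separates the soma from the projections, decomposes the projections into
#' branches, and computes every structural descriptor: the cell-level
#' extent `R_domain`, number of primary projections `N_proj`, maximum branch
#' order `BO`, whole-cell surface-to-volume ratio `SV_domain`; the soma
#' metrics `R_soma`, `R_MRsoma`, `eta_soma`, `SV_soma`; and the per-branch
#' metrics `L_branch`, `R_branch` (mean and std), `R_MRbranch`, `CV_branch`,
#' `SV_branch`, `muOD_branch`, `R_c`, `tau_branch`, plus bifurcation angles
#' `theta_branch`.
#'
#' @param cell A `swc_cell`, already stripped of axons and spines.
#' @param soma_method Soma surface/volume model: `"sphere"` (default; the
#'   nominal soma sphere of the root radius) or `"mesh"` (triangulated
#'   iso-surface of the soma node union via [build_mesh()]).
#' @param segment_mode Sub-segment convention for surfaces and volumes,
#'   `"cylinder"` (default) or `"frustum"`.
#' @param voxel_size Mesh voxel size in micrometres when `soma_method =
#'   "mesh"`; default soma radius / 20.
#' @return A `cell_morphometry` object; see [tidy.cell_morphometry()] for the
#'   per-branch table and [glance.cell_morphometry()] for the one-row cell
#'   summary.
#' @export
cell_morphometry <- function(cell, soma_method = c("sphere", "mesh"),
                             segment_mode = "cylinder", voxel_size = NULL) {
  soma_method <- match.arg(soma_method)
  soma <- separate_soma(cell)
  branches <- decompose_branches(cell, soma)

  if (soma_method == "sphere") {
    r0 <- soma$threshold
    v_soma <- 4 / 3 * pi * r0^3
    s_soma <- 4 * pi * r0^2
  } else {
    vs <- voxel_size %||% (soma$threshold / 20)
    mesh <- build_mesh(cell[soma$soma_rows, ], voxel_size = vs)
    v_soma <- mesh_volume(mesh)
    s_soma <- mesh_surface_area(mesh)
  }
  r_soma <- (3 * v_soma / (4 * pi))^(1 / 3)

  per_branch <- dplyr::mutate(
    branches,
    L_branch = purrr::map_dbl(path, branch_length),
    tau_branch = purrr::map_dbl(path, ~ branch_tortuosity(.x)$tau),
    CV_branch = purrr::map_dbl(path, branch_beading_cv),
    SV_branch = purrr::map_dbl(path, branch_sv, mode = segment_mode),
    muOD_branch = purrr::map_dbl(path, branch_undulation),
    R_c = purrr::map_dbl(path, branch_curvature_radius),
    R_branch = purrr::map_dbl(path, ~ mean(subsegments(.x)$radius)),
    R_branch_sd = purrr::map_dbl(path, ~ stats::sd(subsegments(.x)$radius)),
    surface = purrr::map_dbl(path, ~ sum(subsegments(.x, segment_mode)$surface)),
    volume = purrr::map_dbl(path, ~ sum(subsegments(.x, segment_mode)$volume))
  )

  # bifurcation angles: branches sharing a parent branch
  daughters <- dplyr::filter(per_branch, !is.na(parent_branch))
  theta <- if (nrow(daughters) == 0) {
    tibble::tibble(parent_branch = integer(0), theta_branch = numeric(0))
  } else {
    daughters |>
      dplyr::group_by(parent_branch) |>
      dplyr::filter(dplyr::n() >= 2) |>
      dplyr::summarise(
        theta_branch = branch_angle(path[[1]], path[[2]]),
        .groups = "drop"
      )
  }

  primary_radii <- soma$projections$entry_radius
  eta <- eta_soma(s_soma, primary_radii)
  sv_domain <- (s_soma * (1 - eta) + sum(per_branch$surface)) /
    (v_soma + sum(per_branch$volume))

  rr <- which(is.na(cell$parent))[1]
  r_domain <- max(dist_from_point(cell, soma$root_point))

  structure(
    list(
      branches = per_branch,
      theta = theta,
      soma = list(
        V_soma = v_soma, S_soma = s_soma, R_soma = r_soma,
        SV_soma = s_soma / v_soma, eta_soma = eta,
        threshold = soma$threshold, n_nodes = length(soma$soma_rows)
      ),
      summary = tibble::tibble(
        R_domain = r_domain,
        N_proj = nrow(soma$projections),
        BO = max(per_branch$order),
        SV_domain = sv_domain,
        R_soma = r_soma,
        R_MRsoma = mr_effective_radius(r_soma, p = 7, q = 3),
        eta_soma = eta,
        SV_soma = s_soma / v_soma,
        L_branch = mean(per_branch$L_branch),
        R_branch = mean(per_branch$R_branch),
        R_MRbranch = mr_effective_radius(per_branch$R_branch, p = 6, q = 2),
        CV_branch = mean(per_branch$CV_branch, na.rm = TRUE),
        SV_branch = mean(per_branch$SV_branch),
        muOD_branch = mean(per_branch$muOD_branch, na.rm = TRUE),
        R_c = mean(per_branch$R_c, na.rm = TRUE),
        tau_branch = mean(per_branch$tau_branch),
        theta_branch = if (nrow(theta) > 0) mean(theta$theta_branch) else NA_real_,
        n_branches = nrow(per_branch)
      )
    ),
    class = "cell_morphometry"
  )
}

#' @export
print.cell_morphometry <- function(x, ...) {
  cat(sprintf(
    "<cell_morphometry> %d projections, %d branches, BO %d\n",
    x$summary$N_proj, x$summary$n_branches, x$summary$BO
  ))
  print(x$summary)
  invisible(x)
}

#' Per-branch descriptor table of a morphometry fit
#' @param x A `cell_morphometry` object.
#' @param ... Unused.
#' @return A tibble with one row per branch.
#' @method tidy cell_morphometry
#' @export
tidy.cell_morphometry <- function(x, ...) {
  dplyr::select(
    x$branches, branch_id, projection, order, terminal,
    L_branch, R_branch, R_branch_sd, CV_branch, SV_branch,
    muOD_branch, R_c, tau_branch, surface, volume
  )
}

#' One-row cell summary of a morphometry fit
#' @param x A `cell_morphometry` object.
#' @param ... Unused.
#' @return A one-row tibble with all cell-level structural descriptors.
#' @method glance cell_morphometry
#' @export
glance.cell_morphometry <- function(x, ...) {
  x$summary
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
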