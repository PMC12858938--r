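#' Topological morphology descriptor barcode of a projection
#'
#' Terminal points are filtered by their path length from the soma attachment
#' point. At each branching point the sibling carrying the shorter maximal
#' path is eliminated and recorded as a bar (birth = path length of the
#' branching point, death = the eliminated subtree's maximal terminal path
#' length); the longest path survives to the root and yields the bar
#' (0, max path length). One bar per terminal point.
#'
#' @param cell A `swc_cell`.
#' @param soma Output of [separate_soma()] (computed if `NULL`).
#' @param projection Integer: which primary projection (default all).
#' @return A `persistence_barcode` tibble: `birth`, `death` (um),
#'   `projection`.
#' @export
tmd_barcode <- function(cell, soma = NULL, projection = NULL) {
  if (is.null(soma)) soma <- separate_soma(cell)
  branches <- decompose_branches(cell, soma)
  projs <- projection %||% sort(unique(branches$projection))
  bars <- purrr::map(projs, function(p) {
    pb <- dplyr::filter(branches, projection == p)
    bars_one_projection(pb)
  })
  out <- dplyr::bind_rows(bars)
  class(out) <- c("persistence_barcode", class(out))
  out
}

# elimination on the branch tree of one projection
bars_one_projection <- function(pb) {
  n <- nrow(pb)
  lens <- vapply(pb$path, branch_length, numeric(1))
  # path length from the soma surface to the START of each branch
  start_len <- numeric(n)
  ord <- order(pb$order)
  for (i in ord) {
    p <- pb$parent_branch[i]
    if (!is.na(p)) {
      pi_ <- which(pb$branch_id == p)
      start_len[i] <- start_len[pi_] + lens[pi_]
    }
  }
  end_len <- start_len + lens
  children <- lapply(pb$branch_id, function(id) which(pb$parent_branch == id))
  # subtree max terminal path length, computed leaves-up
  sub_max <- end_len
  for (i in rev(ord)) {
    kids <- children[[i]]
    if (length(kids) > 0) sub_max[i] <- max(sub_max[kids])
  }
  bars <- list()
  for (i in seq_len(n)) {
    kids <- children[[i]]
    if (length(kids) == 0) next
    # deterministic elimination: smaller subtree-max first, ties by branch id
    km <- sub_max[kids]
    o <- order(km, pb$branch_id[kids])
    losers <- kids[o][-length(o)]
    for (l in losers) {
      bars[[length(bars) + 1]] <- c(end_len[i], sub_max[l])
    }
  }
  root_i <- which(is.na(pb$parent_branch))[1]
  bars[[length(bars) + 1]] <- c(0, sub_max[root_i])
  m <- do.call(rbind, bars)
  tibble::tibble(birth = m[, 1], death = m[, 2], projection = pb$projection[1])
}

#' Persistence image of one or more barcodes
#'
#' Isotropic Gaussian kernel density estimate of the bar points in the
#' (birth, death) plane, evaluated on a regular grid and normalized to unit
#' sum.
#'
#' @param bars A `persistence_barcode` (or any data frame with `birth`,
#'   `death`).
#' @param grid_extent Numeric `c(min, max)` for both axes; default
#'   `c(0, max(death))`.
#' @param resolution Grid cells per axis (default 100).
#' @param bandwidth Gaussian sigma in micrometres; default Scott's rule on
#'   the pooled bar coordinates.
#' @return A `persistence_image`: list with `z` (resolution x resolution
#'   matrix summing to 1), `x`, `y` (cell-centre coordinates), `bandwidth`,
#'   `extent`.
#' @export
persistence_image <- function(bars, grid_extent = NULL, resolution = 100,
                              bandwidth = NULL) {
  if (nrow(bars) == 0) {
    rlang::abort("empty barcode set", class = "morphdmri_error_empty")
  }
  grid_extent <- grid_extent %||% c(0, max(bars$death))
  bandwidth <- bandwidth %||% scott_bandwidth(bars)
  h <- diff(grid_extent) / resolution
  centers <- grid_extent[1] + (seq_len(resolution) - 0.5) * h
  gx <- outer(centers, bars$birth, function(a, b) exp(-(a - b)^2 / (2 * bandwidth^2)))
  gy <- outer(centers, bars$death, function(a, b) exp(-(a - b)^2 / (2 * bandwidth^2)))
  z <- gx %*% t(gy) # z[i, j] = sum_k gx[i,k] gy[j,k]; rows birth, cols death
  z <- z / sum(z)
  structure(
    list(z = z, x = centers, y = centers, bandwidth = bandwidth,
      extent = grid_extent, n_bars = nrow(bars)),
    class = "persistence_image"
  )
}

# Scott's rule bandwidth on the pooled (birth, death) coordinates
scott_bandwidth <- function(bars) {
  v <- c(bars$birth, bars$death)
  n <- nrow(bars)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) s <- max(1e-6, mean(v) * 0.05 + 1e-6)
  max(s * n^(-1 / 6), 1e-6)
}

#' @export
print.persistence_image <- function(x, ...) {
  cat(sprintf(
    "<persistence_image> %dx%d grid on [%.3g, %.3g], bandwidth %.3g, %d bars\n",
    nrow(x$z), ncol(x$z), x$extent[1], x$extent[2], x$bandwidth, x$n_bars
  ))
  invisible(x)
}

#' Topological distance between two persistence images
#'
#' L1 distance of the pixel arrays: 0 for identical images, 2 for images
#' with disjoint support (each sums to 1).
#'
#' @param img_a,img_b `persistence_image`s on the identical grid.
#' @return D in [0, 2].
#' @export
topological_distance <- function(img_a, img_b) {
  if (!isTRUE(all.equal(dim(img_a$z), dim(img_b$z))) ||
    max(abs(img_a$extent - img_b$extent)) > 1e-9) {
    rlang::abort("persistence images are on different grids",
      class = "morphdmri_error_grid")
  }
  sum(abs(img_a$z - img_b$z))
}

# mean of per-cell normalized images, renormalized
group_image <- function(barcodes, grid_extent, resolution, bandwidth) {
  imgs <- lapply(barcodes, persistence_image,
    grid_extent = grid_extent, resolution = resolution, bandwidth = bandwidth
  )
  z <- Reduce(`+`, lapply(imgs, `[[`, "z")) / length(imgs)
  z <- z / sum(z)
  img <- imgs[[1]]
  img$z <- z
  img$n_bars <- sum(vapply(imgs, `[[`, numeric(1), "n_bars"))
  img
}

#' Bootstrap significance of a topological distance between cell groups
#'
#' The observed D compares the two group-mean persistence images (each group
#' image is the renormalized mean of per-cell normalized images on a common
#' grid). The null distribution resamples cells with replacement from the
#' pooled set into two pseudo-groups of the original sizes; the p-value is
#' the smoothed fraction of null distances at least as large as observed.
#'
#' @param cells_a,cells_b Lists of `swc_cell` objects (>= 2 per group), or
#'   lists of precomputed `persistence_barcode`s.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @param resolution Image grid resolution (default 100).
#' @return A `distance_result` list: `D`, `p_value`, `n_boot`, `seed`,
#'   `null_distances`.
#' @export
bootstrap_distance <- function(cells_a, cells_b, n_boot = 1000, seed = 1,
                               resolution = 100) {
  if (length(cells_a) < 2 || length(cells_b) < 2) {
    rlang::abort("need at least 2 cells per group",
      class = "morphdmri_error_degenerate")
  }
  as_bars <- function(x) if (inherits(x, "swc_cell")) tmd_barcode(x) else x
  bars_a <- lapply(cells_a, as_bars)
  bars_b <- lapply(cells_b, as_bars)
  pooled <- c(bars_a, bars_b)
  max_death <- max(vapply(pooled, function(b) max(b$death), numeric(1)))
  extent <- c(0, max_death)
  bw <- scott_bandwidth(dplyr::bind_rows(pooled))
  # per-cell normalized images are fixed across resamples: compute once
  zs <- lapply(pooled, function(b) {
    persistence_image(b, grid_extent = extent, resolution = resolution,
      bandwidth = bw)$z
  })
  mean_z <- function(idx) {
    z <- Reduce(`+`, zs[idx]) / length(idx)
    z / sum(z)
  }
  na <- length(bars_a); nb <- length(bars_b); np <- na + nb
  d_obs <- sum(abs(mean_z(seq_len(na)) - mean_z(na + seq_len(nb))))
  null_d <- numeric(n_boot)
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed))
  for (i in seq_len(n_boot)) {
    ia <- sample.int(np, na, replace = TRUE)
    ib <- sample.int(np, nb, replace = TRUE)
    null_d[i] <- sum(abs(mean_z(ia) - mean_z(ib)))
  }
  p <- (1 + sum(null_d >= d_obs)) / (n_boot + 1)
  structure(
    list(D = d_obs, p_value = p, n_boot = n_boot, seed = seed,
      null_distances = null_d),
    class = "distance_result"
  )
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf(
    "<distance_result> D = %.4f, p = %.4g (n_boot = %d, seed = %d)\n",
    x$D, x$p_value, x$n_boot, x$seed
  ))
  invisible(x)
}

# seed handling that restores the caller's RNG state
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
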