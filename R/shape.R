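#' Decompose a cell into volume-weighted line segments
#'
#' Each branch path is divided into consecutive chunks of roughly
#' `target_length` micrometres of path length (chunks shorter than
#' `min_length` are merged into their neighbour). Every chunk yields one
#' axial orientation — the principal axis of its nodes, falling back to the
#' chord for 2-node chunks — weighted by the chunk's cylinder volume.
#' Orientations are axes: u and -u are identified.
#'
#' @param cell A `swc_cell` with projections.
#' @param target_length Segment length in micrometres (default 10).
#' @param min_length Minimum chunk length before merging (default 2).
#' @return A `segment_set` tibble: `ux`, `uy`, `uz` (unit axis), `mx`, `my`,
#'   `mz` (midpoint), `length` (um), `weight` (volume, um^3).
#' @export
segment_cell <- function(cell, target_length = 10, min_length = 2) {
  branches <- decompose_branches(cell)
  segs <- purrr::map(branches$path, segment_path,
    target_length = target_length, min_length = min_length
  )
  out <- dplyr::bind_rows(segs)
  class(out) <- c("segment_set", class(out))
  out
}

# split one branch path into ~target_length chunks and fit a line to each
segment_path <- function(path, target_length = 10, min_length = 2) {
  n <- nrow(path)
  if (n < 2) return(NULL)
  d <- path[-1, 1:3, drop = FALSE] - path[-n, 1:3, drop = FALSE]
  seg_len <- sqrt(rowSums(d^2))
  L <- sum(seg_len)
  n_chunks <- max(1L, round(L / target_length))
  # merge rule: equal-arc chunks no shorter than min_length
  while (n_chunks > 1 && L / n_chunks < min_length) n_chunks <- n_chunks - 1L
  cum <- c(0, cumsum(seg_len))
  breaks <- seq(0, L, length.out = n_chunks + 1)
  # assign sub-segments to chunks by midpoint arc position
  mid_arc <- (cum[-length(cum)] + cum[-1]) / 2
  chunk_of <- pmin(n_chunks, findInterval(mid_arc, breaks, rightmost.closed = TRUE))
  ss <- subsegments(path)
  out <- vector("list", n_chunks)
  for (k in seq_len(n_chunks)) {
    rows <- which(chunk_of == k)
    if (length(rows) == 0) next
    pts <- path[unique(c(rows, rows + 1)), 1:3, drop = FALSE]
    u <- if (nrow(pts) == 2) {
      pts[2, ] - pts[1, ]
    } else {
      ctr <- colMeans(pts)
      sv <- svd(sweep(pts, 2, ctr))
      sv$v[, 1]
    }
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12) next
    u <- u / nu
    if (u[3] < 0 || (u[3] == 0 && u[1] < 0)) u <- -u # canonical hemisphere
    mid <- colMeans(pts)
    out[[k]] <- tibble::tibble(
      ux = u[1], uy = u[2], uz = u[3],
      mx = mid[1], my = mid[2], mz = mid[3],
      length = sum(ss$length[rows]),
      weight = sum(ss$volume[rows])
    )
  }
  dplyr::bind_rows(out)
}

#' Volume-weighted orientation scatter matrix eigenvalues
#'
#' Eigenvalues of `sum(w_i u_i u_i^T) / sum(w_i)`, returned ascending and
#' trace-normalized to 1, with the corresponding principal axes.
#'
#' @param segments A `segment_set`, or a matrix of unit axes with a `weights`
#'   argument.
#' @param weights Optional weights when `segments` is a plain matrix.
#' @return A list with `tau` (ascending eigenvalue triple, sums to 1) and
#'   `axes` (3 x 3 matrix, columns matching `tau`).
#' @export
scatter_eigenvalues <- function(segments, weights = NULL) {
  if (is.data.frame(segments)) {
    U <- as.matrix(segments[, c("ux", "uy", "uz")])
    w <- segments$weight
  } else {
    U <- segments
    w <- weights %||% rep(1, nrow(U))
  }
  S <- crossprod(U * sqrt(w)) / sum(w)
  e <- eigen(S, symmetric = TRUE)
  ord <- order(e$values)
  tau <- pmax(e$values[ord], 0)
  tau <- tau / sum(tau)
  list(tau = tau, axes = e$vectors[, ord, drop = FALSE])
}

#' Fractional anisotropy of an eigenvalue triple
#'
#' `FA = sqrt(3/2 * sum((tau_i - mean)^2) / sum(tau_i^2))`, the normalized
#' dispersion of the scatter-matrix eigenvalues: 0 for isotropic orientation
#' distributions, 1 for perfectly parallel segments. Scale-invariant.
#'
#' @param tau Numeric triple of non-negative eigenvalues (not all zero).
#' @return FA in [0, 1].
#' @export
fractional_anisotropy <- function(tau) {
  stopifnot(length(tau) == 3, all(tau >= 0), any(tau > 0))
  m <- mean(tau)
  sqrt(1.5 * sum((tau - m)^2) / sum(tau^2))
}

#' Adjusted fractional anisotropy
#'
#' FA recomputed with `tau_1` replaced by `tau_2`, compensating the
#' depth-of-field artifact of optical reconstructions (cells compressed along
#' the acquisition Z-axis inflate FA by depressing the smallest eigenvalue).
#'
#' @param tau Ascending eigenvalue triple.
#' @return Adjusted FA in [0, 1].
#' @export
adjusted_fa <- function(tau) {
  tau <- sort(tau)
  fractional_anisotropy(c(tau[2], tau[2], tau[3]))
}

# log of the Watson normalizing integral M(kappa) = int_0^1 exp(kappa t^2) dt,
# computed stably as kappa + log int_0^1 exp(kappa (t^2 - 1)) dt
log_watson_M <- function(kappa) {
  if (kappa == 0) return(0)
  f <- function(t) exp(kappa * (t^2 - 1))
  kappa + log(stats::integrate(f, 0, 1, rel.tol = 1e-10)$value)
}

# E[(u . mu)^2] under Watson(kappa): d/dkappa log M(kappa)
watson_t2_mean <- function(kappa) {
  if (kappa == 0) return(1 / 3)
  num <- stats::integrate(function(t) t^2 * exp(kappa * (t^2 - 1)), 0, 1,
    rel.tol = 1e-10)$value
  den <- stats::integrate(function(t) exp(kappa * (t^2 - 1)), 0, 1,
    rel.tol = 1e-10)$value
  num / den
}

#' Maximum-likelihood Watson concentration
#'
#' Fits the axial Watson distribution about the principal scatter axis. The
#' MLE solves `E[(u . mu)^2] = r2bar`, the weighted mean squared projection
#' onto the axis; kappa = 0 when the sample is at or below isotropy.
#'
#' @param orientations Matrix of unit axes (n x 3) or a `segment_set`.
#' @param weights Optional non-negative weights.
#' @param kappa_max Solver cap (default 1e4); perfectly parallel samples are
#'   reported at the cap.
#' @param tol Solver tolerance (default 1e-6).
#' @return A `watson_fit` list: `kappa`, `mu` (principal axis), `r2bar`, `n`.
#' @export
fit_watson_kappa <- function(orientations, weights = NULL, kappa_max = 1e4,
                             tol = 1e-6) {
  ow <- as_axes(orientations, weights)
  if (nrow(unique(round(ow$U, 8))) < 3) {
    rlang::abort("need at least 3 distinct orientations",
      class = "morphdmri_error_degenerate")
  }
  sc <- scatter_eigenvalues(ow$U, ow$w)
  mu <- sc$axes[, 3]
  t2 <- as.vector(ow$U %*% mu)^2
  r2bar <- sum(ow$w * t2) / sum(ow$w)
  kappa <- if (r2bar <= 1 / 3 + 1e-12) {
    0
  } else if (watson_t2_mean(kappa_max) <= r2bar) {
    kappa_max
  } else {
    stats::uniroot(function(k) watson_t2_mean(k) - r2bar,
      lower = 0, upper = kappa_max, tol = tol
    )$root
  }
  structure(list(kappa = kappa, mu = mu, r2bar = r2bar, n = nrow(ow$U)),
    class = "watson_fit")
}

# normalize orientation inputs to a unit-axis matrix + weights
as_axes <- function(orientations, weights = NULL) {
  if (is.data.frame(orientations)) {
    U <- as.matrix(orientations[, c("ux", "uy", "uz")])
    w <- weights %||% orientations$weight
  } else {
    U <- as.matrix(orientations)
    w <- weights %||% rep(1, nrow(U))
  }
  nu <- sqrt(rowSums(U^2))
  U <- U / nu
  list(U = U, w = w)
}

# log normalizing constant of the Bingham density
# f(u) propto exp(-k1 (u.e1)^2 - k2 (u.e2)^2) on the sphere:
# log of (1/4pi) int exp(-k1 x1^2 - k2 x2^2) dS, by Gauss-Legendre quadrature
log_bingham_F <- function(k1, k2, n_grid = 64) {
  gl <- gauss_legendre(n_grid, -1, 1) # cos(theta) nodes
  ph <- gauss_legendre(n_grid, 0, 2 * pi)
  ct <- gl$nodes
  st2 <- 1 - ct^2
  cp2 <- cos(ph$nodes)^2
  sp2 <- sin(ph$nodes)^2
  # x1 = sin(theta) cos(phi), x2 = sin(theta) sin(phi)
  E <- exp(-outer(st2, k1 * cp2 + k2 * sp2))
  val <- as.numeric(gl$weights %*% E %*% ph$weights) / (4 * pi)
  log(val)
}

gauss_legendre <- function(n, a, b) {
  # Golub-Welsch: nodes/weights from the Jacobi matrix eigen-decomposition
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

#' Maximum-likelihood Bingham concentrations
#'
#' Fits a Bingham density `exp(-kappa1 (u.e1)^2 - kappa2 (u.e2)^2)` about the
#' two minor scatter axes (e1 = smallest-eigenvalue axis). `kappa1 >= kappa2
#' >= 0`: large `kappa1` with small `kappa2` indicates a planar (girdle)
#' distribution. Reduces to Watson when kappa1 = kappa2.
#'
#' @param orientations Unit axes (n x 3 matrix or `segment_set`).
#' @param weights Optional weights.
#' @param kappa_max Concentration cap (default 1e4).
#' @return A `bingham_fit` list: `kappa1`, `kappa2`, `axes` (columns e1, e2,
#'   e3 = principal), `logLik`.
#' @export
fit_bingham <- function(orientations, weights = NULL, kappa_max = 1e4) {
  ow <- as_axes(orientations, weights)
  sc <- scatter_eigenvalues(ow$U, ow$w)
  e1 <- sc$axes[, 1]; e2 <- sc$axes[, 2]
  t1 <- as.vector(ow$U %*% e1)^2
  t2 <- as.vector(ow$U %*% e2)^2
  wsum <- sum(ow$w)
  m1 <- sum(ow$w * t1) / wsum
  m2 <- sum(ow$w * t2) / wsum
  negll <- function(lk) {
    k <- exp(lk)
    k[1] * m1 + k[2] * m2 + log_bingham_F(k[1], k[2])
  }
  # moment-matched Watson start
  k0 <- max(1e-2, tryCatch(
    stats::uniroot(function(k) watson_t2_mean(k) - (1 - m1 - m2),
      lower = 1e-6, upper = kappa_max)$root,
    error = function(e) 1e-2
  ))
  opt <- stats::optim(log(c(k0, k0)), negll, method = "Nelder-Mead",
    control = list(reltol = 1e-10, maxit = 500))
  k <- pmin(exp(opt$par), kappa_max)
  # near-isotropy: shrink to 0 when the likelihood is flat
  if (negll(log(c(1e-8, 1e-8))) <= opt$value + 1e-8) k <- c(0, 0)
  ord <- order(k, decreasing = TRUE)
  structure(
    list(
      kappa1 = k[ord][1], kappa2 = k[ord][2],
      axes = sc$axes[, c(ord, 3)], logLik = -opt$value * wsum
    ),
    class = "bingham_fit"
  )
}

#' Watson concentration from a Bingham fit
#'
#' When the first Bingham concentration dominates the second
#' (`kappa1 / kappa2 >= planarity_ratio`), the sample is planar and `kappa2`
#' is the appropriate Watson concentration; otherwise the average of the two
#' is used.
#'
#' @param kappa1,kappa2 Bingham concentrations, `kappa1 >= kappa2`.
#' @param planarity_ratio Dominance threshold (default 10).
#' @param eps Guard for `kappa2 = 0` (default 1e-8).
#' @return Watson concentration kappa.
#' @export
select_kappa <- function(kappa1, kappa2, planarity_ratio = 10, eps = 1e-8) {
  if (kappa1 == 0 && kappa2 == 0) return(0)
  if (kappa1 / max(kappa2, eps) >= planarity_ratio) kappa2 else (kappa1 + kappa2) / 2
}

#' Orientation dispersion from a Watson concentration
#'
#' `OD = (2/pi) * atan(1/kappa)`: 0 for perfectly aligned axes
#' (kappa -> infinity), 1 for isotropy (kappa -> 0).
#'
#' @param kappa Non-negative concentration.
#' @return OD in (0, 1].
#' @export
od_from_kappa <- function(kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(1)
  2 / pi * atan(1 / kappa)
}

#' Full shape descriptor record of a cell
#'
#' Segments the cell, computes the scatter eigenvalues, FA and adjusted FA,
#' fits the Bingham distribution, selects the Watson concentration and
#' converts it to orientation dispersion.
#'
#' @param cell A `swc_cell`.
#' @param target_length Segment length in micrometres (default 10).
#' @param planarity_ratio Dominance threshold for [select_kappa()].
#' @return A `cell_shape` object with fields `tau`, `FA`, `adjFA`, `kappa1`,
#'   `kappa2`, `kappa`, `OD`, `n_segments`.
#' @export
cell_shape <- function(cell, target_length = 10, planarity_ratio = 10) {
  segs <- segment_cell(cell, target_length)
  sc <- scatter_eigenvalues(segs)
  bf <- fit_bingham(segs)
  kappa <- select_kappa(bf$kappa1, bf$kappa2, planarity_ratio)
  structure(
    list(
      tau = sc$tau,
      FA = fractional_anisotropy(sc$tau),
      adjFA = adjusted_fa(sc$tau),
      kappa1 = bf$kappa1, kappa2 = bf$kappa2, kappa = kappa,
      OD = od_from_kappa(kappa),
      n_segments = nrow(segs),
      segments = segs
    ),
    class = "cell_shape"
  )
}

#' @export
print.cell_shape <- function(x, ...) {
  cat(sprintf(
    "<cell_shape> %d segments; tau = (%.3f, %.3f, %.3f); FA %.3f; adjFA %.3f; kappa %.2f; OD %.3f\n",
    x$n_segments, x$tau[1], x$tau[2], x$tau[3], x$FA, x$adjFA, x$kappa, x$OD
  ))
  invisible(x)
}

#' One-row summary of a shape record
#' @param x A `cell_shape`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance cell_shape
#' @export
glance.cell_shape <- function(x, ...) {
  tibble::tibble(
    tau1 = x$tau[1], tau2 = x$tau[2], tau3 = x$tau[3],
    FA = x$FA, adjFA = x$adjFA,
    kappa1 = x$kappa1, kappa2 = x$kappa2, kappa = x$kappa, OD = x$OD,
    n_segments = x$n_segments
  )
}

#' Per-segment table of a shape record
#' @param x A `cell_shape`.
#' @param ... Unused.
#' @return The `segment_set` tibble.
#' @method tidy cell_shape
#' @export
tidy.cell_shape <- function(x, ...) {
  tibble::as_tibble(x$segments)
}
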