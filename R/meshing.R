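#' Build a watertight surface mesh of a cell or node subset
#'
#' The cell is modelled as the implicit union of one sphere per node and one
#' round cone (a capsule with linearly varying radius) per edge. The zero
#' iso-surface of the signed distance field is extracted by marching
#' tetrahedra on a regular grid (6 tetrahedra per cube around the main
#' diagonal, a conforming decomposition, so the triangulation is watertight
#' by construction). Output meshes are in the cell's native frame, units
#' micrometres, and are compatible with Monte Carlo diffusion simulators.
#'
#' @param cell A `swc_cell` or any data frame with columns x, y, z, radius,
#'   parent (edges follow parent links; rows with `NA` parent contribute a
#'   sphere only).
#' @param voxel_size Grid spacing in micrometres. Must not exceed the
#'   smallest node radius. Default `min(radius) / 4`.
#' @return A `surface_mesh`: list with `vertices` (n x 3), `faces` (m x 3,
#'   outward-oriented, 1-based) and `provenance`.
#' @export
build_mesh <- function(cell, voxel_size = NULL) {
  if (nrow(cell) == 0) {
    rlang::abort("empty node set", class = "morphdmri_error_empty")
  }
  voxel_size <- voxel_size %||% (min(cell$radius) / 4)
  if (voxel_size > min(cell$radius)) {
    rlang::abort(
      sprintf(
        "voxel_size (%.3g) exceeds the smallest node radius (%.3g)",
        voxel_size, min(cell$radius)
      ),
      class = "morphdmri_error_resolution"
    )
  }
  pad <- max(cell$radius) + 2 * voxel_size
  lo <- c(min(cell$x), min(cell$y), min(cell$z)) - pad
  hi <- c(max(cell$x), max(cell$y), max(cell$z)) + pad
  gx <- seq(lo[1], hi[1], by = voxel_size)
  gy <- seq(lo[2], hi[2], by = voxel_size)
  gz <- seq(lo[3], hi[3], by = voxel_size)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)

  sdf <- array(Inf, dim = c(nx, ny, nz))
  idx <- stats::setNames(seq_len(nrow(cell)), cell$id)
  prow <- ifelse(is.na(cell$parent), NA_integer_, idx[as.character(cell$parent)])

  update_box <- function(bb_lo, bb_hi, fun) {
    i1 <- max(1L, findInterval(bb_lo[1], gx)); i2 <- min(nx, findInterval(bb_hi[1], gx) + 1L)
    j1 <- max(1L, findInterval(bb_lo[2], gy)); j2 <- min(ny, findInterval(bb_hi[2], gy) + 1L)
    k1 <- max(1L, findInterval(bb_lo[3], gz)); k2 <- min(nz, findInterval(bb_hi[3], gz) + 1L)
    if (i1 > i2 || j1 > j2 || k1 > k2) return(invisible())
    px <- gx[i1:i2]; py <- gy[j1:j2]; pz <- gz[k1:k2]
    P <- as.matrix(expand.grid(x = px, y = py, z = pz))
    d <- fun(P)
    block <- sdf[i1:i2, j1:j2, k1:k2]
    sdf[i1:i2, j1:j2, k1:k2] <<- pmin(block, array(d, dim = dim(block)))
    invisible()
  }

  # node spheres
  for (i in seq_len(nrow(cell))) {
    c0 <- c(cell$x[i], cell$y[i], cell$z[i]); r <- cell$radius[i]
    update_box(c0 - r - voxel_size, c0 + r + voxel_size, function(P) {
      sqrt((P[, 1] - c0[1])^2 + (P[, 2] - c0[2])^2 + (P[, 3] - c0[3])^2) - r
    })
  }
  # edge round cones
  for (i in which(!is.na(prow))) {
    j <- prow[i]
    a <- c(cell$x[j], cell$y[j], cell$z[j]); r1 <- cell$radius[j]
    b <- c(cell$x[i], cell$y[i], cell$z[i]); r2 <- cell$radius[i]
    rmax <- max(r1, r2)
    update_box(pmin(a, b) - rmax - voxel_size, pmax(a, b) + rmax + voxel_size,
      function(P) sd_round_cone(P, a, b, r1, r2))
  }

  mt <- marching_tetrahedra(sdf, gx, gy, gz)
  if (nrow(mt$faces) == 0) {
    rlang::abort("iso-surface extraction produced no faces",
      class = "morphdmri_error_degenerate")
  }
  mesh <- structure(
    list(
      vertices = mt$vertices, faces = mt$faces,
      provenance = list(voxel_size = voxel_size, n_nodes = nrow(cell))
    ),
    class = "surface_mesh"
  )
  # enforce globally outward orientation (signed volume > 0)
  if (signed_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  }
  mesh
}

# signed distance to a round cone (sphere-capped tapered capsule) from a to b
# with radii r1, r2; exact distance, vectorized over point rows of P
sd_round_cone <- function(P, a, b, r1, r2) {
  ba <- b - a
  l2 <- sum(ba^2)
  if (l2 < 1e-24) {
    return(sqrt((P[, 1] - a[1])^2 + (P[, 2] - a[2])^2 + (P[, 3] - a[3])^2) -
      max(r1, r2))
  }
  rr <- r1 - r2
  a2 <- l2 - rr^2
  il2 <- 1 / l2
  pax <- P[, 1] - a[1]; pay <- P[, 2] - a[2]; paz <- P[, 3] - a[3]
  y <- pax * ba[1] + pay * ba[2] + paz * ba[3]
  z <- y - l2
  wx <- pax * l2 - ba[1] * y
  wy <- pay * l2 - ba[2] * y
  wz <- paz * l2 - ba[3] * y
  x2 <- wx^2 + wy^2 + wz^2
  y2 <- y^2 * l2
  z2 <- z^2 * l2
  k <- sign(rr) * rr^2 * x2
  d <- (sqrt(x2 * a2 * il2) + y * rr) * il2 - r1
  cap_b <- sign(z) * a2 * z2 > k
  cap_a <- sign(y) * a2 * y2 < k
  d[cap_b] <- sqrt(x2[cap_b] + z2[cap_b]) * il2 - r2
  d[cap_a] <- sqrt(x2[cap_a] + y2[cap_a]) * il2 - r1
  d
}

# marching tetrahedra over a scalar grid; returns welded vertices and faces
marching_tetrahedra <- function(v, gx, gy, gz) {
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  # candidate cubes: any corner sign differs
  inside <- v < 0
  cs <- inside[-nx, -ny, -nz] + inside[-1, -ny, -nz] +
    inside[-nx, -1, -nz] + inside[-1, -1, -nz] +
    inside[-nx, -ny, -1] + inside[-1, -ny, -1] +
    inside[-nx, -1, -1] + inside[-1, -1, -1]
  cand <- which(cs > 0 & cs < 8, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))
  }
  # cube corner offsets, standard binary order (x fastest)
  offs <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
  )
  # 6 tetrahedra around the main diagonal corner1 -> corner7 (conforming)
  tets <- rbind(
    c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
    c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7)
  )
  nC <- nrow(cand)
  # corner linear indices and coordinates per cube
  lin <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  corner_lin <- sapply(seq_len(8), function(c8) {
    lin(cand[, 1] + offs[c8, 1], cand[, 2] + offs[c8, 2], cand[, 3] + offs[c8, 3])
  })
  if (nC == 1) corner_lin <- matrix(corner_lin, nrow = 1)
  corner_val <- matrix(v[corner_lin], nrow = nC)
  cx <- matrix(gx[cand[, 1] + rep(offs[, 1], each = nC)], nrow = nC)
  cy <- matrix(gy[cand[, 2] + rep(offs[, 2], each = nC)], nrow = nC)
  cz <- matrix(gz[cand[, 3] + rep(offs[, 3], each = nC)], nrow = nC)

  tri_list <- vector("list", 256)
  tl <- 0L
  emit <- function(p1, p2, p3, outward_ref) {
    # orient triangles so normals point away from the inside reference point
    n1 <- cbind(
      (p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) - (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
      (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) - (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
      (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) - (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
    )
    cen <- (p1 + p2 + p3) / 3
    flip <- rowSums(n1 * (cen - outward_ref)) < 0
    tmp <- p2[flip, , drop = FALSE]
    p2[flip, ] <- p3[flip, , drop = FALSE]
    p3[flip, ] <- tmp
    tl <<- tl + 1L
    tri_list[[tl]] <<- cbind(p1, p2, p3)
  }
  edge_point <- function(rows, cA, cB, vals, X, Y, Z) {
    va <- vals[cbind(rows, cA)]
    vb <- vals[cbind(rows, cB)]
    t <- va / (va - vb)
    cbind(
      X[cbind(rows, cA)] + t * (X[cbind(rows, cB)] - X[cbind(rows, cA)]),
      Y[cbind(rows, cA)] + t * (Y[cbind(rows, cB)] - Y[cbind(rows, cA)]),
      Z[cbind(rows, cA)] + t * (Z[cbind(rows, cB)] - Z[cbind(rows, cA)])
    )
  }

  for (t6 in seq_len(6)) {
    tc <- tets[t6, ]
    tv <- corner_val[, tc, drop = FALSE]
    tin <- tv < 0
    ci <- rowSums(tin)
    active <- which(ci > 0 & ci < 4)
    if (length(active) == 0) next
    tv_a <- tv[active, , drop = FALSE]
    X <- cx[active, tc, drop = FALSE]
    Y <- cy[active, tc, drop = FALSE]
    Z <- cz[active, tc, drop = FALSE]
    tin_a <- tin[active, , drop = FALSE]
    ci_a <- ci[active]
    nA <- length(active)
    rowsA <- seq_len(nA)

    corner_xyz <- function(sel, c4) {
      cbind(X[cbind(sel, rep(c4, length(sel)))],
        Y[cbind(sel, rep(c4, length(sel)))],
        Z[cbind(sel, rep(c4, length(sel)))])
    }
    # one-inside (or one-outside) cases
    for (vtx in 1:4) {
      others <- setdiff(1:4, vtx)
      sel1 <- which(ci_a == 1 & tin_a[, vtx]) # vtx inside
      sel3 <- which(ci_a == 3 & !tin_a[, vtx]) # vtx outside
      if (length(sel1) > 0) {
        emit(
          edge_point(sel1, vtx, others[1], tv_a, X, Y, Z),
          edge_point(sel1, vtx, others[2], tv_a, X, Y, Z),
          edge_point(sel1, vtx, others[3], tv_a, X, Y, Z),
          corner_xyz(sel1, vtx) # inside reference: the lone inside vertex
        )
      }
      if (length(sel3) > 0) {
        emit(
          edge_point(sel3, vtx, others[1], tv_a, X, Y, Z),
          edge_point(sel3, vtx, others[2], tv_a, X, Y, Z),
          edge_point(sel3, vtx, others[3], tv_a, X, Y, Z),
          # inside reference: centroid of the three inside vertices
          (corner_xyz(sel3, others[1]) + corner_xyz(sel3, others[2]) +
            corner_xyz(sel3, others[3])) / 3
        )
      }
    }
    # two-two cases
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (pp in seq_len(6)) {
      A <- pairs[pp, 1]; B <- pairs[pp, 2]
      CD <- setdiff(1:4, c(A, B))
      sel <- which(ci_a == 2 & tin_a[, A] & tin_a[, B])
      if (length(sel) == 0) next
      qAC <- edge_point(sel, A, CD[1], tv_a, X, Y, Z)
      qAD <- edge_point(sel, A, CD[2], tv_a, X, Y, Z)
      qBC <- edge_point(sel, B, CD[1], tv_a, X, Y, Z)
      qBD <- edge_point(sel, B, CD[2], tv_a, X, Y, Z)
      ref <- (corner_xyz(sel, A) + corner_xyz(sel, B)) / 2
      emit(qAC, qAD, qBD, ref)
      emit(qAC, qBD, qBC, ref)
    }
  }
  tris <- do.call(rbind, tri_list[seq_len(tl)])
  # weld vertices
  pts <- rbind(tris[, 1:3], tris[, 4:6], tris[, 7:9])
  key <- paste(round(pts[, 1], 9), round(pts[, 2], 9), round(pts[, 3], 9))
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(key), , drop = FALSE]
  m <- nrow(tris)
  faces <- cbind(uid[1:m], uid[m + (1:m)], uid[2 * m + (1:m)])
  # drop degenerate faces (two welded vertices equal)
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  faces <- faces[ok, , drop = FALSE]
  list(vertices = verts, faces = faces)
}

signed_volume <- function(mesh) {
  V <- mesh$vertices; f <- mesh$faces
  p1 <- V[f[, 1], , drop = FALSE]
  p2 <- V[f[, 2], , drop = FALSE]
  p3 <- V[f[, 3], , drop = FALSE]
  sum(
    p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  ) / 6
}

#' Mesh surface area
#' @param mesh A `surface_mesh`.
#' @return Total triangle area in um^2.
#' @export
mesh_surface_area <- function(mesh) {
  V <- mesh$vertices; f <- mesh$faces
  u <- V[f[, 2], , drop = FALSE] - V[f[, 1], , drop = FALSE]
  w <- V[f[, 3], , drop = FALSE] - V[f[, 1], , drop = FALSE]
  cr <- cbind(
    u[, 2] * w[, 3] - u[, 3] * w[, 2],
    u[, 3] * w[, 1] - u[, 1] * w[, 3],
    u[, 1] * w[, 2] - u[, 2] * w[, 1]
  )
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Mesh volume (divergence theorem)
#' @param mesh A `surface_mesh` (watertight, outward-oriented).
#' @return Enclosed volume in um^3.
#' @export
mesh_volume <- function(mesh) {
  if (!mesh_is_watertight(mesh)) {
    rlang::abort("mesh is not watertight; volume undefined",
      class = "morphdmri_error_open_mesh")
  }
  abs(signed_volume(mesh))
}

#' Check mesh watertightness
#'
#' Every undirected edge must be shared by exactly two faces.
#'
#' @param mesh A `surface_mesh`.
#' @return Logical.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Euler characteristic of a mesh
#' @param mesh A `surface_mesh`.
#' @return Integer V - E + F (2 for a genus-0 closed surface).
#' @export
mesh_euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(mesh$vertices) - length(key) + nrow(f)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "<surface_mesh> %d vertices, %d faces, watertight: %s\n",
    nrow(x$vertices), nrow(x$faces), mesh_is_watertight(x)
  ))
  invisible(x)
}

#' Export a mesh to PLY, OBJ or STL
#'
#' @param mesh A `surface_mesh`.
#' @param path Output file path.
#' @param format `"ply"` (ASCII), `"ply_binary"` (binary little-endian),
#'   `"obj"` (1-based face indexing) or `"stl"` (ASCII with facet normals).
#'   Defaults to the file extension.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path,
                        format = c("auto", "ply", "ply_binary", "obj", "stl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      ply = "ply", obj = "obj", stl = "stl",
      rlang::abort("cannot infer mesh format from extension")
    )
  }
  V <- mesh$vertices; f <- mesh$faces
  if (format == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "ply", "format ascii 1.0",
      paste("element vertex", nrow(V)),
      "property float x", "property float y", "property float z",
      paste("element face", nrow(f)),
      "property list uchar int vertex_indices", "end_header"
    ), con)
    writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (format == "ply_binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(
      "ply", "format binary_little_endian 1.0",
      paste("element vertex", nrow(V)),
      "property float x", "property float y", "property float z",
      paste("element face", nrow(f)),
      "property list uchar int vertex_indices", "end_header"
    ), con)
    writeBin(as.vector(t(V)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else if (format == "obj") {
    lines <- c(
      sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
      sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
    )
    writeLines(lines, path)
  } else { # stl ascii
    u <- V[f[, 2], , drop = FALSE] - V[f[, 1], , drop = FALSE]
    w <- V[f[, 3], , drop = FALSE] - V[f[, 1], , drop = FALSE]
    nrm <- cbind(
      u[, 2] * w[, 3] - u[, 3] * w[, 2],
      u[, 3] * w[, 1] - u[, 1] * w[, 3],
      u[, 1] * w[, 2] - u[, 2] * w[, 1]
    )
    nn <- sqrt(rowSums(nrm^2)); nn[nn == 0] <- 1
    nrm <- nrm / nn
    body <- vapply(seq_len(nrow(f)), function(i) {
      paste0(
        sprintf("facet normal %.9g %.9g %.9g\n", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "outer loop\n",
        sprintf("vertex %.9g %.9g %.9g\n", V[f[i, 1], 1], V[f[i, 1], 2], V[f[i, 1], 3]),
        sprintf("vertex %.9g %.9g %.9g\n", V[f[i, 2], 1], V[f[i, 2], 2], V[f[i, 2], 3]),
        sprintf("vertex %.9g %.9g %.9g\n", V[f[i, 3], 1], V[f[i, 3], 2], V[f[i, 3], 3]),
        "endloop\nendfacet"
      )
    }, character(1))
    writeLines(c("solid mesh", body, "endsolid mesh"), path)
  }
  invisible(path)
}

#' Import a mesh written by [export_mesh()]
#'
#' Supports ASCII PLY, binary little-endian PLY and OBJ.
#'
#' @param path File path.
#' @return A `surface_mesh`.
#' @export
import_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    lines <- readLines(path)
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    V <- do.call(rbind, lapply(strsplit(vl, " +"), function(s) as.numeric(s[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, " +"), function(s) as.integer(s[2:4])))
    return(structure(list(vertices = V, faces = f, provenance = list(file = path)),
      class = "surface_mesh"))
  }
  if (ext != "ply") rlang::abort("unsupported mesh format for import")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  nv <- as.integer(sub("element vertex ", "", hdr[grepl("^element vertex", hdr)]))
  nf <- as.integer(sub("element face ", "", hdr[grepl("^element face", hdr)]))
  binary <- any(grepl("binary_little_endian", hdr))
  if (binary) {
    V <- matrix(readBin(con, numeric(), n = 3 * nv, size = 4, endian = "little"),
      ncol = 3, byrow = TRUE)
    f <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      readBin(con, raw(), n = 1)
      f[i, ] <- readBin(con, integer(), n = 3, size = 4, endian = "little") + 1L
    }
  } else {
    txt <- readLines(con)
    V <- do.call(rbind, lapply(strsplit(txt[seq_len(nv)], " +"),
      function(s) as.numeric(s[1:3])))
    f <- do.call(rbind, lapply(strsplit(txt[nv + seq_len(nf)], " +"),
      function(s) as.integer(s[2:4]) + 1L))
  }
  structure(list(vertices = V, faces = f, provenance = list(file = path)),
    class = "surface_mesh")
}
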