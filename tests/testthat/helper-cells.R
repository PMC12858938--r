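# fixture builders: all cells constructed in code

# SWC line for a dendritic node
swc_line <- function(id, x, y, z, r, parent, type = 3) {
  sprintf("%d %d %g %g %g %g %d", id, type, x, y, z, r, parent)
}

# straight cell: soma at origin plus one straight projection along +x
straight_cell <- function(n_nodes = 20, spacing = 5, soma_r = 5, r = 1) {
  lines <- sprintf("1 1 0 0 0 %g -1", soma_r)
  for (i in seq_len(n_nodes)) {
    lines <- c(lines, swc_line(i + 1, soma_r + i * spacing, 0, 0, r, i))
  }
  read_swc(lines)
}

# Y-shaped cell: trunk along +x then two daughters in the xy-plane
y_cell <- function(trunk = 50, arm_a = 40, arm_b = 30, soma_r = 1, r = 0.5,
                   spacing = 1) {
  lines <- sprintf("1 1 0 0 0 %g -1", soma_r)
  id <- 2L; prev <- 1L
  xs <- seq(soma_r + spacing, soma_r + trunk, by = spacing)
  for (x in xs) { lines <- c(lines, swc_line(id, x, 0, 0, r, prev)); prev <- id; id <- id + 1L }
  bif <- prev; x_end <- xs[length(xs)]
  prev <- bif
  for (y in seq(spacing, arm_a, by = spacing)) {
    lines <- c(lines, swc_line(id, x_end, y, 0, r, prev)); prev <- id; id <- id + 1L
  }
  prev <- bif
  for (y in seq(spacing, arm_b, by = spacing)) {
    lines <- c(lines, swc_line(id, x_end, -y, 0, r, prev)); prev <- id; id <- id + 1L
  }
  read_swc(lines)
}

# path-matrix helpers for branch-level unit tests
path_matrix <- function(x, y, z, r) {
  m <- cbind(x = x, y = y, z = z, radius = r)
  m
}

semicircle_path <- function(R = 20, r = 0.5, step_deg = 1) {
  th <- seq(0, pi, by = step_deg * pi / 180)
  path_matrix(R * cos(th), R * sin(th), 0, rep(r, length(th)))
}

helix_path <- function(a = 10, b = 2, r = 0.5, turns = 2, n = 800) {
  t <- seq(0, turns * 2 * pi, length.out = n)
  path_matrix(a * cos(t), a * sin(t), b * t, rep(r, length(t)))
}

# full binary tree cell of given bifurcation depth, unit radii
binary_tree_cell <- function(depth = 3, branch_len = 20, soma_r = 2) {
  lines <- sprintf("1 1 0 0 0 %g -1", soma_r)
  id_env <- new.env(); id_env$id <- 2L
  grow <- function(parent_id, p, dir, d) {
    n_steps <- branch_len
    prev <- parent_id
    for (i in seq_len(n_steps)) {
      q <- p + dir * i
      lines <<- c(lines, swc_line(id_env$id, q[1], q[2], q[3], 0.5, prev))
      prev <- id_env$id
      id_env$id <- id_env$id + 1L
    }
    if (d > 0) {
      end <- p + dir * n_steps
      perp <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
      perp <- perp - sum(perp * dir) * dir
      perp <- perp / sqrt(sum(perp^2))
      d1 <- (dir + perp) / sqrt(2)
      d2 <- (dir - perp) / sqrt(2)
      grow(prev, end, d1, d - 1)
      grow(prev, end, d2, d - 1)
    }
  }
  # first projection node just outside the soma
  lines <- c(lines, swc_line(2, soma_r + 1, 0, 0, 0.5, 1))
  id_env$id <- 3L
  grow(2L, c(soma_r + 1, 0, 0), c(1, 0, 0), depth)
  read_swc(lines)
}
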