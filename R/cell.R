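#' Construct a cell reconstruction from a node table
#'
#' A cell reconstruction is a rooted tree of SWC nodes: each node carries a
#' 3-D position (micrometres), a radius (micrometres, radius not diameter), an
#' integer type code (1 = soma, 2 = axon, 3 = basal dendrite, 4 = apical
#' dendrite, >= 5 custom) and a parent reference. The root is the unique node
#' with no parent; by SWC convention it is the first node of the file and
#' usually sits at the soma centre.
#'
#' @param nodes A data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (`parent` is `NA` for the root).
#' @param metadata Named list of free-form metadata (species, cell type,
#'   shrinkage, ...).
#' @param validate Check tree invariants (unique ids, existing parents, single
#'   root, acyclicity)? Default `TRUE`.
#' @return A `swc_cell` object: a tibble of nodes with metadata attached.
#' @export
swc_cell <- function(nodes, metadata = list(), validate = TRUE) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("node table lacks column(s): ", paste(missing_cols, collapse = ", ")),
      class = "morphdmri_error_columns"
    )
  }
  nodes <- tibble::as_tibble(nodes)[required]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  if (validate) {
    if (anyDuplicated(nodes$id)) {
      dup <- nodes$id[duplicated(nodes$id)]
      rlang::abort(
        paste0("duplicate node id(s): ", paste(unique(dup), collapse = ", ")),
        class = "morphdmri_error_duplicate_id"
      )
    }
    is_root <- is.na(nodes$parent)
    if (sum(is_root) != 1) {
      rlang::abort(
        paste0("expected exactly one root node, found ", sum(is_root)),
        class = "morphdmri_error_root"
      )
    }
    dangling <- setdiff(nodes$parent[!is_root], nodes$id)
    if (length(dangling) > 0) {
      rlang::abort(
        paste0("dangling parent reference(s): ", paste(dangling, collapse = ", ")),
        class = "morphdmri_error_dangling_parent"
      )
    }
    if (any(nodes$radius <= 0)) {
      rlang::abort("all radii must be positive",
        class = "morphdmri_error_radius"
      )
    }
    # cycle check: every node must reach the root
    ord <- tryCatch(topo_order(nodes), error = function(e) NULL)
    if (is.null(ord) || length(ord) != nrow(nodes)) {
      rlang::abort("node graph contains a cycle or disconnected component",
        class = "morphdmri_error_cycle"
      )
    }
    root_type <- nodes$type[is_root]
    if (root_type != 1L) {
      rlang::warn("root node is not soma-typed (type code 1)")
    }
  }
  structure(nodes,
    metadata = metadata,
    class = c("swc_cell", class(tibble::tibble()))
  )
}

#' @export
print.swc_cell <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf(
    "<swc_cell> %d nodes, root id %d, types {%s}\n",
    nrow(x), root_id(x), paste(sort(unique(x$type)), collapse = ",")
  ))
  if (length(md) > 0) {
    cat("metadata:", paste(names(md), unlist(lapply(md, format)),
      sep = "=", collapse = "; "
    ), "\n")
  }
  NextMethod()
}

#' Root node id of a cell
#' @param cell A `swc_cell`.
#' @return Integer id of the root node.
#' @export
root_id <- function(cell) {
  cell$id[is.na(cell$parent)][1]
}

#' Cell metadata
#' @param cell A `swc_cell`.
#' @return Named list of metadata.
#' @export
cell_metadata <- function(cell) {
  attr(cell, "metadata") %||% list()
}

# Topological order of node row indices (parents before children).
# Errors if the parent graph is cyclic.
topo_order <- function(nodes) {
  n <- nrow(nodes)
  idx <- stats::setNames(seq_len(n), nodes$id)
  parent_row <- ifelse(is.na(nodes$parent), NA_integer_, idx[as.character(nodes$parent)])
  children <- split(seq_len(n), factor(parent_row, levels = seq_len(n)))
  order_out <- integer(n)
  visited <- logical(n)
  root_row <- which(is.na(nodes$parent))[1]
  stack <- root_row
  k <- 0L
  while (length(stack) > 0) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (visited[cur]) stop("cycle")
    visited[cur] <- TRUE
    k <- k + 1L
    order_out[k] <- cur
    kids <- children[[cur]]
    if (length(kids) > 0) stack <- c(stack, rev(kids))
  }
  unname(order_out[seq_len(k)])
}

# row indices of children for every node, as a list indexed by row
children_index <- function(nodes) {
  n <- nrow(nodes)
  idx <- stats::setNames(seq_len(n), nodes$id)
  parent_row <- ifelse(is.na(nodes$parent), NA_integer_, idx[as.character(nodes$parent)])
  unname(split(seq_len(n), factor(parent_row, levels = seq_len(n))))
}

# all row indices in the subtree rooted at each of `rows` (inclusive)
subtree_rows <- function(nodes, rows) {
  ch <- children_index(nodes)
  out <- integer(0)
  stack <- rows
  while (length(stack) > 0) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, cur)
    stack <- c(stack, ch[[cur]])
  }
  out
}

# Euclidean distances of all nodes from a reference point
dist_from_point <- function(nodes, p) {
  sqrt((nodes$x - p[1])^2 + (nodes$y - p[2])^2 + (nodes$z - p[3])^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
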