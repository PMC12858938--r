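#' Read an SWC reconstruction
#'
#' Parses the 7-column ASCII SWC format (id, type, x, y, z, radius, parent;
#' coordinates and radii in micrometres). Lines starting with `#` and blank
#' lines are ignored; both spaces and tabs are accepted as separators; columns
#' beyond the seventh are ignored with a warning. The root is the node whose
#' parent field is -1.
#'
#' @param source Path to an SWC file, or a character vector of SWC lines.
#' @param metadata Optional named list merged into the cell's metadata.
#' @return A [swc_cell()] with the original node order recorded in
#'   `metadata$file_order`.
#' @export
read_swc <- function(source, metadata = list()) {
  lines <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (length(source) == 1 && grepl("\n", source)) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(source)
  }
  data_lines <- trimws(lines)
  data_lines <- data_lines[nzchar(data_lines) & !startsWith(data_lines, "#")]
  if (length(data_lines) == 0) {
    rlang::abort("no data lines in SWC input", class = "morphdmri_error_empty")
  }
  fields <- strsplit(data_lines, "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 7)) {
    rlang::abort(
      paste0("SWC line(s) with fewer than 7 columns: ",
        paste(which(ncols < 7), collapse = ", ")),
      class = "morphdmri_error_columns"
    )
  }
  if (any(ncols > 7)) {
    rlang::warn("SWC lines carry more than 7 columns; extras ignored")
  }
  mat <- vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[1:7]))
    v
  }, numeric(7))
  if (anyNA(mat)) {
    bad <- which(apply(mat, 2, anyNA))
    rlang::abort(
      paste0("non-numeric field on SWC data line(s): ", paste(bad, collapse = ", ")),
      class = "morphdmri_error_nonnumeric"
    )
  }
  nodes <- tibble::tibble(
    id = as.integer(mat[1, ]),
    type = as.integer(mat[2, ]),
    x = mat[3, ], y = mat[4, ], z = mat[5, ],
    radius = mat[6, ],
    parent = as.integer(mat[7, ])
  )
  nodes$parent[nodes$parent < 0] <- NA_integer_
  md <- utils::modifyList(list(file_order = nodes$id), metadata)
  swc_cell(nodes, metadata = md)
}

#' Write a cell to SWC text
#'
#' Nodes are renumbered 1..N in parent-before-child order; coordinates and
#' radii are written with 9 significant digits so a read/write round trip
#' preserves them to well beyond 6 significant digits.
#'
#' @param cell A `swc_cell`.
#' @param path Optional file path; when `NULL` the SWC text is returned as a
#'   character vector of lines.
#' @return Invisibly the SWC lines (also written to `path` when given).
#' @export
write_swc <- function(cell, path = NULL) {
  ord <- topo_order(cell)
  nodes <- cell[ord, ]
  new_id <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  parent_out <- ifelse(is.na(nodes$parent), -1L, new_id[as.character(nodes$parent)])
  fmt <- function(v) formatC(v, digits = 9, format = "g", width = 1)
  out <- sprintf(
    "%d %d %s %s %s %s %d",
    seq_len(nrow(nodes)), nodes$type,
    fmt(nodes$x), fmt(nodes$y), fmt(nodes$z), fmt(nodes$radius),
    parent_out
  )
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Remove axonal subtrees
#'
#' Axonal reconstructions in public repositories are frequently absent or
#' truncated, so axons (SWC type code 2) and all their descendants are removed
#' before morphometry; statistics then describe dendritic projections only.
#'
#' @param cell A `swc_cell`.
#' @return A list with `cell` (the stripped reconstruction) and
#'   `n_nodes_removed`.
#' @export
strip_axon <- function(cell) {
  axon_rows <- which(cell$type == 2L)
  if (length(axon_rows) == 0) {
    return(list(cell = cell, n_nodes_removed = 0L))
  }
  drop <- unique(subtree_rows(cell, axon_rows))
  kept <- cell[-drop, ]
  # parents inside the dropped set would dangle; reattach is not meaningful for
  # axon-rooted subtrees (their descendants are dropped wholesale)
  out <- swc_cell(kept, metadata = cell_metadata(cell))
  if (sum(!is.na(out$parent)) == 0 && nrow(out) <= 1) {
    rlang::warn("axon removal left only the root node")
  }
  list(cell = out, n_nodes_removed = length(drop))
}

#' Remove dendritic spines
#'
#' Spines (micron-scale protrusions) bias branch statistics: they shorten
#' apparent branch length and inflate branch order. A terminal side branch is
#' treated as a spine when its total path length and mean radius are both
#' small and it attaches to a non-terminal dendritic node. Nodes carrying an
#' explicit spine type code are always removed.
#'
#' @param cell A `swc_cell`.
#' @param max_spine_length Maximum spine path length in micrometres (default 3).
#' @param max_spine_radius Maximum mean spine radius in micrometres (default 0.3).
#' @param spine_type_codes Integer type codes always treated as spines
#'   (default: `metadata$spine_type_codes`, else none).
#' @return List with `cell` and `n_spines_removed`.
#' @export
strip_spines <- function(cell, max_spine_length = 3, max_spine_radius = 0.3,
                         spine_type_codes = NULL) {
  if (is.null(spine_type_codes)) {
    spine_type_codes <- cell_metadata(cell)$spine_type_codes
  }
  ch <- children_index(cell)
  n_child <- lengths(ch)
  is_leaf <- n_child == 0L
  idx <- stats::setNames(seq_len(nrow(cell)), cell$id)
  parent_row <- ifelse(is.na(cell$parent), NA_integer_,
    idx[as.character(cell$parent)]
  )
  seg_len <- ifelse(is.na(parent_row), 0,
    sqrt((cell$x - cell$x[parent_row])^2 +
      (cell$y - cell$y[parent_row])^2 +
      (cell$z - cell$z[parent_row])^2)
  )

  drop <- integer(0)
  n_spines <- 0L
  # candidate attachment points: non-terminal nodes with >1 child (side branch)
  # or nodes whose subtree continues past the side branch
  for (row in which(n_child >= 2L)) {
    for (kid in ch[[row]]) {
      sub <- subtree_rows(cell, kid)
      if (any(n_child[sub] >= 2L)) next # branched side structure, not a spine
      path_len <- sum(seg_len[sub])
      mean_r <- mean(cell$radius[sub])
      typed_spine <- !is.null(spine_type_codes) && all(cell$type[sub] %in% spine_type_codes)
      if (typed_spine ||
        (path_len <= max_spine_length && mean_r <= max_spine_radius)) {
        # must be a side branch: the attachment keeps at least one other child
        others <- setdiff(ch[[row]], kid)
        if (length(others) >= 1) {
          drop <- c(drop, sub)
          n_spines <- n_spines + 1L
        }
      }
    }
  }
  # explicitly typed spine subtrees anywhere
  if (!is.null(spine_type_codes)) {
    typed_rows <- which(cell$type %in% spine_type_codes)
    typed_rows <- setdiff(typed_rows, drop)
    if (length(typed_rows) > 0) {
      roots <- typed_rows[!(parent_row[typed_rows] %in% typed_rows)]
      for (r in roots) {
        sub <- subtree_rows(cell, r)
        drop <- c(drop, sub)
        n_spines <- n_spines + 1L
      }
    }
  }
  drop <- unique(drop)
  if (length(drop) == 0) {
    return(list(cell = cell, n_spines_removed = 0L))
  }
  out <- swc_cell(cell[-drop, ], metadata = cell_metadata(cell))
  list(cell = out, n_spines_removed = n_spines)
}

#' Validate a cell reconstruction
#'
#' Checks mirror the inclusion / quality-control rules used for public
#' reconstructions: the node graph must be a connected tree with positive
#' radii; the reconstruction must be genuinely 3-D (non-zero variance on all
#' three axes); and a constant dendritic radius (a nominal fixed diameter
#' rather than a measured one) is flagged.
#'
#' @param cell A `swc_cell` (constructed leniently if needed).
#' @return A `validation_report` list: `passed`, `issues` (tibble of code,
#'   message, node ids), `constant_radius_flag`.
#' @export
validate_cell <- function(cell) {
  issues <- list()
  add_issue <- function(code, message, ids = integer(0), fatal = TRUE) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      code = code, message = message,
      node_ids = list(as.integer(ids)), fatal = fatal
    )
  }
  if (any(cell$radius <= 0)) {
    add_issue("nonpositive_radius", "node radii must be positive",
      cell$id[cell$radius <= 0])
  }
  ord <- tryCatch(topo_order(cell), error = function(e) NULL)
  if (is.null(ord) || length(ord) != nrow(cell)) {
    add_issue("not_a_tree", "node graph is not a connected acyclic tree")
  }
  vars <- c(stats::var(cell$x), stats::var(cell$y), stats::var(cell$z))
  if (nrow(cell) > 1 && any(vars < 1e-12)) {
    add_issue("not_3d",
      paste0("zero variance on axis ", paste(c("x", "y", "z")[vars < 1e-12],
        collapse = ",")),
      fatal = TRUE
    )
  }
  dend <- cell$radius[cell$type %in% c(3L, 4L)]
  constant_radius <- length(dend) > 1 && max(dend) - min(dend) < 1e-12
  if (constant_radius) {
    add_issue("constant_radius",
      "all dendritic radii identical (nominal fixed diameter suspected)",
      fatal = FALSE
    )
  }
  issues_tbl <- if (length(issues) > 0) dplyr::bind_rows(issues) else
    tibble::tibble(code = character(), message = character(),
      node_ids = list(), fatal = logical())
  structure(
    list(
      passed = !any(issues_tbl$fatal),
      issues = issues_tbl,
      constant_radius_flag = constant_radius
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> passed: %s; %d issue(s); constant radius: %s\n",
    x$passed, nrow(x$issues), x$constant_radius_flag
  ))
  if (nrow(x$issues) > 0) print(x$issues[, c("code", "message", "fatal")])
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report A `validation_report`.
#' @return A JSON string.
#' @export
validation_report_json <- function(report) {
  jsonlite::toJSON(
    list(
      passed = report$passed,
      constant_radius_flag = report$constant_radius_flag,
      issues = lapply(seq_len(nrow(report$issues)), function(i) {
        list(
          code = report$issues$code[i],
          message = report$issues$message[i],
          node_ids = report$issues$node_ids[[i]],
          fatal = report$issues$fatal[i]
        )
      })
    ),
    auto_unbox = TRUE
  )
}
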