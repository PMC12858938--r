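#' Analyze one cell end to end
#'
#' Strips axons and spines, computes the structural and shape descriptor
#' records, and returns them as a single one-row tibble.
#'
#' @param cell A `swc_cell`.
#' @param strip Strip axons and spines first? Default `TRUE`.
#' @param ... Passed to [cell_morphometry()].
#' @return One-row tibble of all cell-level structural and shape descriptors.
#' @export
analyze_cell <- function(cell, strip = TRUE, ...) {
  if (strip) {
    cell <- strip_axon(cell)$cell
    cell <- strip_spines(cell)$cell
  }
  dplyr::bind_cols(
    glance(cell_morphometry(cell, ...)),
    glance(cell_shape(cell))
  )
}

#' Quartile summary of descriptor records by group
#'
#' First, second and third quartiles (linear-interpolation quantiles) of each
#' feature per group; missing values are excluded with counts retained.
#'
#' @param records Tibble of per-cell descriptor rows (e.g. from
#'   [analyze_cell()]), with optional grouping columns.
#' @param grouping Character vector of grouping column names (default none).
#' @param features Feature columns to summarize (default: all numeric
#'   non-grouping columns).
#' @return Tibble with `feature`, grouping columns, `Q1`, `median`, `Q3`,
#'   `n` (non-missing count).
#' @export
summarize_population <- function(records, grouping = character(0),
                                 features = NULL) {
  num_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  features <- features %||% setdiff(num_cols, grouping)
  records |>
    tidyr::pivot_longer(dplyr::all_of(features),
      names_to = "feature", values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("feature", grouping)))) |>
    dplyr::summarise(
      Q1 = stats::quantile(value, 0.25, na.rm = TRUE, type = 7, names = FALSE),
      median = stats::quantile(value, 0.50, na.rm = TRUE, type = 7, names = FALSE),
      Q3 = stats::quantile(value, 0.75, na.rm = TRUE, type = 7, names = FALSE),
      n = sum(!is.na(value)),
      .groups = "drop"
    )
}

#' Spearman correlation matrix with Bonferroni correction
#'
#' Rank correlation (average ranks for ties) between all feature pairs, with
#' raw and Bonferroni-adjusted p-values (family = all off-diagonal pairs).
#'
#' @param records Tibble of per-cell descriptor rows.
#' @param features Feature columns (default all numeric).
#' @return A `correlation_matrix` list: `rho`, `p`, `p_adj` (matrices),
#'   `n` (pairwise complete counts), `m` (number of tested pairs).
#' @export
spearman_matrix <- function(records, features = NULL) {
  num_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  features <- features %||% num_cols
  X <- as.data.frame(records[features])
  k <- length(features)
  rho <- diag(1, k); p <- matrix(NA_real_, k, k); n <- matrix(0L, k, k)
  dimnames(rho) <- dimnames(p) <- dimnames(n) <- list(features, features)
  diag(p) <- 0
  for (i in seq_len(k)) {
    n[i, i] <- sum(!is.na(X[[i]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- stats::complete.cases(X[[i]], X[[j]])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) >= 3 && stats::sd(X[[i]][ok]) > 0 && stats::sd(X[[j]][ok]) > 0) {
        ct <- suppressWarnings(
          stats::cor.test(X[[i]][ok], X[[j]][ok], method = "spearman")
        )
        rho[i, j] <- rho[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  m <- k * (k - 1) / 2
  p_adj <- pmin(p * m, 1)
  diag(p_adj) <- 0
  structure(list(rho = rho, p = p, p_adj = p_adj, n = n, m = m),
    class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d features, %d tested pairs\n",
    nrow(x$rho), x$m))
  print(round(x$rho, 3))
  invisible(x)
}

#' Tidy a correlation matrix into one row per pair
#' @param x A `correlation_matrix`.
#' @param ... Unused.
#' @return Tibble with `feature1`, `feature2`, `rho`, `p`, `p_adj`, `n`.
#' @method tidy correlation_matrix
#' @export
tidy.correlation_matrix <- function(x, ...) {
  k <- nrow(x$rho)
  fs <- rownames(x$rho)
  pairs <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    feature1 = fs[pairs[, 1]], feature2 = fs[pairs[, 2]],
    rho = x$rho[pairs], p = x$p[pairs], p_adj = x$p_adj[pairs],
    n = x$n[pairs]
  )
}

#' Batch-analyze a directory (or list) of SWC files
#'
#' @param paths Character vector of SWC file paths, or a directory.
#' @param ... Passed to [analyze_cell()].
#' @return Tibble with one row per cell, first column `file`.
#' @export
batch_analyze <- function(paths, ...) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.swc$", full.names = TRUE,
      ignore.case = TRUE)
  }
  purrr::map_dfr(paths, function(p) {
    dplyr::bind_cols(tibble::tibble(file = basename(p)),
      analyze_cell(read_swc(p), ...))
  })
}
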