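#' Euclidean distance between two points
#'
#' @param p,q Finite numeric 2-vectors.
#' @return The non-negative scalar `sqrt((q1 - p1)^2 + (q2 - p2)^2)`.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(p, q) {
  if (!is.numeric(p) || !is.numeric(q) || length(p) != 2L || length(q) != 2L ||
      !all(is.finite(p)) || !all(is.finite(q))) {
    stop_value("`p` and `q` must be finite numeric 2-vectors")
  }
  sqrt((q[1] - p[1])^2 + (q[2] - p[2])^2)
}

check_cell_columns <- function(tab, cols, what) {
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0L) {
    stop_schema(sprintf("%s table is missing column(s): %s",
                        what, paste(missing, collapse = ", ")))
  }
  invisible(tab)
}

#' k nearest reference cells for every spatial cell
#'
#' Exact brute-force k-nearest-neighbour search in the shared 2-D embedding
#' `(e1, e2)`. Ties at rank k are broken by reference table order (stable
#' sort), so results are reproducible for a fixed reference ordering.
#'
#' @param spatial Spatial cell table with columns `cell_id`, `e1`, `e2`.
#' @param reference Reference cell table with columns `cell_id`,
#'   `cluster_label`, `e1`, `e2`.
#' @param k Number of neighbours (default 10, the usual label-transfer
#'   choice); must not exceed the number of reference cells.
#' @return A tibble with one row per (spatial cell, rank): `cell_id`,
#'   `neighbor_rank`, `ref_cell_id`, `ref_label`, `distance`, ascending in
#'   distance within each spatial cell.
#' @export
k_nearest <- function(spatial, reference, k = 10L) {
  k <- check_count(k, "k", min = 1L)
  check_cell_columns(spatial, c("cell_id", "e1", "e2"), "spatial")
  check_cell_columns(reference, c("cell_id", "cluster_label", "e1", "e2"),
                     "reference")
  if (nrow(spatial) == 0L || nrow(reference) == 0L) {
    stop_value("both tables must be non-empty")
  }
  if (k > nrow(reference)) {
    stop_value(sprintf("k (%d) exceeds the number of reference cells (%d)",
                       k, nrow(reference)))
  }
  rx <- reference$e1
  ry <- reference$e2
  n_sp <- nrow(spatial)
  idx_mat <- matrix(0L, nrow = n_sp, ncol = k)
  dist_mat <- matrix(0, nrow = n_sp, ncol = k)
  for (i in seq_len(n_sp)) {
    d2 <- (rx - spatial$e1[i])^2 + (ry - spatial$e2[i])^2
    ord <- order(d2)[seq_len(k)] # order() is stable: ties keep table order
    idx_mat[i, ] <- ord
    dist_mat[i, ] <- sqrt(d2[ord])
  }
  tibble::tibble(
    cell_id = rep(spatial$cell_id, each = k),
    neighbor_rank = rep(seq_len(k), times = n_sp),
    ref_cell_id = reference$cell_id[as.vector(t(idx_mat))],
    ref_label = reference$cluster_label[as.vector(t(idx_mat))],
    distance = as.vector(t(dist_mat))
  )
}

#' Transfer cluster labels from a reference to spatial cells
#'
#' Assigns each spatial cell the most frequent cluster label among its k
#' nearest reference cells in the shared embedding. Vote ties are broken in
#' favour of the tied label with the smaller summed neighbour distance, then
#' lexicographically — a deterministic rule that favours the geometrically
#' closer class.
#'
#' @inheritParams k_nearest
#' @return The `spatial` table with an `assigned_label` column appended; the
#'   input is not modified.
#' @examples
#' cfg <- default_synth_config(seed = 3)
#' ref <- generate_reference(cfg, "PAD", "PAD_1")
#' sp <- generate_spatial(cfg, "PAD", "PAD_1")
#' sp <- transfer_labels(sp, ref, k = 10)
#' mean(sp$assigned_label == sp$true_label)
#' @export
transfer_labels <- function(spatial, reference, k = 10L) {
  nn <- k_nearest(spatial, reference, k = k)
  votes <- nn |>
    dplyr::group_by(.data$cell_id, .data$ref_label) |>
    dplyr::summarise(n_votes = dplyr::n(),
                     sum_dist = sum(.data$distance), .groups = "drop_last") |>
    dplyr::arrange(dplyr::desc(.data$n_votes), .data$sum_dist,
                   .data$ref_label, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  out <- spatial
  out$assigned_label <- votes$ref_label[match(out$cell_id, votes$cell_id)]
  out
}
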