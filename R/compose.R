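#' Cluster composition per condition
#'
#' Summarises how the cell-type makeup differs between conditions. By default
#' proportions are computed within each sample (count of cells in a cluster
#' divided by the sample's total) and then summarised per condition as mean
#' +/- s.e.m. across samples, as in stacked per-patient bar plots. With
#' `by_sample = FALSE` proportions are instead computed on condition-pooled
#' counts (cells in a cluster divided by all cells of the condition).
#'
#' Clusters absent from a sample (or condition) contribute an explicit zero
#' row, so proportions always sum to 1 per grouping unit and cluster sets are
#' comparable across samples.
#'
#' @param cells Cell table with columns `sample_id`, `condition` and the
#'   label column.
#' @param label_column Name of the cluster label column (default
#'   `"cluster_label"`).
#' @param by_sample If `TRUE` (default), per-sample proportions with condition
#'   mean and s.e.m.; if `FALSE`, pooled per-condition proportions.
#' @param keep_labels Optional character vector restricting (and ordering) the
#'   clusters counted; cells with other labels are dropped from both
#'   numerator and denominator.
#' @return A `composition_table` list with tibbles `per_sample`
#'   (`sample_id`, `condition`, `cluster`, `count`, `total`, `proportion`;
#'   `NULL` when `by_sample = FALSE`) and `per_condition` (pooled `count`,
#'   `total`, `proportion`, and with `by_sample = TRUE` also `mean_proportion`
#'   and `sem_proportion` across samples).
#' @examples
#' cfg <- default_synth_config(seed = 2)
#' ref <- generate_cohort(cfg)$reference
#' composition(ref)$per_condition
#' @export
composition <- function(cells, label_column = "cluster_label",
                        by_sample = TRUE, keep_labels = NULL) {
  check_cell_columns(cells, c("sample_id", "condition", label_column), "cell")
  if (nrow(cells) == 0L) {
    stop_analysis("cell table is empty")
  }
  cells$cluster <- cells[[label_column]]
  if (!is.null(keep_labels)) {
    cells <- cells[cells$cluster %in% keep_labels, ]
    if (nrow(cells) == 0L) {
      stop_analysis("no cells left after filtering to `keep_labels`")
    }
  }
  all_clusters <- keep_labels %||% sort(unique(cells$cluster))

  pooled <- cells |>
    dplyr::count(.data$condition, .data$cluster, name = "count") |>
    tidyr::complete(.data$condition, cluster = all_clusters,
                    fill = list(count = 0L)) |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(total = sum(.data$count),
                  proportion = .data$count / .data$total) |>
    dplyr::ungroup()

  if (!by_sample) {
    return(structure(list(per_sample = NULL, per_condition = pooled),
                     class = "composition_table"))
  }

  per_sample <- cells |>
    dplyr::count(.data$condition, .data$sample_id, .data$cluster,
                 name = "count") |>
    tidyr::complete(tidyr::nesting(!!rlang::sym("condition"),
                                   !!rlang::sym("sample_id")),
                    cluster = all_clusters, fill = list(count = 0L)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(total = sum(.data$count),
                  proportion = .data$count / .data$total) |>
    dplyr::ungroup()

  summary <- per_sample |>
    dplyr::group_by(.data$condition, .data$cluster) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_proportion = mean(.data$proportion),
      sem_proportion = sd(.data$proportion) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  per_condition <- dplyr::left_join(pooled, summary,
                                    by = c("condition", "cluster"))
  structure(list(per_sample = per_sample, per_condition = per_condition),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("Cluster composition per condition:\n")
  print(x$per_condition, ...)
  invisible(x)
}

#' Fraction of a gene set that changed
#'
#' Given the identifiers of changed genes (e.g. differentially expressed
#' between conditions) and a curated gene set (e.g. the core matrisome — the
#' genes encoding structural extracellular-matrix components), reports how
#' much of the set changed: `n_changed = |changed ∩ set|` over
#' `n_total = |set|`, as a percentage rounded half-away-from-zero to one
#' decimal. Both inputs are treated as sets (duplicates ignored).
#'
#' @param changed_ids Character vector of changed gene identifiers.
#' @param geneset_ids Non-empty character vector of gene-set identifiers.
#' @return A list with `n_changed`, `n_total` and `fraction` (percentage,
#'   one decimal).
#' @examples
#' change_fraction(paste0("g", 1:32), paste0("g", 1:274))
#' @export
change_fraction <- function(changed_ids, geneset_ids) {
  geneset <- unique(as.character(geneset_ids))
  geneset <- geneset[!is.na(geneset) & nzchar(geneset)]
  if (length(geneset) == 0L) {
    stop_value("`geneset_ids` must be non-empty")
  }
  changed <- unique(as.character(changed_ids))
  n_changed <- length(intersect(changed, geneset))
  n_total <- length(geneset)
  list(
    n_changed = n_changed,
    n_total = n_total,
    fraction = round_half_away(100 * n_changed / n_total, 1L)
  )
}
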