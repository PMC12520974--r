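#' Nearest target cell for every query cell
#'
#' For each query cell (e.g. a tissue-resident macrophage), finds the single
#' nearest target cell (e.g. an endothelial cell of any subtype) by Euclidean
#' distance in the tissue coordinates `(sx, sy)`, within each sample — never
#' across samples. Exact ties go to the target cell that appears earlier in
#' the table.
#'
#' @param spatial Labelled spatial cell table with columns `cell_id`,
#'   `sample_id`, `sx`, `sy` and the label column.
#' @param query_label Cluster label of the query cell type.
#' @param target_labels Character vector of target subtype labels.
#' @param label_column Which label column to use: `"assigned_label"` (after
#'   transfer, the default) or `"true_label"` (synthetic ground truth).
#' @return A tibble with one row per query cell: `cell_id`, `sample_id`
#'   (and `condition` if present in `spatial`), `target_cell_id`,
#'   `target_subtype`, `distance` (micrometres).
#' @export
nearest_target <- function(spatial, query_label, target_labels,
                           label_column = c("assigned_label", "true_label")) {
  label_column <- match.arg(label_column)
  check_cell_columns(spatial, c("cell_id", "sample_id", "sx", "sy", label_column),
                     "spatial")
  if (length(target_labels) == 0L) {
    stop_value("`target_labels` must be non-empty")
  }
  labels <- spatial[[label_column]]
  has_condition <- "condition" %in% names(spatial)

  out <- lapply(split(seq_len(nrow(spatial)), spatial$sample_id), function(rows) {
    lab <- labels[rows]
    q <- rows[lab == query_label]
    tg <- rows[lab %in% target_labels]
    if (length(q) == 0L) {
      return(NULL)
    }
    if (length(tg) == 0L) {
      stop_analysis(sprintf(
        "sample '%s' has %d query cells but no target cells",
        spatial$sample_id[rows[1]], length(q)))
    }
    # all-pairs squared distances, first-minimum per query row (stable ties)
    d2 <- outer(spatial$sx[q], spatial$sx[tg], "-")^2 +
      outer(spatial$sy[q], spatial$sy[tg], "-")^2
    j <- max.col(-d2, ties.method = "first")
    hit <- tg[j]
    res <- tibble::tibble(
      cell_id = spatial$cell_id[q],
      sample_id = spatial$sample_id[q],
      target_cell_id = spatial$cell_id[hit],
      target_subtype = labels[hit],
      distance = sqrt(d2[cbind(seq_along(q), j)])
    )
    if (has_condition) {
      res$condition <- spatial$condition[q]
    }
    res
  })
  dplyr::bind_rows(out)
}

#' Expected nearest-target proportions under the chance model
#'
#' The chance (null) model for the proximity score: if query cells took no
#' notice of target subtype, the probability that a query cell's nearest
#' target belongs to subtype s would be s's share of all target cells in the
#' same sample. These shares are the `p0` of the binomial null and sum to 1
#' within each sample.
#'
#' @inheritParams nearest_target
#' @return A tibble per (sample, subtype): `sample_id`, `target_subtype`,
#'   `n_targets`, `p0`.
#' @export
expected_proportions <- function(spatial, target_labels,
                                 label_column = c("assigned_label", "true_label")) {
  label_column <- match.arg(label_column)
  check_cell_columns(spatial, c("sample_id", label_column), "spatial")
  if (length(target_labels) == 0L) {
    stop_value("`target_labels` must be non-empty")
  }
  labels <- spatial[[label_column]]
  tg <- spatial[labels %in% target_labels, ]
  if (nrow(tg) == 0L) {
    stop_analysis("no target cells found for the given target_labels")
  }
  tg$target_subtype <- tg[[label_column]]
  counts <- tg |>
    dplyr::count(.data$sample_id, .data$target_subtype, name = "n_targets") |>
    tidyr::complete(.data$sample_id,
                    target_subtype = target_labels,
                    fill = list(n_targets = 0L))
  counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(p0 = .data$n_targets / sum(.data$n_targets)) |>
    dplyr::ungroup()
}

#' Exact one-tailed binomial p-value (upper tail)
#'
#' `P(X >= observed)` for `X ~ Binomial(n, p0)` — the enrichment direction of
#' the observed-versus-expected proximity test. `observed = 0` gives 1
#' (the whole support).
#'
#' @param observed Integer count of successes, `0 <= observed <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability in `[0, 1]`.
#' @return The exact upper-tail p-value.
#' @examples
#' binomial_upper_tail(5, 10, 0.5)  # 0.623046875
#' binomial_upper_tail(10, 10, 0.5) # 2^-10
#' @export
binomial_upper_tail <- function(observed, n, p0) {
  observed <- check_count(observed, "observed")
  n <- check_count(n, "n")
  check_scalar_number(p0, "p0")
  if (observed > n) {
    stop_value(sprintf("observed (%d) exceeds n (%d)", observed, n))
  }
  if (p0 < 0 || p0 > 1) {
    stop_value("`p0` must be in [0, 1]")
  }
  if (observed == 0L) {
    return(1)
  }
  pbinom(observed - 1L, size = n, prob = p0, lower.tail = FALSE)
}

#' Proximity scores with a one-tailed binomial test
#'
#' The proximity score of a query cell type to a target subtype is the ratio
#' of observed to expected query cells whose nearest target cell belongs to
#' that subtype; a score above 1 means the query cells sit closer to that
#' subtype than expected by chance. Scores are computed per sample and
#' summarised per condition as mean +/- s.e.m. across samples. The
#' significance test pools observed counts and trials across each condition's
#' samples (with a count-weighted pooled `p0`) and evaluates the exact
#' one-tailed binomial upper tail — one p-value per (condition, subtype).
#' With `test_scope = "per-sample"` the test is instead applied to every
#' sample separately.
#'
#' @param assignments Output of [nearest_target()].
#' @param p0 Output of [expected_proportions()] on the same samples.
#' @param sample_conditions Optional tibble (`sample_id`, `condition`) mapping
#'   samples to conditions; not needed when `assignments` carries a
#'   `condition` column.
#' @param test_scope `"pooled"` (default) or `"per-sample"`.
#' @param alternative `"enrichment"` (upper tail, default) or `"depletion"`
#'   (lower tail).
#' @param adjust Multiple-testing adjustment across subtypes within a
#'   condition: `"none"` (default, raw binomial p-values) or `"bonferroni"`.
#' @param max_distance Optional distance cap in micrometres: assignments
#'   farther than this are dropped before counting (default `Inf`, i.e. the
#'   unconditional nearest target).
#' @return A `proximity_result` list with tibbles `per_sample` (observed,
#'   expected, score per sample and subtype) and `per_condition` (pooled
#'   counts, pooled score, p-value, mean and s.e.m. of per-sample scores).
#' @export
proximity_scores <- function(assignments, p0, sample_conditions = NULL,
                             test_scope = c("pooled", "per-sample"),
                             alternative = c("enrichment", "depletion"),
                             adjust = c("none", "bonferroni"),
                             max_distance = Inf) {
  test_scope <- match.arg(test_scope)
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  check_cell_columns(assignments, c("cell_id", "sample_id", "target_subtype",
                                    "distance"), "assignments")
  check_cell_columns(p0, c("sample_id", "target_subtype", "p0"), "p0")

  if (is.finite(max_distance)) {
    assignments <- assignments[assignments$distance <= max_distance, ]
  }
  if (nrow(assignments) == 0L) {
    stop_analysis("no assignments to score (all filtered out?)")
  }
  cond_map <- resolve_conditions(assignments, sample_conditions)

  n_query <- assignments |>
    dplyr::count(.data$sample_id, name = "n_query")
  observed <- assignments |>
    dplyr::count(.data$sample_id, .data$target_subtype, name = "observed")

  per_sample <- p0 |>
    dplyr::select("sample_id", "target_subtype", "p0") |>
    dplyr::left_join(observed, by = c("sample_id", "target_subtype")) |>
    dplyr::inner_join(n_query, by = "sample_id") |>
    dplyr::mutate(
      observed = dplyr::coalesce(.data$observed, 0L),
      expected = .data$n_query * .data$p0,
      score = dplyr::if_else(.data$expected > 0,
                             .data$observed / .data$expected,
                             NA_real_)
    ) |>
    dplyr::left_join(cond_map, by = "sample_id") |>
    dplyr::relocate("condition", .after = "sample_id") |>
    dplyr::arrange(.data$condition, .data$sample_id, .data$target_subtype)

  if (anyNA(per_sample$score)) {
    warn("score undefined (expected = 0) for some (sample, subtype); emitted as NA")
  }

  lower_tail <- alternative == "depletion"
  binom_p <- function(obs, n, prob) {
    if (lower_tail) {
      pbinom(obs, size = n, prob = prob)
    } else {
      binomial_upper_tail(obs, n, prob)
    }
  }

  if (test_scope == "per-sample") {
    per_sample$p_value <- mapply(binom_p, per_sample$observed,
                                 per_sample$n_query, per_sample$p0)
  }

  per_condition <- per_sample |>
    dplyr::group_by(.data$condition, .data$target_subtype) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      pooled_observed = sum(.data$observed),
      pooled_n = sum(.data$n_query),
      pooled_p0 = sum(.data$n_query * .data$p0) / sum(.data$n_query),
      condition_mean_score = mean(.data$score, na.rm = TRUE),
      condition_sem_score = sd(.data$score, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$score))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pooled_score = dplyr::if_else(.data$pooled_p0 > 0,
                                    .data$pooled_observed /
                                      (.data$pooled_n * .data$pooled_p0),
                                    NA_real_),
      p_value = mapply(binom_p, .data$pooled_observed, .data$pooled_n,
                       .data$pooled_p0)
    )
  if (adjust == "bonferroni") {
    per_condition <- per_condition |>
      dplyr::group_by(.data$condition) |>
      dplyr::mutate(p_value = pmin(1, .data$p_value * dplyr::n())) |>
      dplyr::ungroup()
  }

  structure(list(per_sample = per_sample, per_condition = per_condition),
            class = "proximity_result")
}

resolve_conditions <- function(assignments, sample_conditions) {
  if ("condition" %in% names(assignments)) {
    return(dplyr::distinct(assignments, .data$sample_id, .data$condition))
  }
  if (is.null(sample_conditions)) {
    stop_value(paste0("assignments carry no `condition` column; supply ",
                      "`sample_conditions`"))
  }
  check_cell_columns(sample_conditions, c("sample_id", "condition"),
                     "sample_conditions")
  dplyr::distinct(tibble::as_tibble(sample_conditions),
                  .data$sample_id, .data$condition)
}

#' @export
print.proximity_result <- function(x, ...) {
  cat("Proximity analysis:",
      nrow(x$per_sample), "(sample, subtype) rows,",
      nrow(x$per_condition), "(condition, subtype) rows\n")
  cat("\nPer condition (pooled binomial test):\n")
  print(x$per_condition, ...)
  invisible(x)
}
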