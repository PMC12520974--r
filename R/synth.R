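#' Generate a synthetic reference (scRNA-seq-like) sample
#'
#' Draws cluster memberships multinomially from the configured frequencies and
#' embedding coordinates per cluster from its isotropic Gaussian. Output is
#' deterministic given `(config$seed, condition, sample_id)`.
#'
#' @param config A [synth_config()].
#' @param condition Condition label for the sample.
#' @param sample_id Sample identifier (unique across the cohort).
#' @return A tibble with columns `cell_id`, `cluster_label`, `sample_id`,
#'   `condition`, `e1`, `e2`.
#' @examples
#' cfg <- default_synth_config(seed = 7)
#' ref <- generate_reference(cfg, "PAD", "PAD_1")
#' table(ref$cluster_label)
#' @export
generate_reference <- function(config, condition, sample_id) {
  if (!inherits(config, "synth_config")) {
    stop_config("`config` must be a synth_config object")
  }
  n <- config$n_ref_cells_per_sample
  with_stream(config$seed, c("reference", condition, sample_id), {
    tab <- draw_cells(config, n)
    tibble::tibble(
      cell_id = sprintf("%s:ref:%d", sample_id, seq_len(n)),
      cluster_label = tab$label,
      sample_id = sample_id,
      condition = condition,
      e1 = tab$e1,
      e2 = tab$e2
    )
  })
}

# Draw n cluster labels and matching embedding coordinates.
draw_cells <- function(config, n) {
  freqs <- cluster_field(config, "frequency")
  labels <- sample(names(config$clusters), n, replace = TRUE, prob = freqs)
  means <- do.call(rbind, lapply(config$clusters, `[[`, "embedding_mean"))
  sds <- cluster_field(config, "embedding_sd")
  idx <- match(labels, names(config$clusters))
  list(
    label = labels,
    e1 = rnorm(n, mean = means[idx, 1], sd = sds[idx]),
    e2 = rnorm(n, mean = means[idx, 2], sd = sds[idx])
  )
}

#' Generate a synthetic spatial sample with planted proximity structure
#'
#' Target- and other-role cells are placed uniformly on the square tissue
#' domain. Each query-role cell is, with the condition's attraction
#' probability `rho`, placed at a uniformly chosen enrichment-target cell's
#' position plus an isotropic Gaussian offset (sd `attraction_sd`), resampled
#' until it falls inside the domain (up to 1000 attempts, then clamped to the
#' boundary with a warning); otherwise it is placed uniformly. Embedding
#' coordinates are drawn from the cell's own cluster cloud exactly as in the
#' reference. `true_label` records the ground truth.
#'
#' @inheritParams generate_reference
#' @return A tibble with columns `cell_id`, `true_label`, `sample_id`,
#'   `condition`, `e1`, `e2`, `sx`, `sy` (tissue coordinates in micrometres).
#' @examples
#' cfg <- default_synth_config(seed = 7)
#' sp <- generate_spatial(cfg, "PAD", "PAD_1")
#' range(sp$sx)
#' @export
generate_spatial <- function(config, condition, sample_id) {
  if (!inherits(config, "synth_config")) {
    stop_config("`config` must be a synth_config object")
  }
  if (!condition %in% names(config$enrichment_rho)) {
    stop_config(sprintf("condition '%s' is not one of the configured conditions",
                        condition))
  }
  n <- config$n_spatial_cells_per_sample
  L <- config$domain_size
  rho <- config$enrichment_rho[[condition]]
  roles <- cluster_roles(config)

  with_stream(config$seed, c("spatial", condition, sample_id), {
    if (n == 0L) {
      return(tibble::tibble(
        cell_id = character(), true_label = character(),
        sample_id = character(), condition = character(),
        e1 = numeric(), e2 = numeric(), sx = numeric(), sy = numeric()
      ))
    }
    tab <- draw_cells(config, n)
    sx <- runif(n, 0, L)
    sy <- runif(n, 0, L)

    is_query <- roles[match(tab$label, names(config$clusters))] == "query"
    if (rho > 0 && any(is_query)) {
      anchors <- which(tab$label == config$enrichment_target)
      if (length(anchors) == 0L) {
        stop_generation(sprintf(
          "enrichment_rho > 0 but no '%s' cells were realized in sample '%s'",
          config$enrichment_target, sample_id))
      }
      qidx <- which(is_query)
      attracted <- qidx[runif(length(qidx)) < rho]
      for (i in attracted) {
        a <- anchors[sample.int(length(anchors), 1L)]
        pos <- attracted_position(sx[a], sy[a], config$attraction_sd, L)
        sx[i] <- pos[1]
        sy[i] <- pos[2]
      }
    }

    tibble::tibble(
      cell_id = sprintf("%s:sp:%d", sample_id, seq_len(n)),
      true_label = tab$label,
      sample_id = sample_id,
      condition = condition,
      e1 = tab$e1,
      e2 = tab$e2,
      sx = sx,
      sy = sy
    )
  })
}

# Gaussian offset around an anchor, rejection-resampled into [0, L]^2.
attracted_position <- function(ax, ay, sd, L, max_attempts = 1000L) {
  for (attempt in seq_len(max_attempts)) {
    x <- ax + rnorm(1L, sd = sd)
    y <- ay + rnorm(1L, sd = sd)
    if (x >= 0 && x <= L && y >= 0 && y <= L) {
      return(c(x, y))
    }
  }
  warn("attraction offset rejected 1000 times; clamping to domain boundary")
  c(min(max(x, 0), L), min(max(y, 0), L))
}

#' Generate the full two-condition cohort
#'
#' Calls [generate_reference()] and [generate_spatial()] for every
#' (condition, sample) pair of the configuration. Sample ids are
#' `<condition>_<i>`. Because random streams are derived per (stage,
#' condition, sample), regenerating any single sample reproduces the same
#' cells as the cohort call.
#'
#' @param config A [synth_config()].
#' @return A list with tibbles `reference` and `spatial` covering all samples.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop_config("`config` must be a synth_config object")
  }
  grid <- expand.grid(
    i = seq_len(config$samples_per_condition),
    condition = config$conditions,
    stringsAsFactors = FALSE
  )
  grid$sample_id <- sprintf("%s_%d", grid$condition, grid$i)
  reference <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(r) {
    generate_reference(config, grid$condition[r], grid$sample_id[r])
  }))
  spatial <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(r) {
    generate_spatial(config, grid$condition[r], grid$sample_id[r])
  }))
  list(reference = reference, spatial = spatial)
}
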