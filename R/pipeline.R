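#' Default end-to-end pipeline configuration
#'
#' Synthetic two-condition study (see [default_synth_config()]) followed by
#' label transfer with k = 10, the proximity analysis of the macrophage query
#' population against the six endothelial target subtypes (pooled binomial
#' test), and a cluster-composition summary.
#'
#' @param seed Integer root seed.
#' @param outdir Output directory for [run_pipeline()] artifacts.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1L, outdir = "proxiscore_out") {
  synth <- default_synth_config(seed = seed)
  roles <- cluster_roles(synth)
  pipeline_config(
    synthetic = synth,
    transfer = list(k = 10L),
    proximity = list(
      query_label = names(roles)[roles == "query"][1],
      target_labels = names(roles)[roles == "target"],
      label_column = "assigned_label",
      test_scope = "pooled",
      max_distance = Inf
    ),
    compose = list(pooled = FALSE),
    seed = seed,
    outdir = outdir
  )
}

#' Build a pipeline configuration
#'
#' Exactly one of `synthetic` (a [synth_config()]) or `inputs` (a list with
#' `reference` and `spatial` CSV/TSV paths) must be supplied.
#'
#' @param synthetic Optional [synth_config()] describing data to generate.
#' @param inputs Optional list with paths `reference` and `spatial`.
#' @param transfer List with `k` (default 10).
#' @param proximity List with `query_label`, `target_labels`, and optionally
#'   `label_column`, `test_scope`, `max_distance`.
#' @param compose List with `pooled` flag (default `FALSE`: per-sample
#'   proportions with condition mean/s.e.m.).
#' @param seed Integer root seed.
#' @param outdir Output directory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL,
                            transfer = list(k = 10L),
                            proximity = list(),
                            compose = list(pooled = FALSE),
                            seed = 1L, outdir = "proxiscore_out") {
  if (is.null(synthetic) == is.null(inputs)) {
    stop_config("exactly one of `synthetic` or `inputs` must be given")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synth_config")) {
    stop_config("`synthetic` must be a synth_config object")
  }
  if (!is.null(inputs)) {
    if (!is.list(inputs) || !all(c("reference", "spatial") %in% names(inputs))) {
      stop_config("`inputs` must list `reference` and `spatial` paths")
    }
    for (p in unlist(inputs[c("reference", "spatial")])) {
      if (!file.exists(p)) {
        stop_config(sprintf("input path does not exist: %s", p))
      }
    }
    if (is.null(proximity$query_label) || is.null(proximity$target_labels)) {
      stop_config("real-input runs must set proximity$query_label and $target_labels")
    }
  }
  transfer$k <- check_count(transfer$k %||% 10L, "transfer$k", min = 1L)
  proximity$label_column <- proximity$label_column %||% "assigned_label"
  proximity$test_scope <- proximity$test_scope %||% "pooled"
  proximity$max_distance <- proximity$max_distance %||% Inf
  compose$pooled <- isTRUE(compose$pooled)
  structure(
    list(synthetic = synthetic, inputs = inputs, transfer = transfer,
         proximity = proximity, compose = compose,
         seed = as.integer(seed), outdir = outdir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file mirrors [pipeline_config()]: top-level keys `synthetic` or
#' `inputs`, `transfer`, `proximity`, `compose`, `seed`, `outdir`. The
#' `synthetic` block holds the [synth_config()] fields, with `clusters` as a
#' list of objects with keys `name`, `role`, `frequency`, `embedding_mean`,
#' `embedding_sd`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_config(sprintf("config file not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  synthetic <- NULL
  if (!is.null(raw$synthetic)) {
    s <- raw$synthetic
    clusters <- lapply(s$clusters, function(cl) {
      cluster_spec(cl$name, cl$role, cl$frequency,
                   as.numeric(unlist(cl$embedding_mean)), cl$embedding_sd)
    })
    rho <- NULL
    if (!is.null(s$enrichment_rho)) {
      rho <- unlist(s$enrichment_rho)
    }
    synthetic <- synth_config(
      clusters = clusters,
      n_ref_cells_per_sample = s$n_ref_cells_per_sample %||% 2000L,
      n_spatial_cells_per_sample = s$n_spatial_cells_per_sample %||% 2000L,
      samples_per_condition = s$samples_per_condition %||% 3L,
      conditions = unlist(s$conditions) %||% c("non-ischemic", "PAD"),
      domain_size = s$domain_size %||% 1000,
      enrichment_target = s$enrichment_target,
      enrichment_rho = rho,
      attraction_sd = s$attraction_sd %||% 15,
      seed = raw$seed %||% s$seed %||% 1L
    )
  }
  proximity <- raw$proximity %||% list()
  if (!is.null(proximity$target_labels)) {
    proximity$target_labels <- unlist(proximity$target_labels)
  }
  pipeline_config(
    synthetic = synthetic,
    inputs = raw$inputs,
    transfer = raw$transfer %||% list(k = 10L),
    proximity = proximity,
    compose = raw$compose %||% list(pooled = FALSE),
    seed = raw$seed %||% 1L,
    outdir = raw$outdir %||% "proxiscore_out"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "proxiscore_stage_error")
  })
}

#' Run the full simulate/ingest -> transfer -> proximity -> compose pipeline
#'
#' Executes every stage of the analysis on either synthetic or supplied data,
#' writes all intermediate and final tables as CSV (with unit sidecars for
#' cell tables) into the configured output directory, and writes a
#' `manifest.json` echoing the configuration, the seed, package and R
#' versions and the row count of every output file.
#'
#' @param config A `pipeline_config` (or a path readable by
#'   [read_pipeline_config()]).
#' @param outdir Optional override of the configured output directory.
#' @return Invisibly, a list with the in-memory results (`reference`,
#'   `spatial`, `assignments`, `proximity`, `composition`) and the `manifest`.
#' @examples
#' \donttest{
#' cfg <- default_pipeline_config(seed = 1, outdir = tempfile())
#' res <- run_pipeline(cfg)
#' res$proximity$per_condition
#' }
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) {
    config <- read_pipeline_config(config)
  }
  if (!inherits(config, "pipeline_config")) {
    stop_config("`config` must be a pipeline_config or a config file path")
  }
  outdir <- outdir %||% config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  message("[proxiscore] stage: data")
  data <- run_stage("data", {
    if (!is.null(config$synthetic)) {
      generate_cohort(config$synthetic)
    } else {
      list(reference = read_cell_table(config$inputs$reference, "reference"),
           spatial = read_cell_table(config$inputs$spatial, "spatial"))
    }
  })

  message("[proxiscore] stage: transfer (k = ", config$transfer$k, ")")
  spatial <- run_stage("transfer", {
    transfer_labels(data$spatial, data$reference, k = config$transfer$k)
  })
  for (s in unique(spatial$sample_id)) {
    n_s <- sum(spatial$sample_id == s)
    message(sprintf("[proxiscore]   sample %s: %d cells labelled", s, n_s))
  }

  prox_cfg <- config$proximity
  if (is.null(prox_cfg$query_label)) {
    roles <- cluster_roles(config$synthetic)
    prox_cfg$query_label <- names(roles)[roles == "query"][1]
    prox_cfg$target_labels <- names(roles)[roles == "target"]
  }
  message("[proxiscore] stage: proximity (query = ", prox_cfg$query_label, ")")
  prox <- run_stage("proximity", {
    assignments <- nearest_target(spatial, prox_cfg$query_label,
                                  prox_cfg$target_labels,
                                  label_column = prox_cfg$label_column)
    p0 <- expected_proportions(spatial, prox_cfg$target_labels,
                               label_column = prox_cfg$label_column)
    result <- proximity_scores(assignments, p0,
                               test_scope = prox_cfg$test_scope,
                               max_distance = prox_cfg$max_distance)
    list(assignments = assignments, result = result)
  })

  message("[proxiscore] stage: compose")
  comp <- run_stage("compose", {
    composition(spatial, label_column = prox_cfg$label_column,
                by_sample = !config$compose$pooled)
  })

  message("[proxiscore] stage: write (", outdir, ")")
  manifest <- run_stage("write", {
    files <- list()
    wr_cell <- function(tab, name) {
      write_cell_table(tab, file.path(outdir, name))
      files[[name]] <<- nrow(tab)
    }
    wr_csv <- function(tab, name) {
      readr::write_csv(tab, file.path(outdir, name), progress = FALSE)
      files[[name]] <<- nrow(tab)
    }
    wr_cell(data$reference, "reference.csv")
    wr_cell(spatial, "spatial_labeled.csv")
    wr_csv(prox$assignments, "assignments.csv")
    wr_csv(prox$result$per_sample, "proximity_per_sample.csv")
    wr_csv(prox$result$per_condition, "proximity_per_condition.csv")
    if (!is.null(comp$per_sample)) {
      wr_csv(comp$per_sample, "composition_per_sample.csv")
    }
    wr_csv(comp$per_condition, "composition_per_condition.csv")
    manifest <- list(
      package = "proxiscore",
      version = as.character(utils::packageVersion("proxiscore")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config = config_echo(config),
      files = files
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest
  })

  invisible(list(reference = data$reference, spatial = spatial,
                 assignments = prox$assignments, proximity = prox$result,
                 composition = comp, manifest = manifest, outdir = outdir))
}

# Serializable echo of the configuration for the manifest.
config_echo <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synthetic)) {
    s <- unclass(out$synthetic)
    s$clusters <- lapply(s$clusters, unclass)
    out$synthetic <- s
  }
  out$proximity$max_distance <-
    if (is.finite(out$proximity$max_distance)) out$proximity$max_distance else "Inf"
  out
}
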