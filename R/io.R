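#' Read a reference or spatial cell table
#'
#' Reads a CSV or TSV cell table (delimiter inferred from the file
#' extension: `.tsv`/`.tab`/`.txt` are tab-separated, everything else
#' comma-separated), validates the mandatory columns for the requested
#' schema, parses coordinate columns as doubles and preserves any extra
#' columns.
#'
#' Mandatory columns — reference: `cell_id`, `cluster_label`, `sample_id`,
#' `condition`, `e1`, `e2`; spatial: `cell_id`, `sample_id`, `condition`,
#' `e1`, `e2`, `sx`, `sy` (labels `true_label`/`assigned_label` are optional
#' on read).
#'
#' @param path Path to the file.
#' @param schema `"reference"` or `"spatial"`.
#' @return A tibble.
#' @export
read_cell_table <- function(path, schema = c("reference", "spatial")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    stop_value(sprintf("file not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  reader <- if (ext %in% c("tsv", "tab", "txt")) readr::read_tsv else readr::read_csv
  tab <- reader(path, show_col_types = FALSE, progress = FALSE)

  required <- switch(schema,
    reference = c("cell_id", "cluster_label", "sample_id", "condition",
                  "e1", "e2"),
    spatial = c("cell_id", "sample_id", "condition", "e1", "e2", "sx", "sy")
  )
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop_schema(sprintf("%s table %s is missing mandatory column(s): %s",
                        schema, path, paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tab$cell_id)) {
    dups <- unique(tab$cell_id[duplicated(tab$cell_id)])
    stop_integrity(sprintf("duplicate cell_id(s) in %s: %s", path,
                           paste(head(dups, 5L), collapse = ", ")))
  }
  num_cols <- intersect(c("e1", "e2", "sx", "sy"), names(tab))
  for (col in num_cols) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  tab
}

#' Write a cell table with a units sidecar
#'
#' Writes the table as UTF-8 CSV with a header row and `.` decimal separator,
#' plus a small JSON sidecar (`<path>.meta.json`) documenting column units
#' (tissue coordinates `sx`, `sy` in micrometres; embedding coordinates
#' `e1`, `e2` in embedding units).
#'
#' @param tab The cell table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(tab, path) {
  readr::write_csv(tab, path, progress = FALSE)
  units <- list()
  if ("sx" %in% names(tab)) units$sx <- "micrometre"
  if ("sy" %in% names(tab)) units$sy <- "micrometre"
  if ("e1" %in% names(tab)) units$e1 <- "embedding unit"
  if ("e2" %in% names(tab)) units$e2 <- "embedding unit"
  meta <- list(columns = names(tab), units = units, n_rows = nrow(tab),
               encoding = "UTF-8", decimal_separator = ".")
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a gene list (one identifier per line)
#'
#' Blank lines and lines starting with `#` are skipped; surrounding
#' whitespace is trimmed.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    stop_value(sprintf("file not found: %s", path))
  }
  ids <- trimws(readLines(path, warn = FALSE))
  ids[nzchar(ids) & !startsWith(ids, "#")]
}
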