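read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

require_columns <- function(tbl, required, what) {
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop_countnet(
      sprintf("%s table is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = "countnet_schema_error"
    )
  }
  invisible(tbl)
}

#' Read a per-method differential-expression result table
#'
#' Expects a TSV with a header containing at least `gene` and `pvalue`;
#' `qvalue` and `log2fc` are optional. Extra columns are preserved untouched.
#'
#' @param path Path to the TSV file.
#' @param method_label Label for the method that produced the list; defaults
#'   to the file name without extension.
#' @return Tibble with `gene_id`, `p_value`, `q_value`, `log2_fc`, `method`
#'   plus any extra columns.
#' @export
read_de_table <- function(path, method_label = NULL) {
  tbl <- read_tsv_quiet(path)
  require_columns(tbl, c("gene", "pvalue"), "differential-expression")
  assert_prob(tbl$pvalue, "p-value")
  if ("qvalue" %in% names(tbl)) assert_prob(tbl$qvalue, "q-value")
  out <- tibble::tibble(
    gene_id = as.character(tbl$gene),
    p_value = as.numeric(tbl$pvalue),
    q_value = if ("qvalue" %in% names(tbl)) as.numeric(tbl$qvalue) else NA_real_,
    log2_fc = if ("log2fc" %in% names(tbl)) as.numeric(tbl$log2fc) else NA_real_,
    method = method_label %||% tools::file_path_sans_ext(basename(path))
  )
  extra <- setdiff(names(tbl), c("gene", "pvalue", "qvalue", "log2fc"))
  if (length(extra)) out <- dplyr::bind_cols(out, tbl[extra])
  out
}

go_categories <- c("biological_process", "molecular_function", "cellular_component")

#' Read gene-to-GO-term assignments
#'
#' Expects a TSV with columns `gene`, `term`, `category`, the category being
#' one of the three Gene Ontology namespaces.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `gene_id`, `term_id`, `category`.
#' @export
read_go_table <- function(path) {
  tbl <- read_tsv_quiet(path)
  require_columns(tbl, c("gene", "term", "category"), "GO assignment")
  bad <- setdiff(unique(tbl$category), go_categories)
  if (length(bad)) {
    stop_countnet(
      sprintf("unknown GO category: %s (expected %s)",
              paste(bad, collapse = ", "), paste(go_categories, collapse = ", ")),
      class = "countnet_validation_error"
    )
  }
  tibble::tibble(
    gene_id = as.character(tbl$gene),
    term_id = as.character(tbl$term),
    category = as.character(tbl$category)
  )
}

#' Read a transcription-factor gene list
#'
#' One gene id per line; blank lines and surrounding whitespace ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of gene ids.
#' @export
read_tf_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Write a regulatory network edge list
#'
#' TSV with columns `tf_id`, `gene_id`, `module_id`, deterministically ordered
#' (module, then TF, then gene, ascending) so identical networks produce
#' byte-identical files.
#'
#' @param edges Tibble with columns `tf_id`, `gene_id`, `module_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  require_columns(edges, c("tf_id", "gene_id", "module_id"), "edge list")
  edges <- dplyr::arrange(tibble::as_tibble(edges), .data$module_id,
                          .data$tf_id, .data$gene_id)
  readr::write_tsv(edges[c("tf_id", "gene_id", "module_id")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a regulatory network edge list written by [write_edge_list()]
#' @param path Path to the TSV file.
#' @return Tibble with `tf_id`, `gene_id`, `module_id`.
#' @export
read_edge_list <- function(path) {
  tbl <- read_tsv_quiet(path, col_types = readr::cols(
    tf_id = readr::col_character(),
    gene_id = readr::col_character(),
    module_id = readr::col_integer()
  ))
  require_columns(tbl, c("tf_id", "gene_id", "module_id"), "edge list")
  tbl
}

#' Write a mapping-statistics table
#'
#' Emits the conventional mapping-report column order: sample, total reads,
#' uniquely mapped, multi-mapped, failed, filtered, and the percentage of
#' reads mapped to the genome.
#'
#' @param stats Tibble from [mapping_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping_stats <- function(stats, path) {
  out <- stats
  names(out) <- c("sample", "# reads", "# reads mapped to unique sites",
                  "# reads mapped to multiple sites", "# reads failed to map",
                  "# filtered reads", "percentage of reads mapped to genome")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
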