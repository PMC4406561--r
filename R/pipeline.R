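pipeline_stages <- c("counts", "de", "functions", "networks")

default_config <- function() {
  list(
    stage = "networks",
    annotation = NULL,
    samples = NULL,
    de_tables = NULL,
    go_table = NULL,
    tf_list = NULL,
    out_dir = NULL,
    seed = 1L,
    count = list(rule = "total_to_each_isoform", min_mapq = 0),
    de = list(criterion = "p_value", threshold = 0.05, min_support = 3,
              assumption_fc = 2, assumption_fraction = 0.5),
    enrichment = list(alternative = "two.sided", top_n = 10, gate = TRUE),
    gnet = list(K = NULL, max_depth = 3, max_iter = 100, rel_tol = 1e-6,
                min_module_size = 2, top_n = 10)
  )
}

merge_config <- function(defaults, user, prefix = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop_countnet(
      sprintf("unknown configuration key(s): %s",
              paste0(prefix, unknown, collapse = ", ")),
      class = "countnet_configuration_error"
    )
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.data.frame(defaults[[key]]) &&
        is.list(user[[key]]) && !is.data.frame(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      prefix = paste0(prefix, key, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Accepts a JSON file path or a list, fills in defaults (threshold 0.05,
#' p-value criterion, minimum support 3, top 10 terms/modules) and rejects
#' unknown keys by name. Selecting a stage implies all earlier stages: the
#' stage order is counts, de, functions, networks.
#'
#' @param config Path to a JSON configuration file, or a list of settings.
#' @return Validated configuration list with class `countnet_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyDataFrame = TRUE)
  }
  cfg <- merge_config(default_config(), config)
  if (!cfg$stage %in% pipeline_stages) {
    stop_countnet(
      sprintf("stage must be one of: %s", paste(pipeline_stages, collapse = ", ")),
      class = "countnet_configuration_error"
    )
  }
  thr <- cfg$de$threshold
  if (!is.numeric(thr) || length(thr) != 1 || thr <= 0 || thr > 1) {
    stop_countnet("de.threshold must lie between 0 and 1",
                  class = "countnet_configuration_error")
  }
  if (!cfg$de$criterion %in% c("p_value", "q_value")) {
    stop_countnet("de.criterion must be 'p_value' or 'q_value'",
                  class = "countnet_configuration_error")
  }
  if (is.null(cfg$out_dir)) {
    stop_countnet("out_dir is required", class = "countnet_configuration_error")
  }
  if (!is.null(cfg$samples)) cfg$samples <- tibble::as_tibble(cfg$samples)
  if (!is.null(cfg$de_tables)) cfg$de_tables <- tibble::as_tibble(cfg$de_tables)
  class(cfg) <- "countnet_config"
  cfg
}

write_tsv_sorted <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Run the multi-level mining pipeline
#'
#' Executes the protocol stages in order up to the configured stage —
#' selecting a later stage automatically runs all earlier ones. Stages:
#' \enumerate{
#'   \item \strong{counts}: read SAM alignments per replicate, keep uniquely
#'     mapped reads, write mapping statistics, gene counts, RPKM and
#'     depth-normalized per-sample expression;
#'   \item \strong{de}: ingest per-method DE tables (or run the built-in
#'     binomial test), apply the p/q cut-off, vote the consensus list, and
#'     run the similar-expression suitability check;
#'   \item \strong{functions}: Fisher-exact GO term ranking of the consensus
#'     genes per ontology category, with the advisory CMH pre-check;
#'   \item \strong{networks}: module-network learning on log2 RPKM profiles
#'     of the consensus genes, skipped with a logged reason when no
#'     transcription factor is differentially expressed.
#' }
#' Every stage persists its outputs (sorted TSVs) under `out_dir` before the
#' next stage starts; with a fixed seed, re-running reproduces byte-identical
#' files.
#'
#' @param config A `countnet_config`, a list, or a JSON path (passed through
#'   [validate_config()]).
#' @return A `countnet_report` (list of per-stage summaries; see
#'   `print.countnet_report`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "countnet_config")) config else validate_config(config)
  stages <- pipeline_stages[seq_len(match(cfg$stage, pipeline_stages))]
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = cfg, stages = stages, seed = cfg$seed)

  ## stage 1: counting ------------------------------------------------------
  if (is.null(cfg$annotation) || is.null(cfg$samples)) {
    stop_countnet("counts stage requires 'annotation' and 'samples'",
                  class = "countnet_configuration_error")
  }
  annotation <- read_gtf(cfg$annotation)
  per_rep <- list()
  stats_rows <- list()
  for (i in seq_len(nrow(cfg$samples))) {
    row <- cfg$samples[i, ]
    aln <- read_sam(row$sam)
    cls <- classify_reads(aln, sample_id = row$sample,
                          min_mapq = cfg$count$min_mapq)
    stats_rows[[i]] <- cls$stats
    per_rep[[row$sample]] <- count_genes(cls$alignments, annotation,
                                         rule = cfg$count$rule)
  }
  stats <- dplyr::bind_rows(stats_rows)
  cm <- count_matrix(per_rep)
  rpkm <- compute_rpkm(cm$counts, cm$library_sizes, annotation)
  groups <- stats::setNames(cfg$samples$condition, cfg$samples$sample)
  norm <- normalize_and_average(cm$counts, cm$library_sizes, groups)
  write_mapping_stats(stats, file.path(cfg$out_dir, "mapping_stats.tsv"))
  write_tsv_sorted(cm$counts, file.path(cfg$out_dir, "gene_counts.tsv"))
  write_tsv_sorted(rpkm, file.path(cfg$out_dir, "rpkm.tsv"))
  write_tsv_sorted(norm$samples, file.path(cfg$out_dir, "expression_samples.tsv"))
  report$mapping_stats <- stats
  report$n_genes <- nrow(cm$counts)

  if (!"de" %in% stages) return(finish_report(report, cfg))

  ## stage 2: differential expression --------------------------------------
  conditions <- unique(cfg$samples$condition)
  assumption <- NULL
  if (length(conditions) == 2) {
    cond_cols <- function(cond) cfg$samples$sample[cfg$samples$condition == cond]
    assumption <- check_similar_expression_assumption(
      cm$counts, cm$library_sizes, cond_cols(conditions[1]),
      cond_cols(conditions[2]), fc_threshold = cfg$de$assumption_fc,
      max_fraction = cfg$de$assumption_fraction)
  }
  if (!is.null(cfg$de_tables) && nrow(cfg$de_tables)) {
    de_results <- purrr::pmap(cfg$de_tables, function(path, method, ...) {
      read_de_table(path, method_label = method)
    })
    names(de_results) <- cfg$de_tables$method
  } else {
    if (length(conditions) != 2) {
      stop_countnet("built-in DE test needs exactly two conditions",
                    class = "countnet_configuration_error")
    }
    cond_cols <- function(cond) cfg$samples$sample[cfg$samples$condition == cond]
    de_results <- list(
      builtin_binomial = builtin_de_test(cm$counts, cm$library_sizes,
                                         cond_cols(conditions[1]),
                                         cond_cols(conditions[2]))
    )
  }
  gene_lists <- lapply(de_results, select_de, criterion = cfg$de$criterion,
                       threshold = cfg$de$threshold)
  min_support <- min(cfg$de$min_support, length(gene_lists))
  consensus <- consensus_vote(gene_lists, min_support = min_support)
  write_tsv_sorted(consensus, file.path(cfg$out_dir, "consensus_de.tsv"))
  report$de <- list(
    per_method = tibble::tibble(method = names(gene_lists),
                                n_selected = lengths(gene_lists)),
    consensus_size = nrow(consensus),
    min_support = min_support,
    assumption = assumption
  )

  if (!"functions" %in% stages) return(finish_report(report, cfg))

  ## stage 3: function enrichment -------------------------------------------
  if (is.null(cfg$go_table)) {
    stop_countnet("functions stage requires 'go_table'",
                  class = "countnet_configuration_error")
  }
  go <- read_go_table(cfg$go_table)
  measured <- cm$counts$gene_id[rowSums(as.matrix(cm$counts[expr_columns(cm$counts)])) > 0]
  if (nrow(consensus)) {
    enr <- rank_terms(consensus$gene_id, measured, go,
                      alternative = cfg$enrichment$alternative,
                      gate = cfg$enrichment$gate)
    top <- dplyr::filter(enr, .data$rank <= cfg$enrichment$top_n)
  } else {
    enr <- top <- tibble::tibble(term_id = character(), category = character(),
                                 n_de_with_term = integer(),
                                 p_value = numeric(), rank = integer())
  }
  write_tsv_sorted(enr, file.path(cfg$out_dir, "enrichment.tsv"))
  write_tsv_sorted(top, file.path(cfg$out_dir, "enrichment_top.tsv"))
  report$enrichment <- list(top = top, n_tested = nrow(enr),
                            cmh = attr(enr, "cmh"))

  if (!"networks" %in% stages) return(finish_report(report, cfg))

  ## stage 4: regulatory module networks ------------------------------------
  if (is.null(cfg$tf_list)) {
    stop_countnet("networks stage requires 'tf_list'",
                  class = "countnet_configuration_error")
  }
  tfs <- read_tf_list(cfg$tf_list)
  usable <- tryCatch(require_tfs(consensus$gene_id, tfs),
                     countnet_no_tf_error = function(e) NULL)
  if (is.null(usable)) {
    report$network <- list(skipped = TRUE,
                           reason = "skipped: no transcription factors among the consensus genes")
  } else {
    expr <- log2_transform(rpkm[rpkm$gene_id %in%
                                  union(consensus$gene_id, usable), ])
    fit <- gnet_fit(expr, usable, K = cfg$gnet$K,
                    max_depth = cfg$gnet$max_depth,
                    max_iter = cfg$gnet$max_iter, rel_tol = cfg$gnet$rel_tol,
                    seed = cfg$seed,
                    min_module_size = cfg$gnet$min_module_size)
    edges <- export_network(fit, top_n = min(cfg$gnet$top_n,
                                             nrow(fit$modules)))
    write_tsv_sorted(fit$modules, file.path(cfg$out_dir, "modules.tsv"))
    write_tsv_sorted(tidy(fit), file.path(cfg$out_dir, "module_assignment.tsv"))
    write_edge_list(edges, file.path(cfg$out_dir, "network_edges.tsv"))
    writeLines(unlist(lapply(names(fit$trees), function(m) {
      c(sprintf("module %s:", m), format_tree(fit$trees[[m]]), "")
    })), file.path(cfg$out_dir, "module_trees.txt"))
    jsonlite::write_json(lapply(fit$trees, tree_to_list),
                         file.path(cfg$out_dir, "module_trees.json"),
                         auto_unbox = TRUE, digits = NA)
    report$network <- list(
      skipped = FALSE,
      modules = fit$modules,
      n_tf_nodes = attr(edges, "n_tf_nodes"),
      n_gene_nodes = attr(edges, "n_gene_nodes"),
      n_edges = attr(edges, "n_edges"),
      converged = fit$converged
    )
  }
  finish_report(report, cfg)
}

finish_report <- function(report, cfg) {
  class(report) <- "countnet_report"
  writeLines(format_report(report), file.path(cfg$out_dir, "report.md"))
  report
}

format_report <- function(report) {
  lines <- c("# Pipeline report", "",
             sprintf("Stages run: %s", paste(report$stages, collapse = " -> ")),
             sprintf("Seed: %s", report$seed), "")
  if (!is.null(report$mapping_stats)) {
    s <- report$mapping_stats
    lines <- c(lines, "## Mapping statistics", "",
               sprintf("- %s: %s reads, %s uniquely mapped (%.2f%% mapped)",
                       s$sample_id, format(s$n_reads, big.mark = ","),
                       format(s$n_unique, big.mark = ","), s$pct_mapped), "")
  }
  if (!is.null(report$de)) {
    lines <- c(lines, "## Differential expression", "",
               sprintf("- %s: %d genes selected", report$de$per_method$method,
                       report$de$per_method$n_selected),
               sprintf("- consensus (support >= %d): %d genes",
                       report$de$min_support, report$de$consensus_size))
    if (!is.null(report$de$assumption)) {
      a <- report$de$assumption
      lines <- c(lines, sprintf(
        "- similar-expression assumption: %s (%.1f%% of genes discordant)",
        if (a$passes) "passes" else "violated", 100 * a$fraction_discordant))
    }
    lines <- c(lines, "")
  }
  if (!is.null(report$enrichment)) {
    lines <- c(lines, "## Function enrichment", "",
               sprintf("- %d terms tested", report$enrichment$n_tested))
    if (!is.null(report$enrichment$cmh)) {
      lines <- c(lines, sprintf("- CMH pre-check p = %.4g (advisory)",
                                report$enrichment$cmh$p_value))
    }
    top <- report$enrichment$top
    if (nrow(top)) {
      lines <- c(lines, "", "| term | category | DE genes | p-value |",
                 "|---|---|---|---|",
                 sprintf("| %s | %s | %d | %.3g |", top$term_id, top$category,
                         top$n_de_with_term, top$p_value))
    }
    lines <- c(lines, "")
  }
  if (!is.null(report$network)) {
    lines <- c(lines, "## Regulatory network", "")
    if (isTRUE(report$network$skipped)) {
      lines <- c(lines, sprintf("- %s", report$network$reason), "")
    } else {
      m <- report$network$modules
      lines <- c(lines,
                 sprintf("- %d modules; %d TF nodes, %d gene nodes, %d edges",
                         nrow(m), report$network$n_tf_nodes,
                         report$network$n_gene_nodes, report$network$n_edges),
                 sprintf("- module %d: %d genes, TFs [%s], correlation %.3f",
                         m$module_id, m$n_genes, m$tfs, m$correlation_score),
                 "")
    }
  }
  lines
}

#' @export
print.countnet_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}
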