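#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i} p_(j) * n / j`
#' clipped to 1, mapped back to the input order. Delegates to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.001, 0.5))
bh_adjust <- function(p) {
  assert_prob(p)
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes by p- or q-value cut-off
#'
#' Genes whose criterion value is at or below the threshold are selected
#' (inclusive boundary). When the q-value criterion is requested but the
#' column is absent, q-values are computed from the raw p-values with
#' [bh_adjust()].
#'
#' @param results Tibble as returned by [read_de_table()] or
#'   [builtin_de_test()].
#' @param criterion `"p_value"` or `"q_value"`.
#' @param threshold Cut-off in (0, 1\]; default 0.05.
#' @return Character vector of selected gene ids.
#' @export
select_de <- function(results, criterion = c("p_value", "q_value"),
                      threshold = 0.05) {
  criterion <- match.arg(criterion)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop_countnet("threshold must lie in (0, 1]",
                  class = "countnet_validation_error")
  }
  values <- results[[criterion]]
  if (criterion == "q_value" && (is.null(values) || all(is.na(values)))) {
    if (!"p_value" %in% names(results)) {
      stop_countnet("no q_value column and no p_value column to adjust",
                    class = "countnet_schema_error")
    }
    values <- bh_adjust(results$p_value)
  }
  if (is.null(values)) {
    stop_countnet(sprintf("missing column: %s", criterion),
                  class = "countnet_schema_error")
  }
  unique(results$gene_id[!is.na(values) & values <= threshold])
}

#' Vote a consensus list of differentially expressed genes
#'
#' A gene enters the consensus when it appears in at least `min_support` of
#' the per-method gene lists (default 3, the usual at-least-three-of-five
#' overlap rule). Output is sorted by support (descending) and gene id.
#'
#' @param lists Named list of character vectors, one per method.
#' @param min_support Minimum number of supporting lists.
#' @return Tibble with `gene_id`, `support`, `methods` (comma-separated
#'   supporting method labels); attributes `min_support` and `n_lists`.
#' @export
consensus_vote <- function(lists, min_support = 3) {
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    names(lists) <- paste0("method", seq_along(lists))
  }
  if (min_support < 1 || min_support > length(lists)) {
    stop_countnet(
      sprintf("min_support (%d) must be between 1 and the number of lists (%d)",
              min_support, length(lists)),
      class = "countnet_configuration_error"
    )
  }
  membership <- purrr::imap_dfr(lists, function(genes, label) {
    tibble::tibble(gene_id = unique(as.character(genes)), method = label)
  })
  out <- membership %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      support = dplyr::n(),
      methods = paste(sort(.data$method), collapse = ","),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$support >= min_support) %>%
    dplyr::arrange(dplyr::desc(.data$support), .data$gene_id)
  attr(out, "min_support") <- min_support
  attr(out, "n_lists") <- length(lists)
  out
}

#' Check the similar-expression normalization assumption
#'
#' Count-based normalization factors assume that the majority of genes have
#' similar expression in the two conditions; localized over-expression (e.g.
#' a transgene region) violates it. The check computes per-gene
#' `|log2|` ratios of depth-normalized condition means (pseudo-count 1 added
#' to each count) and passes iff fewer than `max_fraction` of genes exceed
#' `fc_threshold` in absolute log2 ratio (strict inequality).
#'
#' @param counts Tibble with `gene_id` plus count columns.
#' @param library_sizes Named vector of library sizes per column.
#' @param condition1,condition2 Column names of the two conditions' replicates.
#' @param fc_threshold Absolute log2 ratio counted as discordant; default 2.
#' @param max_fraction Failing fraction boundary; default 0.5.
#' @return List with `passes`, `fraction_discordant`, `median_log2_ratio`.
#' @export
check_similar_expression_assumption <- function(counts, library_sizes,
                                                condition1, condition2,
                                                fc_threshold = 2,
                                                max_fraction = 0.5) {
  sizes <- check_library_sizes(counts, library_sizes)
  if (!length(condition1) || !length(condition2)) {
    stop_countnet("both conditions need at least one replicate column",
                  class = "countnet_grouping_error")
  }
  m1 <- as.matrix(counts[condition1])
  m2 <- as.matrix(counts[condition2])
  if (all(m1 == 0) || all(m2 == 0)) {
    stop_countnet("a condition has all-zero counts",
                  class = "countnet_degenerate_input_error")
  }
  norm_mean <- function(m, cols) {
    rowMeans(sweep(m + 1, 2, sizes[cols], "/"))
  }
  ratio <- log2(norm_mean(m1, condition1) / norm_mean(m2, condition2))
  fraction <- mean(abs(ratio) > fc_threshold)
  list(
    passes = fraction < max_fraction,
    fraction_discordant = fraction,
    median_log2_ratio = stats::median(ratio)
  )
}

#' Built-in two-library exact binomial differential-expression test
#'
#' Dependency-free plumbing so the pipeline can run without external DE
#' packages: per gene, replicate counts and library sizes are summed within
#' each condition, and the p-value is the two-sided exact binomial test of
#' `x1` successes in `x1 + x2` trials with success probability
#' `N1 / (N1 + N2)`. Genes with `x1 + x2 = 0` get p = 1 and are flagged. This
#' test models no biological dispersion; it is calibrated only for
#' low-variability replicates and does not emulate negative-binomial DE
#' methods.
#'
#' @param counts Tibble with `gene_id` plus count columns.
#' @param library_sizes Named vector of library sizes per column.
#' @param condition1,condition2 Column names of the two conditions' replicates.
#' @param method_label Label recorded in the result; default `"builtin_binomial"`.
#' @return Tibble with `gene_id`, `p_value`, `q_value` (BH), `log2_fc`
#'   (of depth-normalized condition means, pseudo-count 0.5), `flagged`,
#'   `method`.
#' @export
builtin_de_test <- function(counts, library_sizes, condition1, condition2,
                            method_label = "builtin_binomial") {
  sizes <- check_library_sizes(counts, library_sizes)
  x1 <- as.integer(round(rowSums(as.matrix(counts[condition1]))))
  x2 <- as.integer(round(rowSums(as.matrix(counts[condition2]))))
  n1 <- sum(sizes[condition1])
  n2 <- sum(sizes[condition2])
  prob <- n1 / (n1 + n2)
  p <- vapply(seq_along(x1), function(i) {
    total <- x1[i] + x2[i]
    if (total == 0L) return(1)
    stats::binom.test(x1[i], total, p = prob)$p.value
  }, numeric(1))
  tibble::tibble(
    gene_id = counts$gene_id,
    p_value = pmin(p, 1),
    q_value = bh_adjust(pmin(p, 1)),
    log2_fc = log2((x1 + 0.5) / n1) - log2((x2 + 0.5) / n2),
    flagged = (x1 + x2) == 0L,
    method = method_label
  )
}
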