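#' Build the 2x2 contingency table for a term's enrichment test
#'
#' Rows are DE status, columns are term membership: `a` = DE genes annotated
#' with the term, `b` = DE genes without it, `c` = background (non-DE) genes
#' with it, `d` = background genes without it. The background universe is the
#' supplied gene universe minus the DE genes.
#'
#' @param de_genes Character vector of differentially expressed genes.
#' @param background Character vector: the gene universe (may include the DE
#'   genes; they are removed from the background side).
#' @param term_genes Character vector of genes annotated with the term.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
build_contingency <- function(de_genes, background, term_genes) {
  de <- unique(as.character(de_genes))
  if (!length(de)) {
    stop_countnet("empty DE gene set", class = "countnet_empty_query_error")
  }
  bg <- setdiff(unique(as.character(background)), de)
  term <- unique(as.character(term_genes))
  c(a = length(intersect(de, term)),
    b = length(setdiff(de, term)),
    c = length(intersect(bg, term)),
    d = length(setdiff(bg, term)))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with fixed margins; the two-sided p-value sums
#' the probabilities of all tables at least as extreme (point probability not
#' exceeding the observed one, up to the conventional 1 + 1e-7 relative
#' tolerance). Wraps `stats::fisher.test`.
#'
#' @param a,b,c,d Non-negative cell counts (DE-with, DE-without, background-with,
#'   background-without), or `a` may be a length-4 vector from
#'   [build_contingency()].
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return The p-value.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) == 4 && is.null(b)) {
    d <- a[[4]]; c <- a[[3]]; b <- a[[2]]; a <- a[[1]]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || anyNA(cells)) {
    stop_countnet("contingency cells must be non-negative",
                  class = "countnet_domain_error")
  }
  tab <- matrix(as.integer(cells), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Cochran-Mantel-Haenszel chi-square test over stratified 2x2 tables
#'
#' Tests conditional association between two binary variables across K
#' strata: `chi2 = (|sum_k (a_k - E_k)| - 1/2 correction)^2 / sum_k V_k` with
#' `E_k = r1_k c1_k / n_k` and `V_k = r1_k r2_k c1_k c2_k / (n_k^2 (n_k - 1))`,
#' referred to a chi-square distribution with 1 degree of freedom.
#'
#' The 1/2 correction is subtracted unconditionally before squaring. (The
#' stock R implementation skips it when `|sum(a - E)| < 0.5`; the two agree
#' everywhere else, and without correction they are identical.)
#'
#' @param strata List of length-4 vectors or 2x2 matrices `(a, b, c, d)`, one
#'   per stratum (K >= 1).
#' @param continuity_correction Apply the 1/2 continuity correction
#'   (default `TRUE`).
#' @return List with `statistic`, `p_value`, `df` (= 1) and `K`.
#' @export
cmh_test <- function(strata, continuity_correction = TRUE) {
  if (!length(strata)) {
    stop_countnet("need at least one stratum", class = "countnet_validation_error")
  }
  cells <- lapply(strata, function(s) {
    v <- as.numeric(if (is.matrix(s)) t(s) else s)
    if (length(v) != 4 || any(v < 0)) {
      stop_countnet("each stratum must be a 2x2 table of non-negative counts",
                    class = "countnet_domain_error")
    }
    v
  })
  a <- vapply(cells, `[[`, numeric(1), 1)
  b <- vapply(cells, `[[`, numeric(1), 2)
  cc <- vapply(cells, `[[`, numeric(1), 3)
  d <- vapply(cells, `[[`, numeric(1), 4)
  n <- a + b + cc + d
  if (any(n <= 1)) {
    stop_countnet("stratum with total <= 1 has undefined variance",
                  class = "countnet_degenerate_stratum_error")
  }
  e <- (a + b) * (a + cc) / n
  v <- (a + b) * (cc + d) * (a + cc) * (b + d) / (n^2 * (n - 1))
  if (sum(v) == 0) {
    stop_countnet("all strata have zero variance (degenerate margins)",
                  class = "countnet_degenerate_stratum_error")
  }
  # conventional form: the 1/2 correction is subtracted before squaring and
  # deliberately not clamped at zero
  num <- abs(sum(a - e)) - if (continuity_correction) 0.5 else 0
  statistic <- num^2 / sum(v)
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
       df = 1L, K = length(strata))
}

#' Rank GO terms by enrichment among differentially expressed genes
#'
#' Within each ontology category, every term annotated to at least one DE
#' gene is tested with Fisher's exact test and the terms are sorted by
#' ascending p-value (ties broken by term id), with consecutive ranks from 1.
#' When `gate = TRUE`, a Cochran-Mantel-Haenszel pre-check of the
#' term-membership x DE-status association, stratified by the three ontology
#' categories, is computed and attached as the `cmh` attribute; it is
#' advisory and never removes terms.
#'
#' @param de_genes Character vector of DE genes.
#' @param background Character vector: gene universe (all genes with measured
#'   expression).
#' @param assignments Tibble with `gene_id`, `term_id`, `category` (see
#'   [read_go_table()]).
#' @param alternative Sidedness passed to [fisher_exact()]; default two-sided.
#' @param gate Run the CMH pre-check; default `TRUE`.
#' @param top_n Optional: keep only the `top_n` best-ranked terms per
#'   category.
#' @return Tibble with `term_id`, `category`, `n_de_with_term`, `p_value`,
#'   `rank` (within category), sorted by category then rank. Attribute `cmh`
#'   holds the pre-check result when gated.
#' @export
rank_terms <- function(de_genes, background, assignments,
                       alternative = "two.sided", gate = TRUE, top_n = NULL) {
  if (!nrow(assignments)) {
    stop_countnet("empty GO assignment table", class = "countnet_empty_input_error")
  }
  de <- unique(as.character(de_genes))
  universe <- union(unique(as.character(background)), de)
  assignments <- dplyr::filter(assignments, .data$gene_id %in% universe)

  testable <- assignments %>%
    dplyr::group_by(.data$category, .data$term_id) %>%
    dplyr::summarise(
      n_de_with_term = length(intersect(unique(.data$gene_id), de)),
      genes = list(unique(.data$gene_id)),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_de_with_term >= 1L)
  if (!nrow(testable)) {
    warn("no GO term overlaps any differentially expressed gene",
         class = "countnet_empty_result_warning")
    out <- tibble::tibble(term_id = character(), category = character(),
                          n_de_with_term = integer(), p_value = numeric(),
                          rank = integer())
    return(out)
  }
  testable$p_value <- purrr::map_dbl(testable$genes, function(g) {
    fisher_exact(build_contingency(de, universe, g), alternative = alternative)
  })
  out <- testable %>%
    dplyr::select(-"genes") %>%
    dplyr::arrange(.data$category, .data$p_value, .data$term_id) %>%
    dplyr::group_by(.data$category) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::select("term_id", "category", "n_de_with_term", "p_value", "rank")
  if (!is.null(top_n)) {
    out <- dplyr::filter(out, .data$rank <= top_n)
  }
  if (gate) {
    strata <- lapply(go_categories, function(cat) {
      with_term <- unique(assignments$gene_id[assignments$category == cat])
      if (!length(with_term)) return(NULL)
      build_contingency(de, universe, with_term)
    })
    strata <- strata[!vapply(strata, is.null, logical(1))]
    cmh <- tryCatch(cmh_test(strata), countnet_error = function(e) NULL)
    if (!is.null(cmh)) {
      inform(sprintf(
        "CMH pre-check (strata = GO categories): statistic %.4g, p = %.4g (advisory)",
        cmh$statistic, cmh$p_value))
    }
    attr(out, "cmh") <- cmh
  }
  out
}
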