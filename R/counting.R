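#' Mapping statistics from per-category read tallies
#'
#' Validates the conservation identity (unique + multi + failed + filtered =
#' total) and computes the percentage of reads mapped to the genome,
#' `100 * (unique + multi) / total`, rounded half-up to two decimals as in
#' standard mapping reports.
#'
#' @param sample_id Sample label(s).
#' @param n_reads,n_unique,n_multi,n_failed,n_filtered Non-negative integer
#'   tallies: total reads, reads mapped to a unique location, reads mapped to
#'   multiple locations, reads that failed to map, and reads removed by the
#'   QC/quality filter.
#' @return Tibble with the tallies and `pct_mapped`.
#' @export
#' @examples
#' mapping_stats("s1", 10, 7, 2, 1, 0)
mapping_stats <- function(sample_id, n_reads, n_unique, n_multi, n_failed,
                          n_filtered) {
  counts <- cbind(n_reads, n_unique, n_multi, n_failed, n_filtered)
  if (any(counts < 0)) {
    stop_countnet("read tallies must be non-negative",
                  class = "countnet_validation_error")
  }
  if (any(n_unique + n_multi + n_failed + n_filtered != n_reads)) {
    stop_countnet(
      "tallies do not close: unique + multi + failed + filtered != total reads",
      class = "countnet_validation_error"
    )
  }
  if (any(n_reads == 0)) {
    stop_countnet("sample with zero reads", class = "countnet_empty_input_error")
  }
  tibble::tibble(
    sample_id = sample_id,
    n_reads = n_reads, n_unique = n_unique, n_multi = n_multi,
    n_failed = n_failed, n_filtered = n_filtered,
    pct_mapped = round_half_up(100 * (n_unique + n_multi) / n_reads, 2)
  )
}

#' Classify reads by mapping multiplicity and keep unique mappers
#'
#' Partitions reads (not alignment lines) into four exclusive categories:
#' failed (unmapped), filtered (QC-fail flag or best mapping quality below
#' `min_mapq`), unique (mapped, one reported placement) and multi (mapped,
#' several placements). Only alignments of uniquely mapped reads are passed
#' downstream; everything else is dropped before counting.
#'
#' @param alignments Tibble from [read_sam()].
#' @param sample_id Sample label for the statistics row.
#' @param min_mapq Minimum mapping quality; reads below it are tallied as
#'   filtered. Default 0 (no quality filtering).
#' @return List with `alignments` (rows for uniquely mapped reads only) and
#'   `stats` (one-row tibble from [mapping_stats()]).
#' @export
classify_reads <- function(alignments, sample_id = "sample", min_mapq = 0) {
  if (!nrow(alignments)) {
    stop_countnet("empty alignment stream", class = "countnet_empty_input_error")
  }
  per_read <- alignments %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::summarise(
      mapped_any = any(.data$mapped),
      qc = any(.data$qc_fail),
      best_mapq = ifelse(any(.data$mapped),
                         max(.data$mapq[.data$mapped], na.rm = TRUE), NA_real_),
      hits = max(.data$hit_count),
      .groups = "drop"
    ) %>%
    dplyr::mutate(category = dplyr::case_when(
      !.data$mapped_any ~ "failed",
      .data$qc | .data$best_mapq < min_mapq ~ "filtered",
      .data$hits == 1L ~ "unique",
      TRUE ~ "multi"
    ))
  tally <- function(cat) sum(per_read$category == cat)
  stats <- mapping_stats(
    sample_id,
    n_reads = nrow(per_read),
    n_unique = tally("unique"),
    n_multi = tally("multi"),
    n_failed = tally("failed"),
    n_filtered = tally("filtered")
  )
  keep <- per_read$read_id[per_read$category == "unique"]
  list(
    alignments = alignments[alignments$read_id %in% keep & alignments$mapped, ],
    stats = stats
  )
}

#' Count uniquely mapped reads per gene and isoform
#'
#' A read is compatible with an exon when their intervals overlap by at least
#' one base. A read overlapping exons of exactly one gene increments that
#' gene's count; reads overlapping several distinct genes are discarded from
#' all counts and tallied as ambiguous. At the transcript level the three
#' assignment rules differ only for reads compatible with several isoforms of
#' the same gene:
#' \describe{
#'   \item{`total_to_each_isoform`}{the read adds 1 to every compatible isoform,}
#'   \item{`discard_ambiguous`}{the read is dropped from transcript counts
#'     (counted only when exactly one isoform is compatible),}
#'   \item{`proportional`}{the read adds 1/n to each of the n compatible
#'     isoforms.}
#' }
#' Gene-level counts are identical under all three rules.
#'
#' @param alignments Unique-read alignments, e.g. `classify_reads()$alignments`.
#' @param annotation An `annotation_index`.
#' @param rule Isoform assignment rule; see Details.
#' @return List with `genes` (tibble `gene_id`, `count` covering every
#'   annotated gene), `isoforms` (tibble `gene_id`, `transcript_id`, `count`),
#'   `n_ambiguous` (reads spanning several genes), `n_unassigned` (reads
#'   overlapping no exon) and `library_size` (number of uniquely mapped reads).
#' @export
count_genes <- function(alignments, annotation,
                        rule = c("total_to_each_isoform", "discard_ambiguous",
                                 "proportional")) {
  rule <- match.arg(rule)
  if (!inherits(annotation, "annotation_index")) {
    stop_countnet("annotation must be an annotation_index",
                  class = "countnet_validation_error")
  }
  reads <- alignments %>%
    dplyr::filter(.data$mapped) %>%
    dplyr::distinct(.data$read_id, .keep_all = TRUE)
  library_size <- nrow(reads)

  zero_genes <- tibble::tibble(gene_id = annotation$genes$gene_id, count = 0L)
  zero_iso <- annotation$transcripts %>%
    dplyr::transmute(.data$gene_id, .data$transcript_id, count = 0)
  if (!library_size) {
    return(list(genes = zero_genes, isoforms = zero_iso, n_ambiguous = 0L,
                n_unassigned = 0L, library_size = 0L))
  }

  query <- GenomicRanges::GRanges(
    seqnames = reads$reference,
    ranges = IRanges::IRanges(start = reads$start + 1L, end = reads$end)
  )
  hits <- GenomicRanges::findOverlaps(query, annotation$ranges,
                                      minoverlap = 1L)
  overlaps <- tibble::tibble(
    read_id = reads$read_id[S4Vectors::queryHits(hits)],
    gene_id = annotation$ranges$gene_id[S4Vectors::subjectHits(hits)],
    transcript_id = annotation$ranges$transcript_id[S4Vectors::subjectHits(hits)]
  ) %>% dplyr::distinct()

  per_read_genes <- overlaps %>%
    dplyr::distinct(.data$read_id, .data$gene_id) %>%
    dplyr::count(.data$read_id, name = "n_genes")
  ambiguous_reads <- per_read_genes$read_id[per_read_genes$n_genes > 1L]
  assigned <- overlaps %>%
    dplyr::filter(!.data$read_id %in% ambiguous_reads)

  gene_counts <- assigned %>%
    dplyr::distinct(.data$read_id, .data$gene_id) %>%
    dplyr::count(.data$gene_id, name = "n")
  genes <- zero_genes %>%
    dplyr::left_join(gene_counts, by = "gene_id") %>%
    dplyr::mutate(count = as.integer(.data$count + dplyr::coalesce(.data$n, 0L))) %>%
    dplyr::select("gene_id", "count")

  iso_compat <- assigned %>%
    dplyr::distinct(.data$read_id, .data$gene_id, .data$transcript_id) %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::mutate(n_iso = dplyr::n()) %>%
    dplyr::ungroup()
  iso_weights <- switch(
    rule,
    total_to_each_isoform = dplyr::mutate(iso_compat, w = 1),
    discard_ambiguous = dplyr::mutate(iso_compat,
                                      w = ifelse(.data$n_iso == 1L, 1, 0)),
    proportional = dplyr::mutate(iso_compat, w = 1 / .data$n_iso)
  )
  iso_counts <- iso_weights %>%
    dplyr::group_by(.data$gene_id, .data$transcript_id) %>%
    dplyr::summarise(n = sum(.data$w), .groups = "drop")
  isoforms <- zero_iso %>%
    dplyr::left_join(iso_counts, by = c("gene_id", "transcript_id")) %>%
    dplyr::mutate(count = .data$count + dplyr::coalesce(.data$n, 0)) %>%
    dplyr::select("gene_id", "transcript_id", "count")

  list(
    genes = genes,
    isoforms = isoforms,
    n_ambiguous = length(ambiguous_reads),
    n_unassigned = library_size - dplyr::n_distinct(overlaps$read_id),
    library_size = library_size
  )
}

#' Assemble per-sample counting results into a count matrix
#'
#' @param results Named list of [count_genes()] results, one per
#'   sample/replicate; names become column labels.
#' @return List with `counts` (tibble, `gene_id` plus one integer column per
#'   sample) and `library_sizes` (named vector of uniquely mapped read
#'   totals).
#' @export
count_matrix <- function(results) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  counts <- results[[1]]$genes["gene_id"]
  for (label in names(results)) {
    col <- results[[label]]$genes
    counts[[label]] <- col$count[match(counts$gene_id, col$gene_id)]
  }
  list(
    counts = counts,
    library_sizes = vapply(results, `[[`, numeric(1), "library_size")
  )
}

expr_columns <- function(counts) setdiff(names(counts), "gene_id")

check_library_sizes <- function(counts, library_sizes) {
  cols <- expr_columns(counts)
  missing <- setdiff(cols, names(library_sizes))
  if (length(missing)) {
    stop_countnet(sprintf("no library size for column(s): %s",
                          paste(missing, collapse = ", ")),
                  class = "countnet_validation_error")
  }
  if (any(library_sizes[cols] <= 0)) {
    stop_countnet("library size must be positive",
                  class = "countnet_degenerate_input_error")
  }
  invisible(library_sizes[cols])
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' `rpkm[g, s] = count[g, s] * 1e9 / (union_exon_length[g] * library_size[s])`.
#' The length denominator is the union of all exon intervals of the gene
#' across its isoforms.
#'
#' @param counts Tibble with `gene_id` plus one count column per sample.
#' @param library_sizes Named vector of uniquely mapped read counts per column.
#' @param annotation An `annotation_index` supplying union exon lengths.
#' @return Tibble with the same shape as `counts`, values in RPKM, with
#'   attribute `units = "rpkm"`.
#' @export
compute_rpkm <- function(counts, library_sizes, annotation) {
  sizes <- check_library_sizes(counts, library_sizes)
  len <- annotation$genes$union_exon_length[
    match(counts$gene_id, annotation$genes$gene_id)]
  if (anyNA(len)) {
    stop_countnet("count table contains genes absent from the annotation",
                  class = "countnet_validation_error")
  }
  if (any(len <= 0)) {
    stop_countnet("gene with non-positive union exon length",
                  class = "countnet_degenerate_input_error")
  }
  out <- counts
  for (col in expr_columns(counts)) {
    out[[col]] <- counts[[col]] * 1e9 / (len * sizes[[col]])
  }
  attr(out, "units") <- "rpkm"
  out
}

#' Depth-normalize replicate counts and average them per sample
#'
#' Each replicate column is divided by its total number of uniquely mapped
#' reads; the per-sample expression value is the arithmetic mean of its
#' replicates' normalized values.
#'
#' @param counts Tibble with `gene_id` plus one count column per replicate.
#' @param library_sizes Named vector of uniquely mapped reads per replicate.
#' @param groups Named character vector mapping replicate column names to
#'   sample labels.
#' @return List with `replicates` (normalized per-replicate tibble) and
#'   `samples` (per-sample means), both with attribute
#'   `units = "depth_normalized"`.
#' @export
normalize_and_average <- function(counts, library_sizes, groups) {
  sizes <- check_library_sizes(counts, library_sizes)
  cols <- expr_columns(counts)
  missing <- setdiff(cols, names(groups))
  if (length(missing)) {
    stop_countnet(sprintf("replicate column(s) not assigned to a sample: %s",
                          paste(missing, collapse = ", ")),
                  class = "countnet_grouping_error")
  }
  empty <- setdiff(unique(unname(groups)), unname(groups[cols]))
  if (length(empty)) {
    stop_countnet(sprintf("sample(s) with zero replicates: %s",
                          paste(empty, collapse = ", ")),
                  class = "countnet_grouping_error")
  }
  reps <- counts
  for (col in cols) reps[[col]] <- counts[[col]] / sizes[[col]]
  samples <- reps["gene_id"]
  for (sample in unique(unname(groups[cols]))) {
    members <- cols[groups[cols] == sample]
    samples[[sample]] <- rowMeans(as.matrix(reps[members]))
  }
  attr(reps, "units") <- "depth_normalized"
  attr(samples, "units") <- "depth_normalized"
  list(replicates = reps, samples = samples)
}
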