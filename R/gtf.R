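#' Build an annotation index from an exon table
#'
#' The annotation index is the package's internal gene-model container: the
#' exon table (0-based half-open intervals), per-transcript exonic lengths,
#' and per-gene union-exon lengths ("exon model" length, the RPKM
#' denominator), plus a `GenomicRanges` interval structure for overlap
#' queries.
#'
#' @param exons Tibble with columns `reference`, `start` (0-based), `end`
#'   (half-open), `strand`, `gene_id`, `transcript_id`.
#' @return An object of class `annotation_index`.
#' @export
annotation_index <- function(exons) {
  required <- c("reference", "start", "end", "strand", "gene_id", "transcript_id")
  missing <- setdiff(required, names(exons))
  if (length(missing)) {
    stop_countnet(sprintf("exon table missing column(s): %s",
                          paste(missing, collapse = ", ")),
                  class = "countnet_schema_error")
  }
  if (!nrow(exons)) {
    stop_countnet("annotation contains no exon features",
                  class = "countnet_empty_annotation_error")
  }
  if (anyNA(exons$gene_id) || any(!nzchar(exons$gene_id))) {
    stop_countnet("exon feature lacks a gene_id attribute",
                  class = "countnet_validation_error")
  }
  if (any(exons$end <= exons$start)) {
    stop_countnet("exon with non-positive width", class = "countnet_validation_error")
  }
  exons <- dplyr::arrange(tibble::as_tibble(exons), .data$gene_id,
                          .data$transcript_id, .data$start)

  union_len <- function(start, end) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start + 1L, end))))
  }
  genes <- exons %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      strand = dplyr::first(.data$strand),
      union_exon_length = union_len(.data$start, .data$end),
      n_transcripts = dplyr::n_distinct(.data$transcript_id),
      .groups = "drop"
    )
  transcripts <- exons %>%
    dplyr::group_by(.data$gene_id, .data$transcript_id) %>%
    dplyr::summarise(exon_length = union_len(.data$start, .data$end),
                     .groups = "drop")

  ranges <- GenomicRanges::GRanges(
    seqnames = exons$reference,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    gene_id = exons$gene_id,
    transcript_id = exons$transcript_id
  )
  structure(
    list(exons = exons, genes = genes, transcripts = transcripts,
         ranges = ranges),
    class = "annotation_index"
  )
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("<annotation_index> %d genes, %d transcripts, %d exons on %d sequence(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              length(unique(x$exons$reference))))
  invisible(x)
}

#' Read gene annotation from GTF/GFF into an annotation index
#'
#' Imports the file with `rtracklayer`, keeps only features of the configured
#' type (case-insensitive; aligner-ecosystem conventions capitalise it
#' variously), converts 1-based inclusive coordinates to the internal 0-based
#' half-open convention and computes per-gene union-exon lengths by interval
#' union.
#'
#' @param path Path to a GTF or GFF3 file.
#' @param feature_type Feature type (3rd column) to retain; default `"exon"`.
#' @return An `annotation_index`.
#' @export
read_gtf <- function(path, feature_type = "exon") {
  if (!file.exists(path)) {
    stop_countnet(sprintf("annotation file not found: %s", path),
                  class = "countnet_io_error")
  }
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  gr <- rtracklayer::import(path, format = fmt)
  keep <- tolower(as.character(gr$type)) == tolower(feature_type)
  gr <- gr[keep]
  if (!length(gr)) {
    stop_countnet(
      sprintf("annotation contains no '%s' features", feature_type),
      class = "countnet_empty_annotation_error"
    )
  }
  gene_id <- gr$gene_id
  if (is.null(gene_id) || anyNA(gene_id)) {
    stop_countnet("exon feature lacks a gene_id attribute",
                  class = "countnet_validation_error")
  }
  transcript_id <- gr$transcript_id
  if (is.null(transcript_id)) transcript_id <- gene_id
  transcript_id[is.na(transcript_id)] <- gene_id[is.na(transcript_id)]
  exons <- tibble::tibble(
    reference = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(gene_id),
    transcript_id = as.character(transcript_id)
  )
  exons$strand[exons$strand == "*"] <- "."
  annotation_index(exons)
}

#' Write an annotation index back to GTF
#'
#' Emits one exon feature per row of the index's exon table, converting the
#' internal 0-based half-open intervals back to 1-based inclusive GTF
#' coordinates, so that [read_gtf()] round-trips the annotation.
#'
#' @param annotation An `annotation_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  ex <- annotation$exons
  strand <- ifelse(ex$strand %in% c("+", "-"), ex$strand, ".")
  lines <- sprintf(
    "%s\tcountnet\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    ex$reference, ex$start + 1L, ex$end, strand, ex$gene_id, ex$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}
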