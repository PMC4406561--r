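make_alignment <- function(read_id, start = 0L, hit_count = 1L,
                           mapped = TRUE, qc_fail = FALSE, mapq = 50L,
                           reference = "chr1", width = 50L) {
  tibble::tibble(
    read_id = read_id,
    reference = ifelse(mapped, reference, NA_character_),
    start = ifelse(mapped, as.integer(start), NA_integer_),
    end = ifelse(mapped, as.integer(start + width), NA_integer_),
    mapped = mapped, mapq = mapq, hit_count = as.integer(hit_count),
    qc_fail = qc_fail
  )
}

test_that("classify_reads partitions reads and keeps unique mappers only", {
  aln <- dplyr::bind_rows(
    purrr::map(sprintf("u%d", 1:7), make_alignment),
    make_alignment(rep("m1", 2), start = c(0, 500), hit_count = 2),
    make_alignment(rep("m2", 2), start = c(10, 600), hit_count = 2),
    make_alignment("f1", mapped = FALSE)
  )
  res <- classify_reads(aln, sample_id = "fix")
  expect_equal(unlist(res$stats[, c("n_reads", "n_unique", "n_multi",
                                    "n_failed", "n_filtered")],
                      use.names = FALSE),
               c(10, 7, 2, 1, 0))
  expect_equal(res$stats$pct_mapped, 90.00)
  expect_setequal(unique(res$alignments$read_id), sprintf("u%d", 1:7))

  one <- classify_reads(make_alignment("r1"))
  expect_equal(one$stats$pct_mapped, 100.00)
  expect_equal(one$stats$n_unique, 1)

  expect_error(classify_reads(make_alignment(character(0))),
               class = "countnet_empty_input_error")
})

test_that("QC flag and mapping-quality threshold route reads to filtered", {
  aln <- dplyr::bind_rows(
    make_alignment("ok"),
    make_alignment("lowq", mapq = 5L),
    make_alignment("qcf", qc_fail = TRUE)
  )
  res <- classify_reads(aln, min_mapq = 10)
  expect_equal(res$stats$n_unique, 1)
  expect_equal(res$stats$n_filtered, 2)
  # default threshold 0 filters nothing on quality
  res0 <- classify_reads(aln)
  expect_equal(res0$stats$n_filtered, 1)
})

test_that("mapping_stats enforces the conservation identity", {
  expect_error(mapping_stats("s", 10, 5, 2, 1, 1),
               class = "countnet_validation_error")
  expect_error(mapping_stats("s", 10, -1, 9, 1, 1),
               class = "countnet_validation_error")
  ok <- mapping_stats("s", 10, 5, 2, 2, 1)
  expect_equal(ok$pct_mapped, 70.00)
})

# Two-isoform gene: I1 = exons A [0,100) + B [200,300); I2 = A + C [400,500);
# a second gene G2 with exon D [1000,1100) overlapping nothing else.
shared_exon_annotation <- function() {
  annotation_index(tibble::tibble(
    reference = "chr1",
    start = c(0L, 200L, 0L, 400L, 1000L),
    end = c(100L, 300L, 100L, 500L, 1100L),
    strand = "+",
    gene_id = c("G", "G", "G", "G", "G2"),
    transcript_id = c("I1", "I1", "I2", "I2", "I3")
  ))
}

test_that("isoform assignment rules differ only for shared-exon reads", {
  ann <- shared_exon_annotation()
  shared <- dplyr::bind_rows(purrr::map(sprintf("s%d", 1:5), make_alignment,
                                        start = 10L))
  iso_counts <- function(rule) {
    res <- count_genes(shared, ann, rule = rule)
    list(gene = res$genes$count[res$genes$gene_id == "G"],
         iso = res$isoforms$count[match(c("I1", "I2"),
                                        res$isoforms$transcript_id)])
  }
  total <- iso_counts("total_to_each_isoform")
  expect_equal(total$gene, 5L)
  expect_equal(total$iso, c(5, 5))
  discard <- iso_counts("discard_ambiguous")
  expect_equal(discard$gene, 5L)
  expect_equal(discard$iso, c(0, 0))
  prop <- iso_counts("proportional")
  expect_equal(prop$gene, 5L)
  expect_equal(prop$iso, c(2.5, 2.5))

  # a read in exon B is specific to I1 under every rule
  specific <- make_alignment("b1", start = 210L)
  for (rule in c("total_to_each_isoform", "discard_ambiguous", "proportional")) {
    res <- count_genes(specific, ann, rule = rule)
    expect_equal(res$isoforms$count[res$isoforms$transcript_id == "I1"], 1)
    expect_equal(res$isoforms$count[res$isoforms$transcript_id == "I2"], 0)
  }
})

test_that("reads spanning two genes are discarded and tallied ambiguous", {
  ann <- annotation_index(tibble::tibble(
    reference = "chr1", start = c(0L, 120L), end = c(100L, 220L),
    strand = "+", gene_id = c("G1", "G2"), transcript_id = c("t1", "t2")
  ))
  spanning <- make_alignment("x1", start = 80L, width = 60L)  # hits both
  res <- count_genes(spanning, ann)
  expect_equal(sum(res$genes$count), 0L)
  expect_equal(res$n_ambiguous, 1L)
  expect_equal(res$library_size, 1L)
})

test_that("gene counts are rule-invariant and order-invariant on fixtures", {
  sim <- simulate_annotation(12, 5, seed = 21)
  al <- simulate_alignments(sim$annotation, n_reads = 400, multi_rate = 0.1,
                            unmapped_rate = 0.05, seed = 22)
  unique_aln <- classify_reads(al$alignments)$alignments
  rules <- c("total_to_each_isoform", "discard_ambiguous", "proportional")
  res <- lapply(rules, function(r) count_genes(unique_aln, sim$annotation, r))
  expect_equal(res[[1]]$genes, res[[2]]$genes)
  expect_equal(res[[1]]$genes, res[[3]]$genes)

  # proportional <= total per isoform; proportional column sums to assigned reads
  expect_true(all(res[[3]]$isoforms$count <= res[[1]]$isoforms$count + 1e-12))
  expect_equal(sum(res[[3]]$isoforms$count), sum(res[[1]]$genes$count))

  set.seed(5)
  shuffled <- unique_aln[sample.int(nrow(unique_aln)), ]
  expect_equal(count_genes(shuffled, sim$annotation)$genes, res[[1]]$genes)
})

test_that("conservation identity holds across simulated fixtures", {
  for (s in 1:5) {
    sim <- simulate_annotation(8, 2, seed = s)
    al <- simulate_alignments(sim$annotation, n_reads = 300,
                              multi_rate = 0.15, unmapped_rate = 0.1,
                              qcfail_rate = 0.05, seed = s + 50)
    st <- classify_reads(al$alignments)$stats
    expect_equal(st$n_unique + st$n_multi + st$n_failed + st$n_filtered,
                 st$n_reads)
    expect_equal(unlist(st[, c("n_reads", "n_unique", "n_multi", "n_failed",
                               "n_filtered")], use.names = FALSE),
                 unlist(al$truth$tallies, use.names = FALSE))
  }
})

test_that("RPKM matches its closed form and is scale-invariant", {
  ann <- annotation_index(tibble::tibble(
    reference = "chr1", start = 0L, end = 2000L, strand = "+",
    gene_id = "g1", transcript_id = "t1"
  ))
  counts <- tibble::tibble(gene_id = "g1", s1 = 500L, s2 = 0L)
  r <- compute_rpkm(counts, c(s1 = 1e7, s2 = 1e7), ann)
  expect_equal(r$s1, 25.0)   # 500 * 1e9 / (2000 * 1e7)
  expect_equal(r$s2, 0.0)

  # random matrix against per-cell formula evaluation
  set.seed(11)
  sim <- simulate_annotation(15, 0, seed = 3)
  genes <- sim$annotation$genes
  cmat <- tibble::tibble(gene_id = genes$gene_id,
                         a = rpois(nrow(genes), 40),
                         b = rpois(nrow(genes), 80))
  sizes <- c(a = 5e5, b = 9e5)
  r2 <- compute_rpkm(cmat, sizes, sim$annotation)
  for (col in c("a", "b")) {
    expect_equal(r2[[col]],
                 cmat[[col]] * 1e9 / (genes$union_exon_length * sizes[[col]]))
  }
  # doubling counts and library sizes leaves RPKM unchanged
  doubled <- dplyr::mutate(cmat, a = a * 2L, b = b * 2L)
  r3 <- compute_rpkm(doubled, sizes * 2, sim$annotation)
  expect_equal(r3$a, r2$a)
  expect_equal(r3$b, r2$b)

  expect_error(compute_rpkm(cmat, c(a = 0, b = 1), sim$annotation),
               class = "countnet_degenerate_input_error")
})

test_that("depth normalization divides by library size and averages replicates", {
  counts <- tibble::tibble(gene_id = "g1", r1 = 10L, r2 = 20L)
  sizes <- c(r1 = 1e6, r2 = 2e6)
  res <- normalize_and_average(counts, sizes, c(r1 = "s", r2 = "s"))
  expect_equal(res$replicates$r1, 1e-5)
  expect_equal(res$replicates$r2, 1e-5)
  expect_equal(res$samples$s, 1e-5)

  # single replicate: average is the normalized value itself
  one <- normalize_and_average(counts[, c("gene_id", "r1")],
                               sizes["r1"], c(r1 = "s"))
  expect_equal(one$samples$s, one$replicates$r1)

  # random three-replicate fixture against brute-force mean of ratios
  set.seed(13)
  cm <- tibble::tibble(gene_id = sprintf("g%d", 1:20),
                       a = rpois(20, 30), b = rpois(20, 60), c = rpois(20, 90))
  sz <- c(a = 4e5, b = 6e5, c = 8e5)
  res3 <- normalize_and_average(cm, sz, c(a = "s", b = "s", c = "s"))
  expect_equal(res3$samples$s, (cm$a / sz[["a"]] + cm$b / sz[["b"]] +
                                  cm$c / sz[["c"]]) / 3)

  expect_error(normalize_and_average(cm, sz, c(a = "s", b = "s")),
               class = "countnet_grouping_error")
})
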