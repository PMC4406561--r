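# Builds a complete integration fixture on disk (annotation, SAM per
# replicate, GO table, TF list) and returns a ready pipeline configuration.
# With plant_tf_overlap = FALSE the TF list is disjoint from every gene so
# the network stage must skip.
integration_config <- function(dir = tempfile("pipe"), seed = 42,
                               plant_tf_overlap = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(30, 8, seed = seed)
  gtf <- file.path(dir, "annotation.gtf")
  write_gtf(ann$annotation, gtf)

  samples <- NULL
  k <- 0
  for (cond in c("c1", "c2")) {
    for (r in 1:2) {
      k <- k + 1
      al <- simulate_alignments(ann$annotation, n_reads = 2500,
                                multi_rate = 0.1, unmapped_rate = 0.05,
                                qcfail_rate = 0.01, seed = seed + k)
      sam <- file.path(dir, sprintf("%s_r%d.sam", cond, r))
      write_sam(al$alignments, sam)
      samples <- rbind(samples,
                       data.frame(sample = sprintf("%s_r%d", cond, r),
                                  condition = cond, sam = sam))
    }
  }
  genes <- ann$annotation$genes$gene_id
  go <- simulate_go(genes[1:10], genes, seed = seed)
  go_path <- file.path(dir, "go.tsv")
  readr::write_tsv(
    tibble::tibble(gene = go$assignments$gene_id,
                   term = go$assignments$term_id,
                   category = go$assignments$category),
    go_path, progress = FALSE)

  tf_path <- file.path(dir, "tf.txt")
  if (plant_tf_overlap) {
    writeLines(genes[seq(1, 29, by = 4)], tf_path)
  } else {
    writeLines(c("not_a_gene_1", "not_a_gene_2"), tf_path)
  }

  list(
    stage = "networks",
    annotation = gtf,
    samples = samples,
    go_table = go_path,
    tf_list = tf_path,
    out_dir = file.path(dir, "out"),
    seed = seed,
    de = list(threshold = 0.5, min_support = 1),
    gnet = list(K = 2, max_depth = 2, min_module_size = 2)
  )
}
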