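with_seed <- function(seed, code) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate a toy gene annotation
#'
#' Builds a deterministic toy genome on one chromosome: `n_genes` genes laid
#' end to end with intergenic gaps, each with a primary transcript of two
#' exons. The first `n_isoform_genes` genes carry a second isoform that
#' shares exon 1 and adds its own downstream exon, exercising the
#' shared-exon isoform counting rules. Exons are at least 100 bp so reads up
#' to that length fit inside a single exon.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_isoform_genes Number of genes with a second isoform.
#' @param seed Integer seed.
#' @return List with `annotation` (an `annotation_index`) and `truth`
#'   (tibble of per-gene union exon lengths and isoform status).
#' @export
simulate_annotation <- function(n_genes = 20, n_isoform_genes = 5, seed = 1) {
  stopifnot(n_genes >= 1, n_isoform_genes <= n_genes)
  with_seed(seed, {
    exon_rows <- list()
    cursor <- 0L
    for (g in seq_len(n_genes)) {
      gene <- sprintf("g%03d", g)
      len1 <- sample(100:300, 1)
      len2 <- sample(100:300, 1)
      gap <- sample(50:150, 1)
      e1 <- c(cursor, cursor + len1)
      e2 <- c(e1[2] + gap, e1[2] + gap + len2)
      t1 <- sprintf("%s.t1", gene)
      exon_rows[[length(exon_rows) + 1]] <- tibble::tibble(
        reference = "chr1", start = c(e1[1], e2[1]), end = c(e1[2], e2[2]),
        strand = sample(c("+", "-"), 1), gene_id = gene,
        transcript_id = t1
      )
      cursor <- e2[2]
      if (g <= n_isoform_genes) {
        len3 <- sample(100:300, 1)
        gap3 <- sample(50:150, 1)
        e3 <- c(cursor + gap3, cursor + gap3 + len3)
        t2 <- sprintf("%s.t2", gene)
        exon_rows[[length(exon_rows) + 1]] <- tibble::tibble(
          reference = "chr1", start = c(e1[1], e3[1]), end = c(e1[2], e3[2]),
          strand = exon_rows[[length(exon_rows)]]$strand[1], gene_id = gene,
          transcript_id = t2
        )
        cursor <- e3[2]
      }
      cursor <- cursor + sample(200:400, 1)
    }
    exons <- dplyr::bind_rows(exon_rows)
    annotation <- annotation_index(exons)
    list(
      annotation = annotation,
      truth = annotation$genes %>%
        dplyr::mutate(has_isoform = .data$n_transcripts > 1L)
    )
  })
}

#' Simulate SAM-style alignments with exact category tallies
#'
#' Category counts are an exact deterministic partition of `n_reads` (rates
#' rounded to whole reads, remainder uniquely mapped), not sampled, so that
#' classification tests are exact. Uniquely mapped reads are placed fully
#' inside a random exon of a random gene (seeded); multi-mapped reads get two
#' placements in exons of two distinct genes with `NH:i:2`; QC-fail reads
#' carry flag 0x200; unmapped reads flag 0x4.
#'
#' @param annotation An `annotation_index` (e.g. from
#'   [simulate_annotation()]).
#' @param n_reads Total reads.
#' @param multi_rate,unmapped_rate,qcfail_rate Category fractions (sum < 1).
#' @param read_length Read length in bp (must fit the smallest exon, 100 bp).
#' @param seed Integer seed.
#' @return List with `alignments` (tibble as from [read_sam()]), and `truth`:
#'   `tallies` (total/unique/multi/failed/filtered) and `gene_counts` (tibble
#'   of per-gene uniquely mapped read counts).
#' @export
simulate_alignments <- function(annotation, n_reads = 1000, multi_rate = 0.1,
                                unmapped_rate = 0.05, qcfail_rate = 0,
                                read_length = 50, seed = 1) {
  stopifnot(multi_rate + unmapped_rate + qcfail_rate <= 1, read_length <= 100)
  n_multi <- round(n_reads * multi_rate)
  n_unmapped <- round(n_reads * unmapped_rate)
  n_qc <- round(n_reads * qcfail_rate)
  n_unique <- n_reads - n_multi - n_unmapped - n_qc
  stopifnot(n_unique >= 0)

  exons <- annotation$exons %>%
    dplyr::distinct(.data$reference, .data$start, .data$end, .data$gene_id) %>%
    dplyr::filter(.data$end - .data$start >= read_length)

  with_seed(seed, {
    place <- function(exon_row_idx) {
      ex <- exons[exon_row_idx, ]
      offset_max <- ex$end - ex$start - read_length
      s <- as.integer(ex$start + sample.int(offset_max + 1L, 1L) - 1L)
      list(reference = ex$reference, start = s,
           end = as.integer(s + read_length), gene_id = ex$gene_id)
    }
    rows <- list()
    gene_tally <- stats::setNames(integer(nrow(annotation$genes)),
                                  annotation$genes$gene_id)
    rid <- 0L
    for (i in seq_len(n_unique)) {
      rid <- rid + 1L
      p <- place(sample.int(nrow(exons), 1L))
      gene_tally[p$gene_id] <- gene_tally[p$gene_id] + 1L
      rows[[length(rows) + 1]] <- tibble::tibble(
        read_id = sprintf("r%06d", rid), reference = p$reference,
        start = p$start, end = p$end, mapped = TRUE, mapq = 50L,
        hit_count = 1L, qc_fail = FALSE
      )
    }
    genes_by_exon <- unique(exons$gene_id)
    for (i in seq_len(n_multi)) {
      rid <- rid + 1L
      two_genes <- sample(genes_by_exon, 2L)
      placements <- lapply(two_genes, function(g) {
        place(sample(which(exons$gene_id == g), 1L))
      })
      rows[[length(rows) + 1]] <- tibble::tibble(
        read_id = sprintf("r%06d", rid),
        reference = vapply(placements, `[[`, character(1), "reference"),
        start = vapply(placements, `[[`, integer(1), "start"),
        end = vapply(placements, `[[`, integer(1), "end"),
        mapped = TRUE, mapq = 3L, hit_count = 2L, qc_fail = FALSE
      )
    }
    for (i in seq_len(n_qc)) {
      rid <- rid + 1L
      p <- place(sample.int(nrow(exons), 1L))
      rows[[length(rows) + 1]] <- tibble::tibble(
        read_id = sprintf("r%06d", rid), reference = p$reference,
        start = p$start, end = p$end, mapped = TRUE, mapq = 50L,
        hit_count = 1L, qc_fail = TRUE
      )
    }
    for (i in seq_len(n_unmapped)) {
      rid <- rid + 1L
      rows[[length(rows) + 1]] <- tibble::tibble(
        read_id = sprintf("r%06d", rid), reference = NA_character_,
        start = NA_integer_, end = NA_integer_, mapped = FALSE, mapq = 0L,
        hit_count = 1L, qc_fail = FALSE
      )
    }
    alignments <- dplyr::bind_rows(rows)
    list(
      alignments = alignments,
      truth = list(
        tallies = tibble::tibble(
          n_reads = n_reads, n_unique = n_unique, n_multi = n_multi,
          n_failed = n_unmapped, n_filtered = n_qc
        ),
        gene_counts = tibble::tibble(gene_id = names(gene_tally),
                                     count = as.integer(gene_tally))
      )
    )
  })
}

#' Simulate a negative-binomial count matrix with planted DE genes
#'
#' Per-gene means are log-normal; counts are negative binomial with variance
#' `mu + dispersion * mu^2`. A fraction of genes is shifted by `de_log2fc`
#' (alternating up/down) in the second condition. The default dispersion
#' (0.005) models homogeneous cell-line replicates, the regime in which the
#' built-in pooled-binomial test is approximately calibrated.
#'
#' @param n_genes Number of genes.
#' @param reps Replicates per condition (two conditions).
#' @param de_fraction Fraction of genes differentially expressed.
#' @param de_log2fc Absolute log2 fold change planted in DE genes.
#' @param nb_dispersion Negative-binomial dispersion (0 = Poisson).
#' @param mean_log_mu,mean_log_sd Log-normal parameters of per-gene means.
#' @param seed Integer seed.
#' @return List with `counts` (tibble `gene_id` + `c1_r*`/`c2_r*` columns),
#'   `library_sizes`, `groups` (replicate to condition map) and `truth`
#'   (tibble `gene_id`, `is_de`, `log2_fc`).
#' @export
simulate_counts <- function(n_genes = 2000, reps = 3, de_fraction = 0.1,
                            de_log2fc = 2, nb_dispersion = 0.005,
                            mean_log_mu = log(20), mean_log_sd = 1,
                            seed = 1) {
  with_seed(seed, {
    gene_id <- sprintf("g%05d", seq_len(n_genes))
    mu <- stats::rlnorm(n_genes, mean_log_mu, mean_log_sd)
    n_de <- round(n_genes * de_fraction)
    is_de <- c(rep(TRUE, n_de), rep(FALSE, n_genes - n_de))[
      sample.int(n_genes)]
    lfc <- ifelse(is_de, de_log2fc * rep_len(c(1, -1), n_genes), 0)
    rcounts <- function(mu_vec) {
      if (nb_dispersion > 0) {
        stats::rnbinom(length(mu_vec), mu = mu_vec, size = 1 / nb_dispersion)
      } else {
        stats::rpois(length(mu_vec), mu_vec)
      }
    }
    counts <- tibble::tibble(gene_id = gene_id)
    for (r in seq_len(reps)) counts[[sprintf("c1_r%d", r)]] <- rcounts(mu)
    mu2 <- mu * 2^lfc
    for (r in seq_len(reps)) counts[[sprintf("c2_r%d", r)]] <- rcounts(mu2)
    cols <- expr_columns(counts)
    library_sizes <- vapply(counts[cols], sum, numeric(1))
    groups <- stats::setNames(sub("_r\\d+$", "", cols), cols)
    list(
      counts = counts,
      library_sizes = library_sizes,
      groups = groups,
      truth = tibble::tibble(gene_id = gene_id, is_de = is_de, log2_fc = lfc)
    )
  })
}

#' Simulate gene-to-GO assignments with one planted enriched term
#'
#' The planted term includes each DE gene with probability `planted_de_prob`
#' and each background gene with probability `planted_bg_prob`
#' (`planted_de_prob = 1, planted_bg_prob = 0` makes the term exactly the DE
#' set). Decoy terms are assigned uniformly at `decoy_prob`; terms are spread
#' round-robin over the three GO categories, with the planted term in
#' biological_process.
#'
#' @param de_genes,background Character vectors (background = gene universe).
#' @param n_decoy_terms Number of decoy terms.
#' @param planted_de_prob,planted_bg_prob,decoy_prob Membership
#'   probabilities.
#' @param seed Integer seed.
#' @return List with `assignments` (tibble `gene_id`, `term_id`, `category`)
#'   and `planted_term`.
#' @export
simulate_go <- function(de_genes, background, n_decoy_terms = 24,
                        planted_de_prob = 0.8, planted_bg_prob = 0.05,
                        decoy_prob = 0.1, seed = 1) {
  de <- unique(as.character(de_genes))
  universe <- union(unique(as.character(background)), de)
  bg <- setdiff(universe, de)
  with_seed(seed, {
    planted <- "GO:1000000"
    rows <- list(tibble::tibble(
      gene_id = c(de[stats::runif(length(de)) < planted_de_prob],
                  bg[stats::runif(length(bg)) < planted_bg_prob]),
      term_id = planted, category = "biological_process"
    ))
    for (i in seq_len(n_decoy_terms)) {
      members <- universe[stats::runif(length(universe)) < decoy_prob]
      if (!length(members)) members <- sample(universe, 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = members,
        term_id = sprintf("GO:%07d", 1000000 + i),
        category = go_categories[(i %% 3) + 1]
      )
    }
    list(assignments = dplyr::bind_rows(rows), planted_term = planted)
  })
}

# Ground-truth threshold tree of depth <= 2 over a module's TFs; thresholds
# at the median split conditions into balanced leaves.
truth_tree <- function(tf_mat, depth, leaf_means) {
  n_cond <- ncol(tf_mat)
  conds <- seq_len(n_cond)
  mean_vec <- numeric(n_cond)
  leaf_counter <- 0L
  split <- function(conds, level, tf_i) {
    v <- tf_mat[tf_i, conds]
    if (level >= depth || length(unique(v)) < 2 ||
        leaf_counter >= length(leaf_means) - 1L) {
      leaf_counter <<- leaf_counter + 1L
      mean_vec[conds] <<- leaf_means[leaf_counter]
      return(list(type = "leaf", mean = leaf_means[leaf_counter],
                  conditions = conds))
    }
    thr <- stats::median(v)
    left <- conds[v < thr]
    right <- conds[v >= thr]
    if (!length(left) || !length(right)) {
      leaf_counter <<- leaf_counter + 1L
      mean_vec[conds] <<- leaf_means[leaf_counter]
      return(list(type = "leaf", mean = leaf_means[leaf_counter],
                  conditions = conds))
    }
    next_tf <- if (tf_i < nrow(tf_mat)) tf_i + 1L else tf_i
    list(type = "split", tf = rownames(tf_mat)[tf_i], threshold = thr,
         left = split(left, level + 1L, next_tf),
         right = split(right, level + 1L, next_tf))
  }
  root <- split(conds, 0L, 1L)
  list(root = root, condition_means = mean_vec)
}

#' Simulate expression data with planted regulatory modules
#'
#' Transcription-factor profiles are independent standard normal draws per
#' condition. Each module's condition means follow a ground-truth threshold
#' tree of depth <= `depth` over the module's own TFs, with leaf means spaced
#' `leaf_sep * noise_sd` apart; member profiles are the module means plus
#' Gaussian noise of sd `noise_sd`.
#'
#' @param n_modules Number of planted modules.
#' @param genes_per_module Member genes per module.
#' @param tfs_per_module TFs per module (distinct across modules).
#' @param n_conditions Number of conditions (columns).
#' @param noise_sd Member-gene noise standard deviation.
#' @param leaf_sep Spacing of adjacent leaf means in units of `noise_sd`.
#' @param depth Ground-truth tree depth (<= 2 recommended).
#' @param seed Integer seed.
#' @return List with `expr` (tibble of targets + TFs), `tf_ids`, `truth`
#'   (tibble `gene_id`, `module_id`), `truth_trees` and `condition_means`
#'   (modules x conditions matrix).
#' @export
simulate_regulatory <- function(n_modules = 3, genes_per_module = 25,
                                tfs_per_module = 2, n_conditions = 12,
                                noise_sd = 0.2, leaf_sep = 4, depth = 2,
                                seed = 1) {
  with_seed(seed, {
    n_tfs <- n_modules * tfs_per_module
    tf_ids <- sprintf("tf%02d", seq_len(n_tfs))
    tf_mat <- matrix(stats::rnorm(n_tfs * n_conditions), nrow = n_tfs,
                     dimnames = list(tf_ids, NULL))
    n_leaves <- 2^depth
    base_means <- (seq_len(n_leaves) - (n_leaves + 1) / 2) *
      leaf_sep * noise_sd
    truth_trees <- list()
    cond_means <- matrix(0, n_modules, n_conditions)
    profiles <- matrix(0, n_modules * genes_per_module, n_conditions)
    gene_ids <- character(nrow(profiles))
    module_of <- integer(nrow(profiles))
    for (m in seq_len(n_modules)) {
      own <- tf_mat[((m - 1) * tfs_per_module + 1):(m * tfs_per_module), ,
                    drop = FALSE]
      tt <- truth_tree(own, depth, sample(base_means))
      truth_trees[[m]] <- tt
      cond_means[m, ] <- tt$condition_means
      for (g in seq_len(genes_per_module)) {
        i <- (m - 1) * genes_per_module + g
        gene_ids[i] <- sprintf("m%02dg%03d", m, g)
        module_of[i] <- m
        profiles[i, ] <- tt$condition_means +
          stats::rnorm(n_conditions, 0, noise_sd)
      }
    }
    cond_names <- sprintf("cond%02d", seq_len(n_conditions))
    to_tbl <- function(mat, ids) {
      tbl <- tibble::as_tibble(as.data.frame(mat),
                               .name_repair = "minimal")
      names(tbl) <- cond_names
      dplyr::bind_cols(tibble::tibble(gene_id = ids), tbl)
    }
    list(
      expr = dplyr::bind_rows(to_tbl(profiles, gene_ids),
                              to_tbl(tf_mat, tf_ids)),
      tf_ids = tf_ids,
      truth = tibble::tibble(gene_id = gene_ids, module_id = module_of),
      truth_trees = truth_trees,
      condition_means = cond_means
    )
  })
}
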