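expr_tbl <- function(mat, ids) {
  tbl <- tibble::as_tibble(as.data.frame(mat), .name_repair = "minimal")
  names(tbl) <- sprintf("c%02d", seq_len(ncol(mat)))
  dplyr::bind_cols(tibble::tibble(gene_id = ids), tbl)
}

test_that("require_tfs intersects and errors when no TF is differentially expressed", {
  expect_equal(require_tfs(c("a", "t1", "b"), c("t1", "t2")), "t1")
  expect_setequal(require_tfs(c("t1", "t2"), c("t1", "t2")), c("t1", "t2"))
  expect_error(require_tfs(c("a", "b"), c("t1")),
               class = "countnet_no_tf_error")
})

test_that("kmeans_init is deterministic and recovers separated blobs", {
  set.seed(1)
  blob1 <- matrix(rnorm(10 * 6, mean = 0), 10, 6)
  blob2 <- matrix(rnorm(8 * 6, mean = 0), 8, 6)
  blob1 <- t(apply(blob1, 1, function(r) r + c(5, 5, 5, -5, -5, -5)))
  blob2 <- t(apply(blob2, 1, function(r) r + c(-5, -5, -5, 5, 5, 5)))
  m <- rbind(blob1, blob2)
  rownames(m) <- sprintf("g%02d", 1:18)
  a1 <- kmeans_init(m, K = 2, seed = 7)
  a2 <- kmeans_init(m, K = 2, seed = 7)
  expect_identical(a1, a2)
  expect_equal(adjusted_rand_index(a1, rep(1:2, c(10, 8))), 1)

  all_one <- kmeans_init(m, K = 1, seed = 7)
  expect_true(all(all_one == 1L))

  expect_warning(big_k <- kmeans_init(m[1:3, ], K = 10, seed = 1),
                 "reduced")
  expect_lte(max(big_k), 3)
})

test_that("learn_tree splits on an informative TF and not otherwise", {
  # 0 TFs: single leaf at the grand mean
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
              dimnames = list("g1", NULL))
  tf0 <- matrix(numeric(0), nrow = 0, ncol = 6)
  t0 <- learn_tree(m, tf0)
  expect_length(t0$leaves, 1)
  expect_equal(t0$leaves[[1]]$mu, mean(m))
  expect_equal(t0$used_tfs, character(0))

  # a TF that perfectly bisects low-mean and high-mean conditions
  members <- matrix(rep(c(-2, -2, -2, 2, 2, 2), each = 3), nrow = 3,
                    byrow = FALSE, dimnames = list(paste0("g", 1:3), NULL))
  tf <- matrix(c(0.1, 0.2, 0.3, 0.8, 0.9, 1.0), nrow = 1,
               dimnames = list("tfA", NULL))
  tr <- learn_tree(members, tf, max_depth = 2)
  expect_equal(tr$root$type, "split")
  expect_equal(tr$root$tf, "tfA")
  expect_equal(sort(vapply(tr$leaves, `[[`, numeric(1), "mu")), c(-2, 2))
  expect_equal(tr$used_tfs, "tfA")

  # constant member expression: no positive gain, sigma2 at the floor
  const <- matrix(1, nrow = 2, ncol = 6,
                  dimnames = list(paste0("g", 1:2), NULL))
  tc <- learn_tree(const, tf, max_depth = 3, var_floor = 1e-6)
  expect_length(tc$leaves, 1)
  expect_equal(tc$leaves[[1]]$sigma2, 1e-6)
})

test_that("tree routing partitions the conditions", {
  reg <- simulate_regulatory(n_modules = 2, genes_per_module = 10,
                             n_conditions = 10, seed = 31)
  expr <- reg$expr
  targets <- expr[!expr$gene_id %in% reg$tf_ids, ]
  tfs <- expr[expr$gene_id %in% reg$tf_ids, ]
  tr <- learn_tree(targets, tfs, max_depth = 3)
  # every condition reaches exactly one leaf
  expect_equal(sort(unlist(lapply(tr$leaves, `[[`, "conditions"))), 1:10)
  expect_true(all(tr$cond_leaf >= 1 & tr$cond_leaf <= length(tr$leaves)))
  expect_length(tr$cond_mu, 10)
})

test_that("gene_log_likelihood matches the per-condition Gaussian sum", {
  reg <- simulate_regulatory(n_modules = 2, genes_per_module = 8,
                             n_conditions = 8, seed = 17)
  targets <- reg$expr[!reg$expr$gene_id %in% reg$tf_ids, ]
  tfs <- reg$expr[reg$expr$gene_id %in% reg$tf_ids, ]
  tr <- learn_tree(targets, tfs, max_depth = 2)
  set.seed(4)
  profile <- rnorm(8)
  manual <- sum(vapply(seq_len(8), function(cond) {
    leaf <- tr$leaves[[tr$cond_leaf[cond]]]
    dnorm(profile[cond], leaf$mu, sqrt(leaf$sigma2), log = TRUE)
  }, numeric(1)))
  expect_equal(gene_log_likelihood(profile, tr), manual)

  # a profile sitting exactly on the leaf means maximises the likelihood
  at_means <- gene_log_likelihood(tr$cond_mu, tr)
  expect_gte(at_means, gene_log_likelihood(tr$cond_mu + 0.05, tr))

  expect_error(gene_log_likelihood(rnorm(5), tr),
               class = "countnet_shape_error")
})

test_that("reassignment sends genes to the best-explaining module", {
  reg <- simulate_regulatory(n_modules = 2, genes_per_module = 10,
                             n_conditions = 12, noise_sd = 0.1, seed = 5)
  targets <- reg$expr[!reg$expr$gene_id %in% reg$tf_ids, ]
  tfs <- reg$expr[reg$expr$gene_id %in% reg$tf_ids, ]
  trees <- lapply(1:2, function(m) {
    members <- targets[reg$truth$module_id == m, ]
    learn_tree(members, tfs, max_depth = 2)
  })
  # a fresh gene generated from module 2's means lands in module 2
  probe <- expr_tbl(matrix(trees[[2]]$cond_mu + rnorm(12, 0, 0.01), 1),
                    "probe")
  names(probe) <- names(targets)
  expect_equal(reassign_genes(probe, trees)$module_id, 2L)

  # identical trees: ties break to the lowest module id
  same <- reassign_genes(targets, list(trees[[1]], trees[[1]]))
  expect_true(all(same$module_id == 1L))

  # a single tree takes everything
  expect_true(all(reassign_genes(targets, trees[1])$module_id == 1L))

  # all planted genes return home under their true trees
  home <- reassign_genes(targets, trees)
  expect_equal(home$module_id, reg$truth$module_id)
})

test_that("gnet_fit converges with a monotone log-likelihood trace", {
  for (s in 1:5) {
    reg <- simulate_regulatory(n_modules = 4, genes_per_module = 15,
                               noise_sd = 0.8, leaf_sep = 1, seed = s)
    fit <- gnet_fit(reg$expr, reg$tf_ids, K = 6, seed = s)
    expect_true(all(diff(fit$trace) >= -1e-8))
    expect_true(fit$converged)
  }
})

test_that("gnet_fit with max_iter = 0 returns the K-means clustering", {
  reg <- simulate_regulatory(n_modules = 3, genes_per_module = 12, seed = 8)
  targets <- reg$expr[!reg$expr$gene_id %in% reg$tf_ids, ]
  fit0 <- gnet_fit(reg$expr, reg$tf_ids, K = 3, max_iter = 0, seed = 8)
  km <- kmeans_init(targets, K = 3, seed = 8)
  expect_equal(fit0$assignment$module_id, unname(km))
  expect_equal(fit0$iterations, 0L)
  expect_length(fit0$trace, 1)
})

test_that("gnet_fit recovers planted modules and is deterministic", {
  reg <- simulate_regulatory(n_modules = 3, genes_per_module = 20,
                             noise_sd = 0.1, leaf_sep = 6, seed = 12)
  fit <- gnet_fit(reg$expr, reg$tf_ids, K = 3, seed = 12)
  td <- tidy(fit)
  truth <- reg$truth$module_id[match(td$gene_id, reg$truth$gene_id)]
  expect_equal(adjusted_rand_index(td$module_id, truth), 1)

  fit2 <- gnet_fit(reg$expr, reg$tf_ids, K = 3, seed = 12)
  expect_identical(fit$assignment, fit2$assignment)
  expect_identical(fit$modules, fit2$modules)
  expect_identical(fit$trace, fit2$trace)

  g <- glance(fit)
  expect_equal(g$n_modules, nrow(fit$modules))
  expect_equal(g$n_genes, 60L)
})

test_that("module correlation scores behave at the extremes", {
  base <- matrix(rnorm(8), nrow = 1)
  identical3 <- rbind(base, base, base)
  rownames(identical3) <- paste0("g", 1:3)
  expect_equal(as.numeric(module_correlation(identical3)), 1)

  pair <- rbind(base, -base)
  rownames(pair) <- c("g1", "g2")
  expect_equal(as.numeric(module_correlation(pair)), -1)

  single <- base
  rownames(single) <- "g1"
  sc <- module_correlation(single)
  expect_equal(as.numeric(sc), 1)
  expect_true(attr(sc, "flagged"))

  flat <- rbind(base, matrix(1, 1, 8))
  rownames(flat) <- c("g1", "g2")
  fc <- module_correlation(flat)
  expect_equal(as.numeric(fc), 0)
  expect_true(attr(fc, "flagged"))

  set.seed(99)
  noise <- matrix(rnorm(10 * 50), nrow = 10,
                  dimnames = list(paste0("g", 1:10), NULL))
  expect_lt(abs(as.numeric(module_correlation(noise))), 0.3)
})

test_that("network export enumerates TF x member pairs per module", {
  # module shaped like the showcase figure: 3 TFs regulating 21 genes
  fig_fit <- structure(list(
    modules = tibble::tibble(module_id = 1L, n_genes = 21L, n_tfs = 3L,
                             tfs = "tf1,tf2,tf3", correlation_score = 0.85,
                             log_likelihood = 0),
    trees = list(`1` = list(used_tfs = c("tf1", "tf2", "tf3"))),
    assignment = tibble::tibble(gene_id = sprintf("g%02d", 1:21),
                                module_id = 1L)
  ), class = "gnet_fit")
  edges <- export_network(fig_fit, top_n = 1)
  expect_equal(nrow(edges), 63L)
  expect_equal(attr(edges, "n_tf_nodes"), 3L)
  expect_equal(attr(edges, "n_gene_nodes"), 21L)

  # a single-leaf tree (no TFs used) contributes no edges
  leaf_fit <- fig_fit
  leaf_fit$trees <- list(`1` = list(used_tfs = character(0)))
  expect_warning(none <- export_network(leaf_fit, top_n = 2), "using all")
  expect_equal(nrow(none), 0L)

  # edge count equals the brute-force double loop on a fitted model
  reg <- simulate_regulatory(n_modules = 3, genes_per_module = 15, seed = 44)
  fit <- gnet_fit(reg$expr, reg$tf_ids, K = 3, seed = 44)
  net <- export_network(fit, top_n = 3)
  brute <- 0L
  for (m in fit$modules$module_id) {
    tfs <- fit$trees[[as.character(m)]]$used_tfs
    members <- fit$assignment$gene_id[fit$assignment$module_id == m]
    for (tf in tfs) for (g in members) if (tf != g) brute <- brute + 1L
  }
  expect_equal(nrow(net), brute)
  expect_equal(attr(net, "n_edges"), brute)
})
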