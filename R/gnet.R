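#' Usable transcription factors for network learning
#'
#' Module-network learning needs at least one transcription factor among the
#' differentially expressed genes; the usable set is the intersection of the
#' DE genes with the TF list. An empty intersection raises a
#' `countnet_no_tf_error`, which the pipeline catches to skip the network
#' stage gracefully.
#'
#' @param de_genes Character vector of DE genes.
#' @param tf_list Character vector of known transcription-factor gene ids.
#' @return Character vector of usable TFs.
#' @export
require_tfs <- function(de_genes, tf_list) {
  usable <- intersect(unique(as.character(tf_list)),
                      unique(as.character(de_genes)))
  if (!length(usable)) {
    stop_countnet(
      "no transcription factor among the differentially expressed genes; network learning needs at least one",
      class = "countnet_no_tf_error"
    )
  }
  usable
}

expr_to_matrix <- function(expr) {
  m <- as.matrix(expr[expr_columns(expr)])
  rownames(m) <- expr$gene_id
  storage.mode(m) <- "double"
  m
}

zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sdev <- apply(m, 1, stats::sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  (m - mu) / sdev
}

#' Log-transform an expression table for network learning
#'
#' Applies `log2(x + 1)` to every expression column; module trees are learned
#' on this scale.
#'
#' @param expr Tibble with `gene_id` plus numeric expression columns.
#' @return Tibble of the same shape.
#' @export
log2_transform <- function(expr) {
  out <- expr
  for (col in expr_columns(expr)) out[[col]] <- log2(expr[[col]] + 1)
  out
}

#' K-means initialization of gene clusters
#'
#' Clusters gene-wise standardized (z-scored) expression profiles with
#' Euclidean K-means, deterministically for a given seed. When fewer genes
#' (or fewer distinct profiles) than `K` are available, `K` is reduced with a
#' warning.
#'
#' @param expr Tibble (`gene_id` + expression columns) or numeric matrix with
#'   gene row names.
#' @param K Number of clusters.
#' @param seed Integer seed.
#' @return Named integer vector of cluster labels (1..K).
#' @export
kmeans_init <- function(expr, K, seed = 1) {
  m <- if (is.matrix(expr)) expr else expr_to_matrix(expr)
  z <- zscore_rows(m)
  k_max <- nrow(unique(round(z, 10)))
  if (K > k_max) {
    warn(sprintf("K reduced from %d to %d (distinct gene profiles)", K, k_max))
    K <- k_max
  }
  if (K == 1L || ncol(z) == 0) {
    assignment <- rep(1L, nrow(m))
  } else if (K >= nrow(m)) {
    # stats::kmeans requires centers < nrow; K = n is the trivial partition
    assignment <- seq_len(nrow(m))
  } else {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    km <- stats::kmeans(z, centers = K, nstart = 10, iter.max = 50)
    assignment <- as.integer(km$cluster)
  }
  names(assignment) <- rownames(m)
  assignment
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

pooled_gaussian <- function(x, var_floor) {
  n <- length(x)
  if (!n) return(list(mu = 0, sigma2 = var_floor, ll = 0, n = 0L))
  mu <- mean(x)
  sigma2 <- max(sum((x - mu)^2) / n, var_floor)
  list(mu = mu, sigma2 = sigma2,
       ll = sum(stats::dnorm(x, mu, sqrt(sigma2), log = TRUE)), n = n)
}

#' Learn a binary TF decision tree for one gene cluster
#'
#' Greedy top-down growth over the experimental conditions: at each node the
#' candidate splits are (TF, threshold) pairs with thresholds at midpoints
#' between consecutive distinct TF expression values in the node's
#' conditions; conditions with TF expression below the threshold go left,
#' the rest right. The chosen split maximizes the gain in pooled Gaussian
#' log-likelihood of the member genes' expression values; growth stops at
#' `max_depth`, when a side would be empty, or when no split has positive
#' gain. Each leaf stores the maximum-likelihood mean and variance (floored
#' at `var_floor`) of all member-gene values over its conditions.
#'
#' @param member_expr Expression of the cluster's member genes: tibble
#'   (`gene_id` + condition columns) or matrix (genes x conditions).
#' @param tf_expr Expression of candidate transcription factors, same
#'   condition columns (may have zero rows: a single-leaf tree results).
#' @param max_depth Maximum tree depth (0 = single leaf).
#' @param var_floor Variance floor for leaf models.
#' @return Object of class `regulatory_tree`: the split structure, the leaf
#'   table, per-condition routed means/variances and the TFs used.
#' @export
learn_tree <- function(member_expr, tf_expr, max_depth = 3, var_floor = 1e-6) {
  m <- if (is.matrix(member_expr)) member_expr else expr_to_matrix(member_expr)
  tf <- if (is.matrix(tf_expr)) tf_expr else expr_to_matrix(tf_expr)
  n_cond <- ncol(m)
  if (!n_cond) {
    stop_countnet("need at least one condition", class = "countnet_validation_error")
  }
  leaves <- list()
  cond_leaf <- integer(n_cond)

  grow <- function(conds, depth) {
    x <- as.vector(m[, conds, drop = FALSE])
    node <- pooled_gaussian(x, var_floor)
    best <- NULL
    if (depth < max_depth && length(conds) >= 2 && nrow(tf) >= 1 &&
        length(x) > 0) {
      for (tf_i in seq_len(nrow(tf))) {
        v <- tf[tf_i, conds]
        sv <- sort(unique(v))
        if (length(sv) < 2) next
        for (thr in (sv[-length(sv)] + sv[-1]) / 2) {
          left <- conds[v < thr]
          right <- conds[v >= thr]
          gain <- pooled_gaussian(as.vector(m[, left, drop = FALSE]), var_floor)$ll +
            pooled_gaussian(as.vector(m[, right, drop = FALSE]), var_floor)$ll -
            node$ll
          if (gain > 0 && (is.null(best) || gain > best$gain)) {
            best <- list(tf = rownames(tf)[tf_i], threshold = thr,
                         left = left, right = right, gain = gain)
          }
        }
      }
    }
    if (is.null(best)) {
      leaf_id <- length(leaves) + 1L
      leaves[[leaf_id]] <<- list(mu = node$mu, sigma2 = node$sigma2,
                                 n = node$n, conditions = conds)
      cond_leaf[conds] <<- leaf_id
      return(list(type = "leaf", leaf = leaf_id))
    }
    list(type = "split", tf = best$tf, threshold = best$threshold,
         left = grow(best$left, depth + 1L),
         right = grow(best$right, depth + 1L))
  }
  root <- grow(seq_len(n_cond), 0L)
  tree_finalize(root, leaves, cond_leaf, n_cond)
}

tree_finalize <- function(root, leaves, cond_leaf, n_cond) {
  used <- character()
  walk <- function(node) {
    if (node$type == "split") {
      used <<- union(used, node$tf)
      walk(node$left); walk(node$right)
    }
  }
  walk(root)
  mu <- vapply(leaves, `[[`, numeric(1), "mu")
  s2 <- vapply(leaves, `[[`, numeric(1), "sigma2")
  structure(
    list(root = root, leaves = leaves, cond_leaf = cond_leaf,
         cond_mu = mu[cond_leaf], cond_sigma2 = s2[cond_leaf],
         used_tfs = used, n_conditions = n_cond),
    class = "regulatory_tree"
  )
}

# Re-estimate leaf parameters of an existing tree structure on new member
# genes. Routing depends only on TF profiles, so the leaf condition sets are
# unchanged and this is exact constrained maximum likelihood -- it can only
# improve the in-cluster likelihood relative to the stale parameters.
reestimate_tree <- function(tree, member_mat, var_floor = 1e-6) {
  leaves <- lapply(tree$leaves, function(leaf) {
    fit <- pooled_gaussian(as.vector(member_mat[, leaf$conditions, drop = FALSE]),
                           var_floor)
    list(mu = fit$mu, sigma2 = fit$sigma2, n = fit$n,
         conditions = leaf$conditions)
  })
  tree_finalize(tree$root, leaves, tree$cond_leaf, tree$n_conditions)
}

#' Log-likelihood of one gene's profile under a regulatory tree
#'
#' Each condition is routed through the tree by its TF expression values
#' (precomputed at fit time); the value is the sum over conditions of the log
#' Gaussian density at the routed leaf's mean and variance.
#'
#' @param profile Numeric vector, one value per condition.
#' @param tree A `regulatory_tree`.
#' @return A single number.
#' @export
gene_log_likelihood <- function(profile, tree) {
  if (length(profile) != tree$n_conditions) {
    stop_countnet(
      sprintf("profile length %d does not match the tree's %d conditions",
              length(profile), tree$n_conditions),
      class = "countnet_shape_error"
    )
  }
  sum(stats::dnorm(profile, tree$cond_mu, sqrt(tree$cond_sigma2), log = TRUE))
}

members_log_likelihood <- function(member_mat, tree) {
  if (!nrow(member_mat)) return(0)
  g <- nrow(member_mat)
  sum(stats::dnorm(member_mat,
                   rep(tree$cond_mu, each = g),
                   rep(sqrt(tree$cond_sigma2), each = g), log = TRUE))
}

ll_by_module <- function(mat, trees) {
  vapply(trees, function(tr) {
    apply(mat, 1, gene_log_likelihood, tree = tr)
  }, numeric(nrow(mat)))
}

reassign_core <- function(mat, trees, active, min_module_size) {
  ll <- matrix(-Inf, nrow(mat), length(trees))
  for (k in which(active)) {
    ll[, k] <- apply(mat, 1, gene_log_likelihood, tree = trees[[k]])
  }
  assignment <- max.col(ll, ties.method = "first")
  repeat {
    sizes <- tabulate(assignment, nbins = length(trees))
    sizes[!active] <- NA
    small <- which(!is.na(sizes) & sizes < min_module_size)
    if (!length(small) || sum(active) <= 1L) break
    victim <- small[which.min(sizes[small])]
    active[victim] <- FALSE
    ll[, victim] <- -Inf
    moving <- which(assignment == victim)
    if (length(moving)) {
      assignment[moving] <- max.col(ll[moving, , drop = FALSE],
                                    ties.method = "first")
    }
  }
  list(assignment = assignment, active = active)
}

#' Reassign genes to the modules whose trees best explain them
#'
#' Each gene goes to the module maximizing [gene_log_likelihood()] (ties to
#' the lowest module id). Modules ending up smaller than `min_module_size`
#' are dissolved, their members redistributed to the next-best surviving
#' module.
#'
#' @param expr Tibble (`gene_id` + condition columns) or matrix of the genes
#'   to assign.
#' @param trees List of `regulatory_tree` objects (module id = position).
#' @param min_module_size Minimum surviving module size; default 1 (no
#'   dissolution).
#' @return Tibble with `gene_id`, `module_id`.
#' @export
reassign_genes <- function(expr, trees, min_module_size = 1) {
  if (!length(trees)) {
    stop_countnet("need at least one tree", class = "countnet_validation_error")
  }
  mat <- if (is.matrix(expr)) expr else expr_to_matrix(expr)
  res <- reassign_core(mat, trees, rep(TRUE, length(trees)), min_module_size)
  tibble::tibble(gene_id = rownames(mat), module_id = res$assignment)
}

#' Mean pairwise expression correlation of a module
#'
#' The module score is the mean Pearson correlation over all pairs of member
#' profiles across conditions. A module with fewer than two members scores
#' 1.0 by convention and is flagged; pairs involving a zero-variance profile
#' contribute 0 and set the flag.
#'
#' @param member_expr Tibble or matrix of member profiles (genes x conditions).
#' @return Numeric score in \[-1, 1\] with attribute `flagged`.
#' @export
module_correlation <- function(member_expr) {
  m <- if (is.matrix(member_expr)) member_expr else expr_to_matrix(member_expr)
  if (nrow(m) < 2) {
    return(structure(1.0, flagged = TRUE))
  }
  cors <- suppressWarnings(stats::cor(t(m)))
  vals <- cors[upper.tri(cors)]
  flagged <- anyNA(vals)
  vals[is.na(vals)] <- 0
  structure(mean(vals), flagged = flagged)
}

#' Learn regulatory modules by iterated tree fitting and gene reassignment
#'
#' Non-TF genes are clustered by K-means on z-scored profiles, then the loop
#' alternates (1) fitting a TF decision tree per module ([learn_tree()]) and
#' (2) reassigning every gene to the module whose tree gives it the highest
#' log-likelihood, until the relative improvement in total log-likelihood
#' falls below `rel_tol` or `max_iter` is reached. Each refit keeps the
#' better of the fresh greedy tree and the previous structure with leaf
#' parameters re-estimated, which makes the recorded log-likelihood trace
#' non-decreasing (up to small-module dissolution).
#'
#' @param expr Tibble (`gene_id` + condition columns) holding both target
#'   genes and TFs, typically log2-transformed RPKM per replicate
#'   ([log2_transform()]).
#' @param tf_ids Transcription factors among the rows of `expr`; rows not in
#'   `tf_ids` are the clustered target genes.
#' @param K Number of initial clusters; default `max(2, floor(n/20))` capped
#'   at 10.
#' @param max_depth Maximum tree depth; default 3.
#' @param max_iter Maximum refit/reassign iterations; default 100. `0`
#'   returns the K-means clusters with their initial trees.
#' @param rel_tol Relative log-likelihood convergence tolerance; default 1e-6.
#' @param seed Integer seed (K-means initialization).
#' @param min_module_size Modules smaller than this are dissolved; default 2.
#' @param var_floor Leaf variance floor; default 1e-6.
#' @return Object of class `gnet_fit` with elements `modules` (summary
#'   tibble incl. correlation scores), `assignment`, `trees`, `trace`
#'   (log-likelihood per recorded step), `iterations`, `converged`, `expr`,
#'   `tf_ids` and `config`.
#' @export
gnet_fit <- function(expr, tf_ids, K = NULL, max_depth = 3, max_iter = 100,
                     rel_tol = 1e-6, seed = 1, min_module_size = 2,
                     var_floor = 1e-6) {
  tf_ids <- intersect(unique(as.character(tf_ids)), expr$gene_id)
  if (!length(tf_ids)) {
    stop_countnet("no transcription factor has an expression profile",
                  class = "countnet_no_tf_error")
  }
  targets <- expr[!expr$gene_id %in% tf_ids, ]
  if (!nrow(targets)) {
    stop_countnet("no target genes left after removing TFs",
                  class = "countnet_validation_error")
  }
  mat <- expr_to_matrix(targets)
  tf_mat <- expr_to_matrix(expr[expr$gene_id %in% tf_ids, ])
  if (is.null(K)) K <- min(max(2L, floor(nrow(mat) / 20)), 10L)

  assignment <- kmeans_init(mat, K, seed = seed)
  K <- max(assignment)
  fit_trees <- function(assignment, active, previous = NULL) {
    lapply(seq_len(length(active)), function(k) {
      if (!active[k]) return(previous[[k]])
      members <- mat[assignment == k, , drop = FALSE]
      greedy <- learn_tree(members, tf_mat, max_depth = max_depth,
                           var_floor = var_floor)
      if (is.null(previous) || is.null(previous[[k]])) return(greedy)
      reest <- reestimate_tree(previous[[k]], members, var_floor = var_floor)
      if (members_log_likelihood(members, greedy) >=
          members_log_likelihood(members, reest)) greedy else reest
    })
  }
  total_ll <- function(assignment, trees, active) {
    sum(vapply(which(active), function(k) {
      members_log_likelihood(mat[assignment == k, , drop = FALSE], trees[[k]])
    }, numeric(1)))
  }

  active <- rep(TRUE, K)
  trees <- fit_trees(assignment, active)
  trace <- total_ll(assignment, trees, active)
  iterations <- 0L
  converged <- FALSE
  if (max_iter > 0) {
    for (it in seq_len(max_iter)) {
      step <- reassign_core(mat, trees, active, min_module_size)
      assignment <- step$assignment
      active <- step$active
      ll <- total_ll(assignment, trees, active)
      trace <- c(trace, ll)
      iterations <- it
      prev <- trace[length(trace) - 1]
      if (abs(ll - prev) <= rel_tol * max(1, abs(prev))) {
        converged <- TRUE
        break
      }
      trees <- fit_trees(assignment, active, previous = trees)
    }
    # final refit so the returned trees describe the returned modules
    trees <- fit_trees(assignment, active, previous = trees)
    trace <- c(trace, total_ll(assignment, trees, active))
  }

  keep <- which(active)
  new_id <- match(seq_along(active), keep)
  module_ids <- new_id[assignment]
  trees_out <- trees[keep]
  names(trees_out) <- as.character(seq_along(keep))

  modules <- purrr::map_dfr(seq_along(keep), function(m) {
    members <- mat[module_ids == m, , drop = FALSE]
    score <- module_correlation(members)
    tr <- trees_out[[m]]
    tibble::tibble(
      module_id = m,
      n_genes = nrow(members),
      n_tfs = length(tr$used_tfs),
      tfs = paste(tr$used_tfs, collapse = ","),
      correlation_score = as.numeric(score),
      log_likelihood = members_log_likelihood(members, tr)
    )
  })

  structure(
    list(
      modules = modules,
      assignment = tibble::tibble(gene_id = rownames(mat),
                                  module_id = module_ids),
      trees = trees_out,
      trace = trace,
      iterations = iterations,
      converged = converged,
      expr = targets,
      tf_expr = expr[expr$gene_id %in% tf_ids, ],
      tf_ids = tf_ids,
      config = list(K = K, max_depth = max_depth, max_iter = max_iter,
                    rel_tol = rel_tol, seed = seed,
                    min_module_size = min_module_size, var_floor = var_floor)
    ),
    class = "gnet_fit"
  )
}

#' Export the global TF-to-gene regulatory network
#'
#' Takes the `top_n` modules ranked by expression correlation score and emits
#' one edge per (TF used in the module's tree) x (member gene) pair;
#' self-edges are dropped. Node roles: TFs are regulators, members are
#' targets.
#'
#' @param fit A `gnet_fit`.
#' @param top_n Number of top modules to export; default 10.
#' @return Tibble with `tf_id`, `gene_id`, `module_id`, ordered (module, TF,
#'   gene); attributes `n_tf_nodes`, `n_gene_nodes`, `n_edges`.
#' @export
export_network <- function(fit, top_n = 10) {
  modules <- fit$modules %>%
    dplyr::arrange(dplyr::desc(.data$correlation_score), .data$module_id)
  if (top_n > nrow(modules)) {
    warn(sprintf("top_n (%d) exceeds the number of modules (%d); using all",
                 top_n, nrow(modules)))
    top_n <- nrow(modules)
  }
  selected <- modules$module_id[seq_len(top_n)]
  edges <- purrr::map_dfr(selected, function(m) {
    tfs <- fit$trees[[as.character(m)]]$used_tfs
    members <- fit$assignment$gene_id[fit$assignment$module_id == m]
    if (!length(tfs) || !length(members)) return(NULL)
    tidyr::expand_grid(tf_id = tfs, gene_id = members) %>%
      dplyr::filter(.data$tf_id != .data$gene_id) %>%
      dplyr::mutate(module_id = m)
  })
  if (!nrow(edges)) {
    edges <- tibble::tibble(tf_id = character(), gene_id = character(),
                            module_id = integer())
  }
  edges <- dplyr::arrange(edges, .data$module_id, .data$tf_id, .data$gene_id)
  attr(edges, "n_tf_nodes") <- dplyr::n_distinct(edges$tf_id)
  attr(edges, "n_gene_nodes") <- dplyr::n_distinct(edges$gene_id)
  attr(edges, "n_edges") <- nrow(edges)
  edges
}

#' @export
print.regulatory_tree <- function(x, ...) {
  cat(format_tree(x), sep = "\n")
  invisible(x)
}

#' Indented-text rendering of a regulatory tree
#' @param tree A `regulatory_tree`.
#' @return Character vector, one line per node.
#' @export
format_tree <- function(tree) {
  fmt <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      leaf <- tree$leaves[[node$leaf]]
      sprintf("%sleaf: mu=%.4g sigma2=%.4g (%d conditions)",
              pad, leaf$mu, leaf$sigma2, length(leaf$conditions))
    } else {
      c(sprintf("%sif %s < %.4g:", pad, node$tf, node$threshold),
        fmt(node$left, indent + 1L),
        sprintf("%selse:", pad),
        fmt(node$right, indent + 1L))
    }
  }
  fmt(tree$root, 0L)
}

#' Structured (list) export of a regulatory tree, JSON-ready
#' @param tree A `regulatory_tree`.
#' @return A nested list mirroring the split structure.
#' @export
tree_to_list <- function(tree) {
  conv <- function(node) {
    if (node$type == "leaf") {
      leaf <- tree$leaves[[node$leaf]]
      list(type = "leaf", mu = leaf$mu, sigma2 = leaf$sigma2,
           conditions = leaf$conditions)
    } else {
      list(type = "split", tf = node$tf, threshold = node$threshold,
           left = conv(node$left), right = conv(node$right))
    }
  }
  conv(tree$root)
}

#' @export
print.gnet_fit <- function(x, ...) {
  cat(sprintf(
    "<gnet_fit> %d modules over %d genes, %d TFs available; %d iteration(s), %s\n",
    nrow(x$modules), nrow(x$assignment), length(x$tf_ids), x$iterations,
    if (x$converged) "converged" else "not converged"))
  print(x$modules)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-gene module assignments of a module-network fit
#' @param x A `gnet_fit`.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `module_id`, `correlation_score` of the
#'   gene's module.
#' @export
tidy.gnet_fit <- function(x, ...) {
  dplyr::left_join(x$assignment,
                   x$modules[c("module_id", "correlation_score")],
                   by = "module_id")
}

#' One-row summary of a module-network fit
#' @param x A `gnet_fit`.
#' @param ... Unused.
#' @return One-row tibble: module count, gene count, TFs used, total
#'   log-likelihood, iterations, convergence.
#' @export
glance.gnet_fit <- function(x, ...) {
  tibble::tibble(
    n_modules = nrow(x$modules),
    n_genes = nrow(x$assignment),
    n_tfs_used = dplyr::n_distinct(unlist(lapply(x$trees, `[[`, "used_tfs"))),
    log_likelihood = x$trace[length(x$trace)],
    iterations = x$iterations,
    converged = x$converged
  )
}
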