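# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# Benjamini-Hochberg step-up by the textbook definition:
# q_(i) = min_{j >= i} p_(j) * n / j, clipped to 1, in input order.
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    q_sorted[i] <- min(1, min(p[ord][i:n] * n / (i:n)))
  }
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

# Two-sided Fisher p by full enumeration of all tables with the observed
# margins, summing hypergeometric point probabilities <= observed (with the
# conventional 1 + 1e-7 relative tolerance).
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(x, r1, r2, c1)
  obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Interval-union length by per-base occupancy on a toy genome.
union_occupancy <- function(start0, end0, genome_size = 10000) {
  occupied <- logical(genome_size)
  for (i in seq_along(start0)) {
    occupied[(start0[i] + 1):end0[i]] <- TRUE
  }
  sum(occupied)
}

# Brute-force consensus voting: count memberships per gene directly.
consensus_bruteforce <- function(lists, min_support) {
  genes <- sort(unique(unlist(lists)))
  support <- vapply(genes, function(g) {
    sum(vapply(lists, function(l) g %in% l, logical(1)))
  }, numeric(1))
  sort(genes[support >= min_support])
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
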