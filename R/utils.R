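#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr %>%
NULL

# Round half away from zero (table-style rounding); base round() is
# round-half-even, which flips exact .xx5 ties.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_countnet <- function(message, class, ...) {
  abort(message, class = c(class, "countnet_error"), ...)
}

assert_prob <- function(x, what = "p-value") {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_countnet(
      sprintf("every %s must lie in [0, 1]", what),
      class = "countnet_domain_error"
    )
  }
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same objects;
#' 1 for identical partitions (up to relabelling), ~0 for independent ones.
#' Used to quantify recovery of planted regulatory modules.
#'
#' @param a,b Label vectors of equal length.
#' @return A single number in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
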