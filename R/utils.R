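# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global `.Random.seed`, so seeded package functions
#' do not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministically derive per-stage seeds from one root seed.
# Kept below 2^31 so they remain valid R integers.
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_named_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must be a matrix with row and column names")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones. Used to score recovery of planted co-occurrence modules.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

# Kruskal-Wallis H (tie-corrected) for every column of a matrix at once.
# Matches stats::kruskal.test; vectorized because ANCOM needs O(m^2) tests.
kw_stat_matrix <- function(Y, groups) {
  groups <- as.factor(groups)
  n <- nrow(Y)
  R <- apply(Y, 2, rank)
  if (!is.matrix(R)) R <- matrix(R, nrow = n)
  g <- as.integer(groups)
  ng <- tabulate(g)
  # sum of ranks per group per column
  S <- rowsum(R, g)                      # k x m
  H <- 12 / (n * (n + 1)) * colSums(S^2 / ng) - 3 * (n + 1)
  # tie correction per column
  ties <- apply(Y, 2, function(col) {
    t <- table(col)
    1 - sum(t^3 - t) / (n^3 - n)
  })
  H <- ifelse(ties > 0, H / ties, 0)
  p <- pchisq(H, df = nlevels(groups) - 1, lower.tail = FALSE)
  p[H == 0] <- 1
  list(H = H, p = p)
}
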