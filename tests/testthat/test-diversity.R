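test_that("Faith's PD matches path-union oracle and edge cases", {
  tr <- tree_from_text("((T1:1,T2:2):1,(T3:0.5,T4:0.5):3);")
  all_present <- toy_counts(matrix(1L, 1, 4))
  expect_equal(unname(faiths_pd(all_present, tr)), sum(tr$edge.length))
  one <- toy_counts(matrix(c(1L, 0L, 0L, 0L), 1))
  expect_equal(unname(faiths_pd(one, tr)), 2)  # root-to-T1 path

  for (seed in 1:6) {
    n <- sample(3:6, 1)
    tree <- random_binary_tree(n, seed)
    patterns <- expand.grid(rep(list(0:1), n))
    patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
    counts <- as.matrix(patterns)
    dimnames(counts) <- list(paste0("S", seq_len(nrow(counts))),
                             tree$tip.label)
    storage.mode(counts) <- "integer"
    got <- faiths_pd(counts, tree)
    want <- apply(counts, 1, function(row)
      oracle_faiths_pd(tree, tree$tip.label[row > 0]))
    expect_equal(unname(got), unname(want))
  }
  expect_error(faiths_pd(toy_counts(matrix(1L, 1, 2),
                                    taxa = c("T1", "ZZ")), tr), "ZZ")
})

test_that("unweighted UniFrac matches the per-edge oracle on exhaustive patterns", {
  tr <- tree_from_text("((T1:1,T2:1):1,(T3:1,T4:1):1);")
  same <- toy_counts(rbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L)))
  expect_equal(unname(unweighted_unifrac(same, tr)[1, 2]), 0)
  disjoint <- toy_counts(rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)))
  expect_equal(unname(unweighted_unifrac(disjoint, tr)[1, 2]), 1)

  for (seed in 7:10) {
    n <- sample(4:6, 1)
    tree <- random_binary_tree(n, seed)
    patterns <- expand.grid(rep(list(0:1), n))
    patterns <- as.matrix(patterns[rowSums(patterns) > 0, , drop = FALSE])
    dimnames(patterns) <- list(paste0("S", seq_len(nrow(patterns))),
                               tree$tip.label)
    storage.mode(patterns) <- "integer"
    d <- unweighted_unifrac(patterns, tree)
    pick <- utils::combn(nrow(patterns), 2)[, sample(
      ncol(utils::combn(nrow(patterns), 2)), 20)]
    for (k in seq_len(ncol(pick))) {
      i <- pick[1, k]; j <- pick[2, k]
      want <- oracle_unifrac(tree,
                             tree$tip.label[patterns[i, ] > 0],
                             tree$tip.label[patterns[j, ] > 0])
      expect_equal(unname(d[i, j]), want)
    }
  }
})

test_that("Bray-Curtis matches hand arithmetic", {
  x <- rbind(S1 = c(2, 1), S2 = c(1, 3), S3 = c(2, 1))
  colnames(x) <- c("a", "b")
  d <- bray_curtis(x)
  expect_equal(unname(d["S1", "S2"]), 3 / 7)
  expect_equal(unname(d["S1", "S3"]), 0)
  y <- rbind(S1 = c(1, 0), S2 = c(0, 1)); colnames(y) <- c("a", "b")
  expect_equal(unname(bray_curtis(y)[1, 2]), 1)
  z <- rbind(S1 = c(0, 0), S2 = c(0, 0)); colnames(z) <- c("a", "b")
  expect_error(bray_curtis(z), "all-zero")
})

test_that("PCoA reproduces Euclidean geometry and orders axes", {
  pts <- cbind(x = c(0, 3, 3, 0, 7), y = c(0, 0, 4, 4, 2))
  rownames(pts) <- paste0("S", 1:5)
  d <- as.matrix(dist(pts))
  ord <- pcoa(validate_distance_matrix(d))
  rec <- as.matrix(dist(ord$coordinates))
  expect_lt(max(abs(rec - d)), 1e-9)
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)

  # collinear points embed on one axis
  line <- matrix(c(0, 1, 4), dimnames = list(paste0("S", 1:3), NULL))
  dl <- as.matrix(dist(line))
  ol <- pcoa(validate_distance_matrix(dl))
  expect_equal(ncol(ol$coordinates), 1)
  expect_equal(as.numeric(dist(ol$coordinates)), c(1, 4, 3))
})

test_that("PERMANOVA separates planted groups and respects conventions", {
  # two groups of duplicated near-identical points, far apart; only a
  # permutation reproducing the true partition can match the observed F
  pts <- rbind(matrix(0, 6, 2), matrix(10, 6, 2)) +
    matrix(seq(-0.01, 0.01, length.out = 24), 12, 2)
  rownames(pts) <- paste0("S", 1:12)
  d <- as.matrix(dist(pts))
  g <- rep(c("A", "B"), each = 6)
  res <- permanova(d, g, n_perm = 99, seed = 1)
  expect_gt(res$pseudo_F, 100)
  expect_gte(res$p, 1 / (1 + 99))   # (1 + count) / (1 + n_perm) floor
  expect_lte(res$p, 0.05)
  expect_identical(permanova(d, g, n_perm = 99, seed = 5)$p,
                   permanova(d, g, n_perm = 99, seed = 5)$p)
  expect_error(permanova(d, c("A", rep("B", 11)), 99, 1), "n >= 2")
})

test_that("Kruskal-Wallis wrapper matches the rank formula and handles ties", {
  expect_equal(kruskal_wallis(rep(1, 9), rep(1:3, 3))$H, 0)
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b", "c"), each = 2)
  # direct formula, no ties: H = 12/(N(N+1)) * sum n_g rbar_g^2 - 3(N+1)
  H_hand <- 12 / (6 * 7) * 2 * (1.5^2 + 3.5^2 + 5.5^2) - 3 * 7
  expect_equal(kruskal_wallis(v, g)$H, H_hand)
  expect_equal(kruskal_wallis(v + 100, g)$H, kruskal_wallis(v, g)$H)
})

test_that("alpha regression gives exact fits and permutation-null slopes", {
  x <- 1:10
  y <- 2 * x + 1
  fit <- suppressWarnings(alpha_regression(y, x))  # exact fit
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_lt(max(fit$band$upr - fit$band$lwr), 1e-9)

  set.seed(10)
  yr <- rnorm(30); xr <- rnorm(30)
  slopes <- vapply(1:500, function(i)
    alpha_regression(yr, sample(xr))$slope, numeric(1))
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(500))
  expect_error(alpha_regression(yr, rep(1, 30)), "variance")
})

test_that("duplicating the data shrinks the regression CI by ~sqrt(2)", {
  set.seed(2)
  x <- rnorm(40); y <- x + rnorm(40)
  f1 <- alpha_regression(y, x)
  f2 <- alpha_regression(c(y, y), c(x, x))
  w1 <- mean(f1$band$upr - f1$band$lwr)
  w2 <- mean(f2$band$upr - f2$band$lwr)
  expect_equal(w1 / w2, sqrt(2), tolerance = 0.1)
})

test_that("ANOVA + Dunn matches hand computation and adjusts monotonically", {
  same <- rep(c(1, 2, 3), 3)           # every group is a copy of {1,2,3}
  expect_equal(anova_dunn(same, rep(c("a", "b", "c"), each = 3))$F, 0)
  res <- anova_dunn(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 13.5)
  expect_true(all(res$dunn$p_adj >= res$dunn$p_unadj))
})
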