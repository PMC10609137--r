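test_that("pairwise Pearson matches the covariance formula", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 7)
  X <- cbind(a = x, b = y, c = -x)
  rownames(X) <- paste0("S", 1:5)
  res <- pairwise_pearson(X)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r["a", "b"], r_hand)
  expect_equal(res$r["a", "a"], 1)
  expect_equal(res$r["a", "c"], -1)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res$p["a", "b"], 2 * pt(-abs(t_hand), 3))

  Xz <- cbind(X, d = rep(2, 5))
  resz <- pairwise_pearson(Xz)
  expect_true(all(is.na(resz$r["d", c("a", "b", "c")])))
})

test_that("edges require r > 0.5 AND p < 0.05, strictly, positive only", {
  feats <- c("a", "b", "c", "d")
  r <- diag(4); dimnames(r) <- list(feats, feats)
  p <- matrix(1, 4, 4, dimnames = list(feats, feats)); diag(p) <- 0
  r["a", "b"] <- r["b", "a"] <- 0.5;   p["a", "b"] <- p["b", "a"] <- 0.001
  r["a", "c"] <- r["c", "a"] <- 0.9;   p["a", "c"] <- p["c", "a"] <- 0.001
  r["b", "c"] <- r["c", "b"] <- -0.9;  p["b", "c"] <- p["c", "b"] <- 0.001
  r["a", "d"] <- r["d", "a"] <- 0.9;   p["a", "d"] <- p["d", "a"] <- 0.05
  g <- build_graph(r, p)
  expect_equal(nrow(g$edges), 1)
  expect_equal(sort(c(g$edges$node1, g$edges$node2)), c("a", "c"))
})

test_that("edge set is invariant to feature and sample ordering", {
  set.seed(9)
  X <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(paste0("S", 1:30), paste0("F", 1:8)))
  X[, 2] <- X[, 1] + rnorm(30, 0, 0.3)
  X[, 5] <- X[, 4] + rnorm(30, 0, 0.3)
  e1 <- with(pairwise_pearson(X), build_graph(r, p))$edges
  perm_f <- sample(8); perm_s <- sample(30)
  e2 <- with(pairwise_pearson(X[perm_s, perm_f]), build_graph(r, p))$edges
  key <- function(e) sort(paste(pmin(e$node1, e$node2),
                                pmax(e$node1, e$node2)))
  expect_identical(key(e1), key(e2))
})

test_that("Louvain recovers exact communities and the oracle's modularity", {
  tri2 <- data.frame(node1 = c("a", "b", "c", "d", "e", "f"),
                     node2 = c("b", "c", "a", "e", "f", "d"))
  tri2$r <- 0.9; tri2$p <- 0.001
  g <- structure(list(nodes = data.frame(node = letters[1:6],
                                         kind = "taxon"),
                      edges = tri2), class = "mblink_graph")
  part <- louvain(g, seed = 1)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(length(unique(part$membership[c("a", "b", "c")])), 1)
  expect_equal(length(unique(part$membership[c("d", "e", "f")])), 1)
  expect_equal(part$Q, oracle_max_modularity(tri2, letters[1:6]))

  # complete graph: a single module
  cg <- t(utils::combn(letters[1:5], 2))
  kedges <- data.frame(node1 = cg[, 1], node2 = cg[, 2], r = 0.9, p = 0.001)
  gk <- structure(list(nodes = data.frame(node = letters[1:5],
                                          kind = "taxon"),
                       edges = kedges), class = "mblink_graph")
  pk <- louvain(gk, seed = 1)
  expect_equal(length(unique(pk$membership)), 1)

  # random graphs up to 10 nodes vs exhaustive-partition oracle
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(5:10, 1)
    nodes <- paste0("v", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.35
    if (!any(keep)) keep[1] <- TRUE
    edges <- data.frame(node1 = pairs[keep, 1], node2 = pairs[keep, 2],
                        r = 0.9, p = 0.001)
    gr <- structure(list(nodes = data.frame(node = nodes, kind = "taxon"),
                         edges = edges), class = "mblink_graph")
    part <- louvain(gr, seed = seed, n_restarts = 20)
    expect_equal(part$Q, oracle_max_modularity(edges, nodes),
                 tolerance = 1e-9)
  }
})

test_that("isolated nodes become singleton modules and empty graphs work", {
  g <- structure(list(nodes = data.frame(node = c("a", "b", "c"),
                                         kind = "taxon"),
                      edges = data.frame(node1 = "a", node2 = "b",
                                         r = 0.9, p = 0.001)),
                 class = "mblink_graph")
  part <- louvain(g, seed = 2)
  expect_equal(unname(part$membership["a"]), unname(part$membership["b"]))
  expect_false(part$membership["c"] == part$membership["a"])
  e <- structure(list(nodes = data.frame(node = character(),
                                         kind = character()),
                      edges = data.frame(node1 = character(),
                                         node2 = character(),
                                         r = numeric(), p = numeric())),
                 class = "mblink_graph")
  expect_equal(length(louvain(e, seed = 1)$membership), 0)
})

test_that("module abundances sum taxon relative abundances only", {
  counts <- toy_counts(rbind(c(10L, 10L, 80L), c(0L, 0L, 50L)))
  part <- structure(list(membership = c(T1 = 1L, T2 = 1L, T3 = 2L,
                                        `16:0` = 1L), Q = 0.1),
                    class = "mblink_partition")
  ab <- module_abundances(counts, part)
  expect_equal(unname(ab[1, "module_1"]), 0.2)
  expect_equal(unname(ab[1, "module_2"]), 0.8)
  expect_equal(unname(ab[2, "module_1"]), 0)   # zero counts -> 0
  one <- structure(list(membership = c(T1 = 1L, T2 = 1L, T3 = 1L), Q = 0),
                   class = "mblink_partition")
  expect_equal(unname(module_abundances(counts, one)[, 1]), c(1, 1))
})

test_that("module group tests report k-1 degrees of freedom", {
  set.seed(3)
  ab <- matrix(runif(40), 20, 2,
               dimnames = list(paste0("S", 1:20), c("module_1", "module_2")))
  g2 <- rep(c("Control", "IBS"), each = 10)
  g4 <- rep(c("Control", "IBS-D", "IBS-M", "IBS-C"), each = 5)
  t2 <- module_group_test(ab, g2)
  t4 <- module_group_test(ab, g4)
  expect_true(all(t2$df == 1))
  expect_true(all(t4$df == 3))
  same <- matrix(1, 20, 2, dimnames = dimnames(ab))
  expect_true(all(module_group_test(same, g2)$H == 0))
})

test_that("adjusted Rand index matches an independent implementation", {
  set.seed(77)
  for (i in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 1, 4, 5, 3)), 1)
})
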