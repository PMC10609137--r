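# Independent brute-force oracles used to validate the fast
# implementations, plus small fixture builders. The oracles deliberately
# use different algorithms (path enumeration, exhaustive partitioning,
# direct per-pair tests) from the package code they check.

tree_from_text <- function(txt) ape::read.tree(text = txt)

# Edges on the root-to-tip path of one tip, identified by child node.
path_edges <- function(tree, tip_label) {
  nt <- length(tree$tip.label)
  root <- nt + 1
  tip <- match(tip_label, tree$tip.label)
  np <- ape::nodepath(tree, from = root, to = tip)
  np[-1]  # child nodes of the path edges
}

# Faith's PD by unioning root-to-tip edge paths.
oracle_faiths_pd <- function(tree, present_tips) {
  if (!length(present_tips)) return(0)
  children <- unique(unlist(lapply(present_tips, path_edges, tree = tree)))
  sum(tree$edge.length[match(children, tree$edge[, 2])])
}

# Unweighted UniFrac by per-edge presence indicators from path enumeration.
oracle_unifrac <- function(tree, tips_a, tips_b) {
  edges_a <- unique(unlist(lapply(tips_a, path_edges, tree = tree)))
  edges_b <- unique(unlist(lapply(tips_b, path_edges, tree = tree)))
  len <- function(ch) sum(tree$edge.length[match(ch, tree$edge[, 2])])
  uni <- len(union(setdiff(edges_a, edges_b), setdiff(edges_b, edges_a)))
  tot <- len(union(edges_a, edges_b))
  if (tot == 0) 0 else uni / tot
}

# Exhaustive maximum modularity over all partitions of <= 10 nodes.
oracle_max_modularity <- function(edges, nodes) {
  n <- length(nodes)
  m <- nrow(edges)
  if (m == 0) return(0)
  deg <- setNames(rep(0, n), nodes)
  for (e in seq_len(m)) {
    deg[edges$node1[e]] <- deg[edges$node1[e]] + 1
    deg[edges$node2[e]] <- deg[edges$node2[e]] + 1
  }
  i1 <- match(edges$node1, nodes)
  i2 <- match(edges$node2, nodes)
  best <- -Inf
  assign_next <- function(membership, k) {
    pos <- length(membership) + 1
    if (pos > n) {
      within <- sum(membership[i1] == membership[i2])
      dsum <- tapply(deg, membership, sum)
      q <- within / m - sum((dsum / (2 * m))^2)
      if (q > best) best <<- q
      return(invisible())
    }
    for (c in seq_len(k + 1)) # restricted growth: at most one new label
      assign_next(c(membership, c), max(k, c))
  }
  assign_next(integer(0), 0)
  best
}

# Naive ANCOM W: direct per-pair kruskal.test loops.
oracle_ancom_w <- function(counts, groups, alpha = 0.05, pc = 1) {
  m <- ncol(counts)
  W <- integer(m)
  for (i in seq_len(m)) {
    p <- numeric(0)
    for (j in seq_len(m)) {
      if (i == j) next
      lr <- log((counts[, i] + pc) / (counts[, j] + pc))
      p <- c(p, kruskal.test(lr, as.factor(groups))$p.value)
    }
    W[i] <- sum(p.adjust(p, "BH") < alpha)
  }
  names(W) <- colnames(counts)
  W
}

# A small deterministic feature table on named samples/taxa.
toy_counts <- function(mat, samples = NULL, taxa = NULL) {
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(mat)))
  if (is.null(taxa)) taxa <- paste0("T", seq_len(ncol(mat)))
  dimnames(mat) <- list(samples, taxa)
  storage.mode(mat) <- "integer"
  mat
}

random_binary_tree <- function(n, seed) {
  tr <- mblink::generate_tree(n, seed)
  tr$tip.label <- paste0("T", seq_len(n))
  tr
}
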