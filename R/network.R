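# Taxon-lipid co-occurrence network and Louvain modules.
#
# Taxa enter the correlation as CLR values, lipids untransformed; edges are
# kept only for Pearson r > 0.5 AND p < 0.05 (strict, positive side only),
# so the graph captures co-occurrence, not exclusion.

#' Pairwise Pearson correlations with p-values
#'
#' @param X samples x features matrix (taxa columns CLR-transformed, lipid
#'   columns untransformed).
#' @return list with `r` and `p` matrices; zero-variance features have NA
#'   rows/columns (they can never form edges).
#' @export
pairwise_pearson <- function(X) {
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  v <- apply(X, 2, var)
  r <- suppressWarnings(cor(X))
  r[v == 0, ] <- NA
  r[, v == 0] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(r) <- 1
  diag(p) <- 0
  list(r = r, p = p, n = n)
}

#' Build the co-occurrence graph
#'
#' @param r,p matched correlation/p matrices from [pairwise_pearson()].
#' @param r_min,p_max edge thresholds; an edge needs r > r_min AND
#'   p < p_max (strict inequalities). Negative correlations never create
#'   edges.
#' @param kind optional named vector classifying nodes ("taxon"/"lipid").
#' @return `mblink_graph` list: `nodes` (data.frame: node, kind) and
#'   `edges` (data.frame: node1, node2, r, p).
#' @export
build_graph <- function(r, p, r_min = 0.5, p_max = 0.05, kind = NULL) {
  stopifnot(identical(dim(r), dim(p)))
  feats <- colnames(r)
  keep <- !is.na(r) & r > r_min & p < p_max
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(node1 = feats[idx[, 1]], node2 = feats[idx[, 2]],
                      r = r[idx], p = p[idx], stringsAsFactors = FALSE)
  if (is.null(kind)) kind <- setNames(rep("feature", length(feats)), feats)
  nodes <- data.frame(node = feats, kind = unname(kind[feats]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "mblink_graph")
}

graph_to_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges[, c("node1", "node2")],
                                directed = FALSE,
                                vertices = graph$nodes$node)
}

#' Louvain module detection
#'
#' Two-phase Louvain modularity maximization (resolution 1) on the
#' unweighted graph, taking the best-modularity partition over seeded
#' random vertex-order restarts. Isolated nodes become singleton modules.
#' Module ids are 1-based and ordered by decreasing module size for
#' reproducible naming.
#'
#' @param graph an `mblink_graph`.
#' @param seed integer seed.
#' @param n_restarts random restarts (default 20).
#' @return `mblink_partition` list: `membership` (named integer vector) and
#'   `Q` (modularity of the returned partition; 0 for an edgeless graph).
#' @export
louvain <- function(graph, seed = NULL, n_restarts = 20) {
  nodes <- graph$nodes$node
  if (!length(nodes))
    return(structure(list(membership = integer(0), Q = NA_real_),
                     class = "mblink_partition"))
  g <- graph_to_igraph(graph)
  best_mem <- NULL
  best_q <- -Inf
  local_seed(seed, {
    for (rep in seq_len(n_restarts)) {
      perm <- sample(igraph::vcount(g))
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp)
      q <- if (nrow(graph$edges)) igraph::modularity(cl) else 0
      if (q > best_q) {
        best_q <- q
        # membership named by vertex name; realign to input node order
        best_mem <- igraph::membership(cl)[nodes]
      }
    }
  })
  # relabel modules by decreasing size (ties: first appearance)
  sizes <- sort(table(best_mem), decreasing = TRUE)
  relab <- setNames(seq_along(sizes), names(sizes))
  membership <- setNames(as.integer(relab[as.character(best_mem)]), nodes)
  structure(list(membership = membership, Q = best_q),
            class = "mblink_partition")
}

#' Summed module relative abundances
#'
#' Per sample, the sum of taxon relative abundances (count / sample total)
#' over the taxa of each module. Lipid members of a module are listed in
#' the report but excluded from the sum by default, since concentrations
#' are not relative abundances.
#'
#' @param counts samples x taxa matrix (filtered table).
#' @param partition an `mblink_partition` over the graph's features.
#' @param include_lipids if TRUE, non-taxon members are not excluded
#'   (requires them to be columns of `counts`).
#' @return samples x modules numeric matrix.
#' @export
module_abundances <- function(counts, partition, include_lipids = FALSE) {
  rel <- counts / rowSums(counts)
  mem <- partition$membership
  if (!include_lipids) mem <- mem[names(mem) %in% colnames(counts)]
  mods <- sort(unique(mem))
  out <- sapply(mods, function(m) {
    members <- intersect(names(mem)[mem == m], colnames(counts))
    if (!length(members)) return(rep(0, nrow(counts)))
    rowSums(rel[, members, drop = FALSE])
  })
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(counts))
  dimnames(out) <- list(rownames(counts), paste0("module_", mods))
  out
}

#' Kruskal-Wallis tests of module abundances across groups
#'
#' @param mod_ab samples x modules matrix from [module_abundances()].
#' @param groups grouping vector (e.g. IBS status for H(1), the four
#'   groups for H(3)).
#' @return data.frame: module, H, df, p.
#' @export
module_group_test <- function(mod_ab, groups) {
  res <- lapply(colnames(mod_ab), function(m) {
    kt <- kruskal_wallis(mod_ab[, m], groups)
    data.frame(module = m, H = kt$H, df = kt$df, p = kt$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Export the graph as edge-list and membership TSVs
#' @param graph an `mblink_graph`.
#' @param partition an `mblink_partition`.
#' @param edge_path,membership_path output paths.
#' @export
write_graph <- function(graph, partition, edge_path, membership_path) {
  write.table(graph$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  mem <- data.frame(node = names(partition$membership),
                    module = as.integer(partition$membership))
  mem$kind <- graph$nodes$kind[match(mem$node, graph$nodes$node)]
  write.table(mem, membership_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}
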