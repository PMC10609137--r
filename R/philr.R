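# Phylogenetic balances: one isometric log-ratio coordinate per internal
# node of the rooted binary tree, contrasting its two child subtrees.

#' Build the balance basis of a binary rooted tree
#'
#' One balance per internal node: numerator = leaves under the first-parsed
#' child, denominator = leaves under the second. Node labels are
#' "n1", "n2", ... in the tree's internal-node order (root = n1).
#'
#' @param tree rooted binary `phylo`.
#' @return `mblink_basis` list: `label`, `node`, `numerator` /
#'   `denominator` (lists of leaf-name vectors), `r`, `s`.
#' @export
build_balance_basis <- function(tree) {
  if (!ape::is.binary(tree)) stop("tree must be binary (resolve at load time)")
  nt <- length(tree$tip.label)
  nodes <- nt + seq_len(tree$Nnode)
  # leaf sets below every node
  tr <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- i
  for (e in seq_len(nrow(tr$edge)))
    below[[tr$edge[e, 1]]] <- c(below[[tr$edge[e, 1]]], below[[tr$edge[e, 2]]])
  num <- vector("list", length(nodes))
  den <- vector("list", length(nodes))
  for (k in seq_along(nodes)) {
    children <- tree$edge[tree$edge[, 1] == nodes[k], 2]
    if (length(children) != 2) stop("non-binary node ", nodes[k])
    num[[k]] <- tree$tip.label[sort(below[[children[1]]])]
    den[[k]] <- tree$tip.label[sort(below[[children[2]]])]
  }
  structure(list(label = paste0("n", nodes - nt), node = nodes,
                 numerator = num, denominator = den,
                 r = lengths(num), s = lengths(den)),
            class = "mblink_basis")
}

#' PhILR-style balance transform
#'
#' For each internal node with r numerator and s denominator leaves,
#' b = sqrt(r s / (r + s)) * ln(num / den), where num and den are either
#' the summed pseudocounted reads of each subtree (`variant = "summed"`,
#' the default) or their geometric means (`variant = "gmean"`, the
#' reference isometric construction).
#'
#' @param counts samples x taxa matrix covering all tree leaves.
#' @param basis from [build_balance_basis()].
#' @param pseudocount positive offset (default 1).
#' @param variant "summed" or "gmean".
#' @return samples x balances matrix (columns named by balance label).
#' @export
philr_transform <- function(counts, basis, pseudocount = 1,
                            variant = c("summed", "gmean")) {
  variant <- match.arg(variant)
  stopifnot(pseudocount > 0)
  leaves <- unique(c(unlist(basis$numerator), unlist(basis$denominator)))
  missing <- setdiff(leaves, colnames(counts))
  if (length(missing))
    stop("counts missing tree leaves: ", paste(missing, collapse = ", "))
  x <- counts[, leaves, drop = FALSE] + pseudocount
  m <- length(basis$label)
  ind_num <- matrix(0, ncol(x), m, dimnames = list(leaves, basis$label))
  ind_den <- ind_num
  for (k in seq_len(m)) {
    ind_num[basis$numerator[[k]], k] <- 1
    ind_den[basis$denominator[[k]], k] <- 1
  }
  scale_k <- sqrt(basis$r * basis$s / (basis$r + basis$s))
  if (variant == "summed") {
    lr <- log(x %*% ind_num) - log(x %*% ind_den)
  } else {
    lx <- log(x)
    lr <- sweep(lx %*% ind_num, 2, basis$r, "/") -
      sweep(lx %*% ind_den, 2, basis$s, "/")
  }
  B <- sweep(lr, 2, scale_k, "*")
  dimnames(B) <- list(rownames(counts), basis$label)
  B
}

#' Export balance definitions as TSV
#' @param basis from [build_balance_basis()].
#' @param path output path.
#' @export
write_balance_basis <- function(basis, path) {
  df <- data.frame(
    label = basis$label, r = basis$r, s = basis$s,
    numerator = vapply(basis$numerator, paste, "", collapse = ","),
    denominator = vapply(basis$denominator, paste, "", collapse = ","))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotated Newick with internal-node balance labels
#' @param tree rooted binary `phylo`.
#' @param path output path.
#' @export
write_labeled_tree <- function(tree, path) {
  tree$node.label <- paste0("n", seq_len(tree$Nnode))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
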