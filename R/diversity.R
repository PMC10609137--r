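# Alpha/beta diversity, ordination and group tests.

# Tip indices below the child node of every edge (postorder accumulation).
edge_tip_indicator <- function(tree) {
  nt <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- tree$Nnode
  below <- matrix(FALSE, nt + nnode, nt)
  below[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    below[parent, ] <- below[parent, ] | below[child, ]
  }
  # rows: edges of the (original-order) tree; columns: tips
  ind <- below[tree$edge[, 2], , drop = FALSE]
  storage.mode(ind) <- "double"
  colnames(ind) <- tree$tip.label
  ind
}

check_taxa_in_tree <- function(counts, tree) {
  missing <- setdiff(colnames(counts), tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
}

# samples x edges presence matrix (weighted by nothing; 0/1)
sample_edge_presence <- function(counts, tree) {
  check_taxa_in_tree(counts, tree)
  ind <- edge_tip_indicator(tree)             # edges x tips
  P <- (counts > 0) * 1                       # samples x taxa
  P_full <- matrix(0, nrow(counts), ncol(ind),
                   dimnames = list(rownames(counts), colnames(ind)))
  P_full[, colnames(counts)] <- P
  EP <- P_full %*% t(ind)                     # samples x edges: tips below
  (EP > 0) * 1
}

#' Faith's phylogenetic diversity
#'
#' Per sample, the total branch length of the minimal subtree connecting
#' all observed taxa to the root.
#'
#' @param counts samples x taxa matrix (presence inferred from counts > 0).
#' @param tree rooted phylogeny whose leaves cover the taxa.
#' @return named numeric vector, one value per sample.
#' @export
faiths_pd <- function(counts, tree) {
  EP <- sample_edge_presence(counts, tree)
  pd <- as.numeric(EP %*% tree$edge.length)
  names(pd) <- rownames(counts)
  pd
}

#' Unweighted UniFrac distance matrix
#'
#' d(A, B) = branch length unique to either sample's taxon set divided by
#' the branch length of the union, using presence/absence only.
#'
#' @inheritParams faiths_pd
#' @return symmetric distance matrix with zero diagonal, values in \[0, 1\].
#' @export
unweighted_unifrac <- function(counts, tree) {
  EP <- sample_edge_presence(counts, tree)
  W <- EP * rep(tree$edge.length, each = nrow(EP))
  shared <- W %*% t(EP)                       # branch length present in both
  s <- rowSums(W)
  tot <- outer(s, s, "+")
  unique_len <- pmax(tot - 2 * shared, 0)   # clamp fp negatives
  union_len <- tot - shared
  d <- ifelse(union_len > 0, unique_len / union_len, 0)
  d <- (d + t(d)) / 2
  dimnames(d) <- list(rownames(counts), rownames(counts))
  validate_distance_matrix(d)
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param x samples x features non-negative matrix (abundances or
#'   concentrations).
#' @return symmetric distance matrix, values in \[0, 1\].
#' @export
bray_curtis <- function(x) {
  if (any(x < 0)) stop("negative values")
  if (any(rowSums(x) == 0)) stop("all-zero sample row: Bray-Curtis undefined")
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  dimnames(d) <- list(rownames(x), rownames(x))
  validate_distance_matrix(d)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared-distance matrix and eigendecomposes it.
#' Axes with negative eigenvalues are dropped (their count is reported);
#' the proportion explained is relative to the sum of positive eigenvalues.
#'
#' @param dm distance matrix.
#' @return `mblink_ordination` list: `coordinates` (samples x axes),
#'   `eigenvalues`, `proportion_explained`, `n_negative`.
#' @export
pcoa <- function(dm) {
  dm <- validate_distance_matrix(dm)
  n <- nrow(dm)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (dm^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  n_negative <- sum(e$values < -tol)
  vals <- e$values[pos]
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals), sum(pos))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = vals,
                 proportion_explained = vals / sum(vals),
                 n_negative = n_negative),
            class = "mblink_ordination")
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F from the among/within partition of squared distances, with a
#' permutation p-value using the (1 + count) / (1 + n_perm) convention.
#'
#' @param dm distance matrix.
#' @param groups grouping vector aligned with `dm` rows (>= 2 groups, each
#'   of size >= 2).
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed.
#' @return list with `pseudo_F`, `p`, `df` and `n_perm`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = NULL) {
  dm <- validate_distance_matrix(dm)
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group must have n >= 2")
  df <- data.frame(g = groups)
  fit <- local_seed(seed,
    vegan::adonis2(stats::as.dist(dm) ~ g, data = df,
                   permutations = n_perm))
  list(pseudo_F = unname(fit$F[1]), p = unname(fit$`Pr(>F)`[1]),
       df = c(among = nlevels(groups) - 1,
              within = nrow(dm) - nlevels(groups)),
       n_perm = n_perm)
}

#' Kruskal-Wallis test
#'
#' Tie-corrected rank H with a chi-square p on k - 1 df; fully tied data
#' yield H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups grouping vector.
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(unique(values)) == 1)
    return(list(H = 0, p = 1, df = nlevels(groups) - 1))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Linear regression of alpha diversity on a covariate
#'
#' Ordinary least squares with a t-based 95% confidence band.
#'
#' @param alpha per-sample response (e.g. Faith's PD).
#' @param covariate per-sample numeric covariate.
#' @param level confidence level (default 0.95).
#' @return list with `slope`, `intercept`, `p`, `r_squared`, and `band`
#'   (data.frame: covariate, fit, lwr, upr, at sorted covariate values).
#' @export
alpha_regression <- function(alpha, covariate, level = 0.95) {
  if (length(alpha) < 3) stop("need n >= 3")
  if (var(covariate) == 0) stop("covariate has zero variance")
  fit <- lm(alpha ~ covariate)
  xs <- sort(unique(covariate))
  ci <- predict(fit, newdata = data.frame(covariate = xs),
                interval = "confidence", level = level)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p = sm$coefficients[2, 4], r_squared = sm$r.squared,
       band = data.frame(covariate = xs, fit = ci[, "fit"],
                         lwr = ci[, "lwr"], upr = ci[, "upr"]))
}

#' One-way ANOVA with Dunn's post hoc tests
#'
#' Reports the ANOVA F and p alongside Dunn's rank-based pairwise z tests
#' with Bonferroni adjustment (the pairing used to contrast group means and
#' then locate the differing pairs).
#'
#' @param values numeric vector.
#' @param groups grouping vector (>= 2 groups, each n >= 2).
#' @return list with `F`, `p`, `df`, and `dunn` (data.frame: group1,
#'   group2, z, p_unadj, p_adj).
#' @export
anova_dunn <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group must have n >= 2")
  pairs0 <- combn(levels(groups), 2)
  if (length(unique(values)) == 1)
    return(list(F = 0, p = 1,
                df = c(nlevels(groups) - 1,
                       length(values) - nlevels(groups)),
                dunn = data.frame(group1 = pairs0[1, ], group2 = pairs0[2, ],
                                  z = 0, p_unadj = 1, p_adj = 1)))
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- table(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  pairs <- combn(levels(groups), 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(v0 * (1 / ng[pr[1]] + 1 / ng[pr[2]]))
  })
  p_unadj <- 2 * pnorm(-abs(z))
  p_adj <- pmin(1, p_unadj * ncol(pairs))
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = c(tab$Df[1], tab$Df[2]),
       dunn = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         z = as.numeric(z), p_unadj = as.numeric(p_unadj),
                         p_adj = as.numeric(p_adj)))
}
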