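# Rare-taxon filtering, CLR transform, ANCOM W statistic, LEfSe scores.

#' Filter rare taxa
#'
#' A taxon is removed only when BOTH its total read count is below
#' `total_min` AND its mean read count is below `mean_min` (conjunction, so
#' a taxon abundant by either criterion is kept).
#'
#' @param counts samples x taxa matrix of raw counts.
#' @param total_min total-count threshold (default 500).
#' @param mean_min mean-count threshold (default 3).
#' @return filtered samples x taxa matrix.
#' @export
filter_rare_taxa <- function(counts, total_min = 500, mean_min = 3) {
  totals <- colSums(counts)
  means <- colMeans(counts)
  drop <- totals < total_min & means < mean_min
  if (all(drop)) stop("no taxa left after rare-taxon filter")
  counts[, !drop, drop = FALSE]
}

#' Centered log-ratio transform
#'
#' Per sample: log(count + pseudocount) minus the sample mean of those
#' logs. Every output row sums to zero.
#'
#' @param counts samples x taxa matrix.
#' @param pseudocount positive offset added before the log (default 1).
#' @return samples x taxa real matrix.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  lx <- log(counts + pseudocount)
  out <- lx - rowMeans(lx)
  dimnames(out) <- dimnames(counts)
  out
}

#' ANCOM W statistic
#'
#' For each taxon i, W_i counts the reference taxa j for which the
#' Kruskal-Wallis test on log((x_i + pc) / (x_j + pc)) across groups is
#' significant after Benjamini-Hochberg correction over taxon i's m - 1
#' pairwise tests. A taxon is flagged differentially abundant when
#' W_i >= w_cutoff_frac * (m - 1).
#'
#' @param counts samples x taxa matrix (already rare-filtered).
#' @param groups grouping vector (>= 2 groups).
#' @param alpha significance level on adjusted pairwise p (default 0.05).
#' @param w_cutoff_frac declaration cutoff as a fraction of m - 1
#'   (default 0.7).
#' @param pseudocount offset in the log-ratios (default 1).
#' @return list with `W` (named integer vector), `flag` (named logical),
#'   `m`, and `cutoff`.
#' @export
ancom <- function(counts, groups, alpha = 0.05, w_cutoff_frac = 0.7,
                  pseudocount = 1) {
  m <- ncol(counts)
  if (m < 3) stop("ANCOM needs at least 3 taxa")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  lx <- log(counts + pseudocount)
  pr <- combn(m, 2)
  Y <- lx[, pr[1, ], drop = FALSE] - lx[, pr[2, ], drop = FALSE]
  pvals <- kw_stat_matrix(Y, groups)$p
  P <- matrix(NA_real_, m, m)
  P[t(pr)] <- pvals
  P[t(pr[2:1, , drop = FALSE])] <- pvals
  W <- integer(m)
  for (i in seq_len(m)) {
    adj <- p.adjust(P[i, -i], method = "BH")
    W[i] <- sum(adj < alpha)
  }
  names(W) <- colnames(counts)
  cutoff <- w_cutoff_frac * (m - 1)
  list(W = W, flag = W >= cutoff, m = m, cutoff = cutoff)
}

# Per-feature LDA effect size for one bootstrap draw, following the LEfSe
# convention: average of the between-class difference of the feature's
# means and its contribution to the difference of the LDA projections.
lda_effect_once <- function(X, cls) {
  mu <- rowsum(X, cls) / as.vector(table(cls))
  dmu <- mu[1, ] - mu[2, ]
  w <- tryCatch({
    # collinearity among compositional features is expected; lda still
    # returns a usable direction
    fit <- suppressWarnings(MASS::lda(X, grouping = cls))
    sc <- fit$scaling[, 1]
    sc / sqrt(sum(sc^2))
  }, error = function(e) {
    v <- apply(X, 2, var)
    v[v == 0] <- 1
    d <- dmu / v
    d / sqrt(sum(d^2))
  })
  dproj <- sum(w * dmu)
  abs(0.5 * (dmu + w * dproj))
}

#' LEfSe effect sizes (two classes)
#'
#' Screens features with a Kruskal-Wallis test, then scores survivors with
#' a bootstrapped one-dimensional linear-discriminant effect size on
#' relative abundances (scaled to a per-sample total of 1e6, the
#' conventional LEfSe scale). Scores are log10 effect sizes signed toward
#' the enriched class; only features with |score| >= `lda_threshold` are
#' reported.
#'
#' @param rel samples x features relative abundances (rows sum to 1) or raw
#'   counts (converted internally).
#' @param groups two-class grouping vector.
#' @param kw_alpha screen level (default 0.05).
#' @param lda_threshold absolute log10 score cutoff (default 2).
#' @param n_boot bootstrap rounds (default 30).
#' @param seed integer seed.
#' @return data.frame (feature, kw_p, lda_score, enriched), possibly empty.
#' @export
lefse <- function(rel, groups, kw_alpha = 0.05, lda_threshold = 2,
                  n_boot = 30, seed = NULL) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("LEfSe here is two-class")
  X <- rel / rowSums(rel) * 1e6
  kw <- kw_stat_matrix(X, groups)
  keep <- which(kw$p < kw_alpha)
  empty <- data.frame(feature = character(), kw_p = numeric(),
                      lda_score = numeric(), enriched = character(),
                      stringsAsFactors = FALSE)
  if (!length(keep)) return(empty)
  Xs <- X[, keep, drop = FALSE]
  idx_by_class <- split(seq_len(nrow(Xs)), groups)
  eff <- local_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(b) {
      take <- unlist(lapply(idx_by_class, function(ii)
        sample(ii, max(2, floor(2 / 3 * length(ii))), replace = TRUE)))
      lda_effect_once(Xs[take, , drop = FALSE], groups[take])
    }, numeric(ncol(Xs)))
    if (!is.matrix(boots)) boots <- matrix(boots, nrow = ncol(Xs))
    rowMeans(boots)
  })
  mu <- rowsum(Xs, groups) / as.vector(table(groups))
  enriched <- ifelse(mu[2, ] > mu[1, ], levels(groups)[2], levels(groups)[1])
  score <- log10(pmax(eff, 1e-10)) *
    ifelse(enriched == levels(groups)[2], 1, -1)
  out <- data.frame(feature = colnames(Xs), kw_p = kw$p[keep],
                    lda_score = score, enriched = enriched,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[abs(out$lda_score) >= lda_threshold, , drop = FALSE]
}
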