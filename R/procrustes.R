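# Procrustes superimposition and the randomization test (PROTEST) linking
# the microbiome and lipidome ordinations.

# Center and scale a configuration to unit sum of squares; pad columns
# with zeros to `width`.
procrustes_prepare <- function(X, width = ncol(X)) {
  X <- as.matrix(X)
  if (ncol(X) < width)
    X <- cbind(X, matrix(0, nrow(X), width - ncol(X)))
  Xc <- sweep(X, 2, colMeans(X))
  ss <- sum(Xc^2)
  if (ss == 0) stop("degenerate configuration (zero spread)")
  Xc / sqrt(ss)
}

#' Procrustes superimposition of two configurations
#'
#' Both configurations are centered and scaled to unit sum of squares; the
#' second is then rotated (reflections allowed) and rescaled to best fit
#' the first. The residual sum of squared differences is Gower's m2
#' statistic, in \[0, 1\] under this symmetric convention (0 = exact match
#' after transformation).
#'
#' @param X,Y samples x axes coordinate matrices with matching row order;
#'   axis counts may differ (zero-padded internally).
#' @return `mblink_procrustes` list: `m2`, `rotation`, `scale`,
#'   `Yhat` (transformed Y on X's standardized scale), `X` (standardized).
#' @export
procrustes <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y need the same samples")
  if (nrow(X) < 3) stop("need at least 3 samples")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop("sample order mismatch between configurations")
  w <- max(ncol(X), ncol(Y))
  Xs <- procrustes_prepare(X, w)
  Ys <- procrustes_prepare(Y, w)
  sv <- svd(crossprod(Ys, Xs))          # t(Ys) %*% Xs
  A <- sv$u %*% t(sv$v)                 # rotation (full orthogonal group)
  scale <- sum(sv$d)
  Yhat <- scale * Ys %*% A
  m2 <- 1 - scale^2
  structure(list(m2 = max(0, m2), rotation = A, scale = scale,
                 Yhat = Yhat, X = Xs),
            class = "mblink_procrustes")
}

#' Procrustes randomization test (PROTEST)
#'
#' PCoA is applied to both distance matrices (all positive-eigenvalue
#' axes, optionally truncated to `axes`); the observed Procrustes m2 is
#' compared against a null distribution obtained by permuting the sample
#' rows of the second (lipidome) coordinate matrix `n_perm` times.
#'
#' Two p-values are reported: `p_better`, the fraction of null m2 values
#' strictly LOWER than the observed — i.e. the fraction of random sample
#' matchings that fit better, so an observed disparity lower than 99.8%
#' of the null reads p_better = 0.002 — and the conventional significance
#' `p_conventional = (1 + #\{null <= observed\}) / (1 + n_perm)`.
#'
#' @param dm_microbiome,dm_lipidome distance matrices over the same
#'   samples (same order).
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @param axes optional cap on the number of PCoA axes per ordination.
#' @return `mblink_protest` list: `m2`, `null` (length n_perm), `p_better`,
#'   `p_conventional`, `n_perm`.
#' @export
protest <- function(dm_microbiome, dm_lipidome, n_perm = 10000,
                    seed = NULL, axes = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  dm_microbiome <- validate_distance_matrix(dm_microbiome)
  dm_lipidome <- validate_distance_matrix(dm_lipidome)
  if (!identical(rownames(dm_microbiome), rownames(dm_lipidome)))
    stop("sample sets/order differ between distance matrices")
  ox <- pcoa(dm_microbiome)$coordinates
  oy <- pcoa(dm_lipidome)$coordinates
  if (!is.null(axes)) {
    ox <- ox[, seq_len(min(axes, ncol(ox))), drop = FALSE]
    oy <- oy[, seq_len(min(axes, ncol(oy))), drop = FALSE]
  }
  w <- max(ncol(ox), ncol(oy))
  Xs <- procrustes_prepare(ox, w)
  Ys <- procrustes_prepare(oy, w)
  m2_of <- function(Yperm) {
    d <- svd(crossprod(Yperm, Xs), nu = 0, nv = 0)$d
    max(0, 1 - sum(d)^2)
  }
  m2_obs <- m2_of(Ys)
  n <- nrow(Xs)
  null <- local_seed(seed, {
    vapply(seq_len(n_perm),
           function(b) m2_of(Ys[sample(n), , drop = FALSE]),
           numeric(1))
  })
  structure(list(m2 = m2_obs, null = null,
                 p_better = mean(null < m2_obs),
                 p_conventional = (1 + sum(null <= m2_obs)) / (1 + n_perm),
                 n_perm = n_perm),
            class = "mblink_protest")
}

#' Write the PROTEST null distribution as one-column TSV
#' @param result an `mblink_protest`.
#' @param path output path.
#' @export
write_protest_null <- function(result, path) {
  write.table(data.frame(m2 = result$null), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
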