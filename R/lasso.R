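# LASSO by cyclic coordinate descent, and selection of the top diet-
# associated balances.
#
# Objective (standardized scale):
#   (1 / (2n)) * sum((y - b0 - X b)^2) + lambda * sum(|b|)
# with columns of X standardized internally to mean 0 and 1/n-variance 1,
# so lambda is directly comparable across designs.

soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

#' LASSO objective value
#' @param X design matrix (the scale on which `beta` lives).
#' @param y response.
#' @param intercept,beta coefficients.
#' @param lambda penalty.
#' @return scalar objective.
#' @export
lasso_objective <- function(X, y, intercept, beta, lambda) {
  n <- length(y)
  r <- y - intercept - as.numeric(X %*% beta)
  sum(r^2) / (2 * n) + lambda * sum(abs(beta))
}

#' LASSO regression by cyclic coordinate descent
#'
#' Minimizes (1/(2n)) * RSS + lambda * L1 with soft-thresholding updates to
#' a coefficient-change tolerance of 1e-8. Columns are standardized
#' internally (mean 0, 1/n-variance 1); coefficients are reported on both
#' the standardized and the original scale. Zero-variance columns are
#' dropped with a warning.
#'
#' @param X samples x predictors matrix (e.g. a balance matrix).
#' @param y numeric response (e.g. HFCS g/month).
#' @param lambda non-negative penalty.
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_iter sweep cap.
#' @return `mblink_lasso` list: `beta_std`, `beta`, `intercept`, `lambda`,
#'   `selected` (names of nonzero coefficients), `objective`, `n_iter`.
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-8, max_iter = 100000L) {
  stopifnot(nrow(X) == length(y), nrow(X) >= 3, lambda >= 0)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  mu <- colMeans(X)
  sds <- sqrt(colMeans(X^2) - mu^2)
  drop <- sds == 0
  if (any(drop)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, !drop, drop = FALSE]
    mu <- mu[!drop]; sds <- sds[!drop]
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  p <- ncol(Xs)
  yc <- y - mean(y)
  beta <- numeric(p)
  r <- yc
  it <- 0L
  repeat {
    it <- it + 1L
    delta <- 0
    for (j in seq_len(p)) {
      bj_old <- beta[j]
      zj <- sum(Xs[, j] * r) / n + bj_old     # (1/n) x_j' (r + x_j b_j)
      bj <- soft_threshold(zj, lambda)
      if (bj != bj_old) {
        r <- r - Xs[, j] * (bj - bj_old)
        delta <- max(delta, abs(bj - bj_old))
        beta[j] <- bj
      }
    }
    if (delta < tol || it >= max_iter) break
  }
  names(beta) <- colnames(Xs)
  beta_raw <- beta / sds
  intercept <- mean(y) - sum(beta_raw * mu)
  structure(list(beta_std = beta, beta = beta_raw, intercept = intercept,
                 lambda = lambda, selected = names(beta)[beta != 0],
                 objective = lasso_objective(Xs, yc, 0, beta, lambda),
                 n_iter = it),
            class = "mblink_lasso")
}

#' Smallest lambda that zeroes every coefficient
#' @param X predictor matrix (standardized internally as in [lasso_fit()]).
#' @param y response.
#' @return scalar lambda_max.
#' @export
lasso_lambda_max <- function(X, y) {
  n <- nrow(X)
  mu <- colMeans(X)
  sds <- sqrt(colMeans(X^2) - mu^2)
  keep <- sds > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sds[keep], "/")
  max(abs(crossprod(Xs, y - mean(y)))) / n
}

#' Select the top diet-associated balances
#'
#' Runs the LASSO at `lambda`, keeps at most `k` balances (the k largest
#' |standardized coefficient| among the nonzero set), then refits ordinary
#' least squares of the response on the selected balances and reports the
#' refit adjusted R-squared, F statistic and p-value.
#'
#' @param X samples x balances matrix.
#' @param y response (HFCS g/month).
#' @param lambda LASSO penalty (default 3000).
#' @param k maximum number of balances kept (default 5).
#' @return `mblink_lasso_selection` list: `selected`, `lasso`
#'   (the underlying fit), `coefficients` (refit OLS), `adj_r_squared`,
#'   `F`, `df`, `p`, `null_model` flag.
#' @export
select_top_balances <- function(X, y, lambda = 3000, k = 5) {
  fit <- lasso_fit(X, y, lambda)
  nz <- fit$selected
  if (length(nz) > k)
    nz <- names(sort(abs(fit$beta_std[nz]), decreasing = TRUE))[seq_len(k)]
  if (!length(nz)) {
    return(structure(list(selected = character(0), lasso = fit,
                          coefficients = c(`(Intercept)` = mean(y)),
                          adj_r_squared = 0, F = NA_real_,
                          df = c(0, length(y) - 1), p = NA_real_,
                          null_model = TRUE),
                     class = "mblink_lasso_selection"))
  }
  df <- data.frame(y = y, X[, nz, drop = FALSE], check.names = FALSE)
  refit <- lm(y ~ ., data = df)
  sm <- summary(refit)
  fs <- sm$fstatistic
  structure(list(selected = nz, lasso = fit,
                 coefficients = coef(refit),
                 adj_r_squared = sm$adj.r.squared,
                 F = unname(fs[1]), df = unname(fs[2:3]),
                 p = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
                 null_model = FALSE),
            class = "mblink_lasso_selection")
}
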