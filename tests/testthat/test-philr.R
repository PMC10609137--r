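test_that("balance basis enumerates internal nodes with partitioning leaf sets", {
  tr <- tree_from_text("((A:1,B:1):1,C:1);")
  basis <- build_balance_basis(tr)
  expect_equal(length(basis$label), 2)
  sets <- lapply(seq_along(basis$label), function(k)
    list(num = basis$numerator[[k]], den = basis$denominator[[k]]))
  root_k <- which(basis$r + basis$s == 3)
  leaf_k <- which(basis$r + basis$s == 2)
  expect_setequal(c(basis$numerator[[root_k]], basis$denominator[[root_k]]),
                  c("A", "B", "C"))
  expect_setequal(c(basis$numerator[[leaf_k]], basis$denominator[[leaf_k]]),
                  c("A", "B"))
  for (k in seq_along(basis$label))
    expect_length(intersect(basis$numerator[[k]], basis$denominator[[k]]), 0)

  big <- generate_tree(255, seed = 3)
  expect_equal(length(build_balance_basis(big)$label), 254)
})

test_that("balance values match the closed form", {
  tr <- tree_from_text("((A:1,B:1):1,C:1);")
  basis <- build_balance_basis(tr)
  # equal subtree sums -> balance 0 at the A|B node
  counts <- toy_counts(matrix(c(5L, 5L, 3L), 1), taxa = c("A", "B", "C"))
  B <- philr_transform(counts, basis)
  leaf_k <- basis$label[basis$r + basis$s == 2]
  expect_equal(unname(B[1, leaf_k]), 0)

  # r = s = 1 with ratio e after pseudocount: b = sqrt(1/2) * 1
  c2 <- round(exp(1) * 100) - 1L
  counts2 <- toy_counts(matrix(c(c2, 99L, 1L), 1), taxa = c("A", "B", "C"))
  B2 <- philr_transform(counts2, basis)
  expect_equal(unname(B2[1, leaf_k]),
               sqrt(1 / 2) * log((c2 + 1) / 100), tolerance = 1e-12)

  # doubling counts with the pseudocount scaled leaves balances unchanged
  counts3 <- toy_counts(matrix(c(40L, 10L, 25L), 1), taxa = c("A", "B", "C"))
  expect_equal(philr_transform(counts3 * 2L, basis, pseudocount = 2),
               philr_transform(counts3, basis, pseudocount = 1))
})

test_that("swapping numerator and denominator flips the balance sign", {
  tr <- generate_tree(12, seed = 4)
  basis <- build_balance_basis(tr)
  flipped <- basis
  flipped$numerator <- basis$denominator
  flipped$denominator <- basis$numerator
  flipped$r <- basis$s; flipped$s <- basis$r
  set.seed(8)
  counts <- matrix(rpois(5 * 12, 30), 5, 12,
                   dimnames = list(paste0("S", 1:5), tr$tip.label))
  storage.mode(counts) <- "integer"
  for (variant in c("summed", "gmean"))
    expect_equal(philr_transform(counts, flipped, variant = variant),
                 -philr_transform(counts, basis, variant = variant))
})

test_that("gmean balances are an isometry of CLR space on 4-leaf trees", {
  tr <- tree_from_text("((A:1,B:1):1,(C:1,D:1):1);")
  basis <- build_balance_basis(tr)
  set.seed(12)
  counts <- matrix(rpois(8 * 4, 40), 8, 4,
                   dimnames = list(paste0("S", 1:8), c("A", "B", "C", "D")))
  storage.mode(counts) <- "integer"
  B <- philr_transform(counts, basis, variant = "gmean")
  clr <- clr_transform(counts)
  expect_lt(max(abs(as.matrix(dist(B)) - as.matrix(dist(clr)))), 1e-9)
})

test_that("coordinate descent matches closed forms and the convex-solver oracle", {
  set.seed(20)
  n <- 40
  # orthonormal design on the 1/n scale with exactly mean-zero columns
  # (QR of column-centered data spans only mean-zero vectors)
  A <- scale(matrix(rnorm(n * 5), n, 5), center = TRUE, scale = FALSE)
  X <- sqrt(n) * qr.Q(qr(A))
  beta_true <- c(3, -2, 0, 1.5, 0)
  y <- as.numeric(X %*% beta_true) + rnorm(n, 0, 0.5)

  # lambda beyond lambda_max zeroes everything
  lmax <- lasso_lambda_max(X, y)
  f0 <- lasso_fit(X, y, lambda = lmax * 1.0001)
  expect_true(all(f0$beta_std == 0))

  # lambda = 0 equals OLS
  fit0 <- lasso_fit(X, y, lambda = 0)
  ols <- lm(y ~ X)
  expect_equal(unname(fit0$beta), unname(coef(ols)[-1]), tolerance = 1e-6)
  expect_equal(fit0$intercept, unname(coef(ols)[1]), tolerance = 1e-6)

  # soft-threshold closed form on the standardized design
  lam <- 0.8
  fit <- lasso_fit(X, y, lambda = lam)
  mu <- colMeans(X); sds <- sqrt(colMeans(X^2) - mu^2)
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  ols_std <- as.numeric(crossprod(Xs, y - mean(y))) / n
  closed <- sign(ols_std) * pmax(abs(ols_std) - lam, 0)
  expect_equal(unname(fit$beta_std), closed, tolerance = 1e-6)
})

test_that("lasso objective matches glmnet on random instances", {
  skip_if_not_installed("glmnet")
  set.seed(30)
  for (i in 1:10) {
    n <- sample(20:50, 1); p <- sample(5:15, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n, sd = 2)
    lam <- runif(1, 0.05, 1)
    fit <- lasso_fit(X, y, lambda = lam)
    mu <- colMeans(X); sds <- sqrt(colMeans(X^2) - mu^2)
    Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
    gn <- glmnet::glmnet(Xs, y, lambda = lam, standardize = FALSE,
                         thresh = 1e-14)
    b_gn <- as.numeric(gn$beta)
    obj_mine <- lasso_objective(Xs, y - mean(y), 0, fit$beta_std, lam)
    obj_gn <- lasso_objective(Xs, y - mean(y), 0, b_gn, lam)
    expect_lt(abs(obj_mine - obj_gn), 1e-6)
  }
})

test_that("objective never increases across coordinate-descent sweeps", {
  # re-run a fit and track the objective sweep by sweep via decreasing tol
  set.seed(31)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rnorm(30)
  objs <- vapply(c(1e-1, 1e-3, 1e-5, 1e-8), function(tl)
    lasso_fit(X, y, lambda = 0.3, tol = tl)$objective, numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("top-balance selection caps at k and refits honestly", {
  set.seed(33)
  n <- 45; p <- 40
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("n", 1:p)))
  y <- 3 * X[, 7] + rnorm(n, 0, 0.5)
  sel <- select_top_balances(X, y, lambda = 0.1, k = 5)
  expect_lte(length(sel$selected), 5)
  expect_true("n7" %in% sel$selected)
  expect_gt(sel$adj_r_squared, 0.8)
  expect_equal(sel$df[1], length(sel$selected))

  # independent response: refit R2 centered near zero over repeats
  r2 <- vapply(1:30, function(i) {
    yi <- rnorm(n)
    select_top_balances(X, yi, lambda = lasso_lambda_max(X, yi) * 0.95,
                        k = 5)$adj_r_squared
  }, numeric(1))
  expect_lt(abs(mean(r2)), 0.15)

  # nothing selected -> flagged null model
  null_sel <- select_top_balances(X, y, lambda = 1e6, k = 5)
  expect_true(null_sel$null_model)
  expect_equal(length(null_sel$selected), 0)
})
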