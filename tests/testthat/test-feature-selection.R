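test_that("standardize centres and scales with the n-1 convention", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 20, 60))
  s <- standardize(d)
  expect_equal(s$a, c(-1, 0, 1))
  expect_equal(mean(s$b), 0)
  expect_equal(stats::sd(s$b), 1)
  # idempotence
  s2 <- standardize(s)
  expect_equal(as.matrix(s2), as.matrix(s), tolerance = 1e-12)
  expect_error(standardize(data.frame(a = 1:3, k = rep(2, 3))), "k")
})

test_that("elastic net with no penalty reproduces least squares", {
  set.seed(1)
  n <- 200
  X <- scale(matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4))))
  y <- drop(X %*% c(1, -2, 0.5, 0)) + rnorm(n)
  fit <- elastic_net_fit(X, y, lambda = 0, alpha = 1)
  ols <- stats::coef(stats::lm(y ~ X))
  expect_equal(unname(fit$beta), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-6)
})

test_that("lambda at or above lambda_max zeroes every coefficient", {
  set.seed(2)
  n <- 300
  X <- scale(matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6))))
  y <- drop(X %*% c(2, 1, 0, 0, -1, 0)) + rnorm(n)
  lmax <- lambda_max(X, y, alpha = 1)
  fit <- elastic_net_fit(X, y, lambda = lmax * 1.0001, alpha = 1)
  expect_true(all(fit$beta == 0))
  expect_length(fit$selected, 0)
  # strictly below lambda_max at least one coefficient enters
  fit2 <- elastic_net_fit(X, y, lambda = lmax * 0.95, alpha = 1)
  expect_gt(sum(fit2$beta != 0), 0)
})

test_that("lasso on a centred orthonormal design equals soft-thresholding", {
  set.seed(3)
  n <- 400; p <- 5
  M <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  X <- qr.Q(qr(M)) * sqrt(n)            # X'X / n = I, columns centred
  colnames(X) <- paste0("x", 1:p)
  beta <- c(2, -1, 0.5, 0, 0.2)
  y <- drop(X %*% beta) + rnorm(n)
  b_ols <- drop(crossprod(X, y - mean(y))) / n
  for (lam in c(0.1, 0.4, 0.8)) {
    fit <- elastic_net_fit(X, y, lambda = lam, alpha = 1)
    soft <- sign(b_ols) * pmax(abs(b_ols) - lam, 0)
    expect_equal(unname(fit$beta), unname(soft), tolerance = 1e-6)
  }
})

test_that("KKT conditions hold at convergence for inactive coefficients", {
  set.seed(4)
  n <- 500
  X <- scale(matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("x", 1:8))))
  y <- drop(X %*% c(1.5, 1, 0.5, rep(0, 5))) + rnorm(n)
  lam <- 0.2; alpha <- 0.8
  fit <- elastic_net_fit(X, y, lambda = lam, alpha = alpha)
  r <- y - fit$intercept - drop(X %*% fit$beta)
  grad <- abs(crossprod(X, r)) / n
  inactive <- fit$beta == 0
  expect_true(all(grad[inactive] <= lam * alpha + 1e-6))
})

test_that("the l1 norm of the lasso path is monotone in lambda (orthonormal)", {
  set.seed(5)
  n <- 400; p <- 5
  M <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  X <- qr.Q(qr(M)) * sqrt(n)
  colnames(X) <- paste0("x", 1:p)
  y <- drop(X %*% c(2, -1, 0.5, 0.3, 0)) + rnorm(n)
  lams <- seq(0.05, 1, by = 0.05)
  norms <- vapply(lams, function(l)
    sum(abs(elastic_net_fit(X, y, l, alpha = 1)$beta)), 0)
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("CV selection recovers planted predictors and rejects pure noise", {
  d <- sample_dataset(food_template("wheat"), 1000, seed = 11)
  X <- d[, setdiff(names(d), "volume")]
  fit <- select_features_cv(X, d$volume, alpha = 0.5, n_folds = 10, seed = 1)
  expect_gte(sum(template_active_set("wheat") %in% fit$selected), 9)
  expect_gt(fit$variance_explained, 0.5)
  expect_true(all(c("lambda", "cv_error", "cv_se") %in% names(fit$cv_table)))
  set.seed(21)
  noise_fit <- select_features_cv(X, rnorm(nrow(X)), alpha = 0.5, seed = 1)
  expect_true(length(noise_fit$selected) == 0 ||
                noise_fit$variance_explained < 0.1)
  expect_error(select_features_cv(X[1:5, ], d$volume[1:5], n_folds = 10),
               "folds")
})

test_that("pca_variance matches eigenvalue oracles", {
  # spherical case: 11 independent unit-variance columns
  set.seed(6)
  d <- as.data.frame(matrix(rnorm(20000 * 11), ncol = 11))
  p <- pca_variance(d, use_correlation = TRUE)
  expect_lt(abs(p$cumulative[3] - 3 / 11), 0.02)
  expect_equal(p$cumulative[11], 1)
  expect_true(all(diff(p$eigenvalues) <= 1e-9))
  # planted covariance eigenvalues (4, 1, 1, 0, 0): first share 4/6
  V <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  S <- V %*% diag(c(4, 1, 1, 0, 0)) %*% t(V)
  X <- MASS::mvrnorm(200000, rep(0, 5), S)
  p2 <- pca_variance(as.data.frame(X), use_correlation = FALSE)
  expect_equal(p2$cumulative[1], 4 / 6, tolerance = 0.02)
  # brute-force eigensolver cross-check on random 5x5 covariance matrices
  for (s in 1:5) {
    set.seed(s)
    A <- matrix(rnorm(25), 5, 5)
    S <- crossprod(A)
    X <- MASS::mvrnorm(200, rep(0, 5), S)
    p3 <- pca_variance(as.data.frame(X), use_correlation = FALSE)
    ev <- sort(eigen(stats::cov(X))$values, decreasing = TRUE)
    expect_equal(p3$eigenvalues, ev, tolerance = 1e-8)
    expect_equal(p3$cumulative, cumsum(ev) / sum(ev), tolerance = 1e-8)
  }
})
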