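#' Standardize columns to mean 0, sample sd 1
#'
#' Sample standard deviation uses the n-1 denominator. The centring/scaling
#' parameters are stored in the `standardize_params` attribute so estimates
#' can be mapped back to natural units.
#'
#' @param data a data frame (ordinal columns are coerced to numeric level
#'   codes first).
#' @param columns columns to standardize (default: all).
#' @return a data frame of standardized numeric columns.
#' @export
standardize <- function(data, columns = names(data)) {
  m <- as_numeric_dataset(data[, columns, drop = FALSE])
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  zero <- sdv < .Machine$double.eps^0.5
  if (any(zero)) {
    stop("zero-variance column(s): ", paste(columns[zero], collapse = ", "))
  }
  out <- as.data.frame(scale(m, center = mu, scale = sdv))
  attr(out, "standardize_params") <- list(center = mu, scale = sdv)
  out
}

#' Elastic-net fit at a fixed penalty
#'
#' Minimizes `(1/2n) ||y - b0 - X beta||^2 +
#' lambda * (alpha ||beta||_1 + (1 - alpha)/2 ||beta||_2^2)`
#' (the sample-size-stable 1/(2n) convention). The solver is glmnet's
#' coordinate descent with a tight convergence threshold; the intercept is
#' never penalized and no internal re-standardization is applied, so closed
#' forms (soft-thresholding on orthonormal designs, the lambda_max KKT bound)
#' hold exactly.
#'
#' @param X numeric predictor matrix (standardized by the caller).
#' @param y numeric response.
#' @param lambda penalty weight >= 0.
#' @param alpha L1 mixing fraction in `[0, 1]`.
#' @return an object of class `elastic_net_fit` with elements `lambda`,
#'   `alpha`, `beta`, `intercept`, `selected`, `cv_table` (NULL here).
#' @export
elastic_net_fit <- function(X, y, lambda, alpha = 0.5) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite values in X or y")
  stopifnot(lambda >= 0, alpha >= 0, alpha <= 1)
  # warm-started path that ends exactly at the requested lambda, so the
  # extracted solution is solved (never interpolated) at that penalty
  lmax <- lambda_max(X, y, alpha = max(alpha, 1e-3))
  path <- if (lambda >= lmax) lambda else {
    lo <- max(lambda, lmax * 1e-6)
    unique(c(exp(seq(log(lmax), log(lo), length.out = 50)), lambda))
  }
  fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = path,
                        standardize = FALSE, thresh = 1e-14)
  # the requested lambda is a path member: take its column directly rather
  # than going through glmnet's interpolator
  cf <- as.numeric(stats::coef(fit)[, which.min(abs(fit$lambda - lambda))])
  beta <- stats::setNames(cf[-1], colnames(X))
  structure(list(lambda = lambda, alpha = alpha, beta = beta,
                 intercept = cf[1],
                 selected = names(beta)[beta != 0],
                 cv_table = NULL),
            class = "elastic_net_fit")
}

#' @export
print.elastic_net_fit <- function(x, ...) {
  cat("elastic-net fit: lambda =", signif(x$lambda, 4), ", alpha =", x$alpha,
      ";", length(x$selected), "of", length(x$beta), "predictors selected\n")
  invisible(x)
}

#' Smallest penalty that zeroes every coefficient (alpha > 0)
#'
#' From the KKT conditions of the 1/(2n) objective:
#' `lambda_max = max_j |x_j' (y - ybar)| / (n * alpha)`.
#' @param X predictor matrix; `y` response; `alpha` L1 fraction.
#' @param y numeric response.
#' @param alpha L1 mixing fraction (> 0).
#' @export
lambda_max <- function(X, y, alpha = 1) {
  stopifnot(alpha > 0)
  max(abs(crossprod(as.matrix(X), y - mean(y)))) / (nrow(X) * alpha)
}

#' Cross-validated elastic-net feature selection
#'
#' Runs K-fold cross-validation over a log-spaced lambda path (100 points
#' from `lambda_max` down four decades by default), picks the lambda with
#' minimal mean CV squared error, refits on the full data, and reports the
#' variance explained (OLS R^2) by the selected set. Predictors are
#' standardized internally; coefficients are reported on both scales.
#'
#' @param X predictor matrix or data frame; ordinal columns are coerced to
#'   numeric codes.
#' @param y response (ordinal responses coerced to numeric codes).
#' @param alpha L1 mixing fraction (default 0.5).
#' @param n_folds number of CV folds (>= 2, default 10).
#' @param lambda_grid optional decreasing lambda sequence.
#' @param seed integer seed controlling the fold assignment.
#' @return an `elastic_net_fit` with `cv_table` (lambda, mean CV error, se),
#'   `beta_natural` (coefficients on the original predictor scale) and
#'   `variance_explained`.
#' @export
select_features_cv <- function(X, y, alpha = 0.5, n_folds = 10,
                               lambda_grid = NULL, seed = 1) {
  if (is.data.frame(X)) X <- as_numeric_dataset(X)
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.numeric(as.integer(y))
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (nrow(X) < n_folds) stop("fewer rows than folds")
  sp <- standardize(as.data.frame(X))
  Xs <- as.matrix(sp)
  scales <- attr(sp, "standardize_params")$scale
  if (is.null(lambda_grid)) {
    lmax <- lambda_max(Xs, y, alpha = max(alpha, 1e-3))
    lambda_grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 100))
  }
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), nrow(X)))
  cv <- glmnet::cv.glmnet(Xs, y, alpha = alpha, lambda = lambda_grid,
                          foldid = foldid, standardize = FALSE, thresh = 1e-10)
  best <- cv$lambda.min
  fit <- elastic_net_fit(Xs, y, lambda = best, alpha = alpha)
  fit$cv_table <- data.frame(lambda = cv$lambda, cv_error = cv$cvm,
                             cv_se = cv$cvsd)
  fit$beta_natural <- fit$beta / scales
  sel <- fit$selected
  fit$variance_explained <- if (length(sel)) {
    summary(stats::lm(y ~ Xs[, sel, drop = FALSE]))$r.squared
  } else 0
  fit
}

#' Principal-component variance summary
#'
#' Eigen-decomposition of the covariance (or correlation) matrix of the
#' continuous columns, reporting eigenvalues and cumulative variance shares.
#'
#' @param data data frame or matrix with >= 2 numeric columns.
#' @param use_correlation analyse the correlation matrix (default TRUE).
#' @return a list of class `pca_summary` with `eigenvalues` (descending,
#'   non-negative) and `cumulative` variance fractions.
#' @export
pca_variance <- function(data, use_correlation = TRUE) {
  m <- if (is.data.frame(data)) as_numeric_dataset(data) else as.matrix(data)
  if (ncol(m) < 2) stop("need at least two columns")
  S <- if (use_correlation) stats::cor(m) else stats::cov(m)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)   # clip eigenvalues that are numerically -0
  structure(list(eigenvalues = ev, cumulative = cumsum(ev) / sum(ev)),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat("PCA:", length(x$eigenvalues), "components; cumulative share of first",
      k, ":", paste(sprintf("%.1f%%", 100 * x$cumulative[seq_len(k)]),
                    collapse = ", "), "\n")
  invisible(x)
}
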