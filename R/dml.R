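#' Cross-fitted out-of-fold residuals
#'
#' Partitions the rows into folds; each row's prediction comes from a
#' nuisance learner trained on the other folds, so no observation is
#' predicted by a model that saw it. Residuals (observed minus out-of-fold
#' prediction) are centred to mean zero.
#'
#' The default learner is a random forest (ranger, 500 trees, minimum node
#' size 20 — regression trees bagged on bootstrap resamples); `learner` may
#' also be `list(type = "lm")` for a linear nuisance or a list of ranger
#' arguments. With no covariates the prediction is the training-fold mean.
#'
#' @param data data frame.
#' @param target target column name.
#' @param covariates character vector of covariate names (may be empty; must
#'   exclude the target).
#' @param learner nuisance learner spec, e.g.
#'   `list(type = "ranger", num.trees = 500, min.node.size = 20)`.
#' @param n_folds number of folds (>= 2; every fold needs >= 5 rows).
#' @param seed integer seed for the fold assignment.
#' @return numeric residual vector of length `nrow(data)`.
#' @export
crossfit_residuals <- function(data, target, covariates,
                               learner = default_learner(), n_folds = 5,
                               seed = 1) {
  stopifnot(n_folds >= 2)
  if (target %in% covariates) stop("covariates must exclude the target")
  m <- as.data.frame(as_numeric_dataset(data))
  n <- nrow(m)
  set.seed(as.integer(seed %% 2147483647))
  foldid <- sample(rep_len(seq_len(n_folds), n))
  if (min(table(foldid)) < 5) stop("every fold needs at least 5 rows")
  pred <- numeric(n)
  for (k in seq_len(n_folds)) {
    test <- foldid == k
    train <- m[!test, , drop = FALSE]
    pred[test] <- if (!length(covariates)) {
      mean(train[[target]])
    } else {
      fit_nuisance(train, target, covariates, learner,
                   seed = (as.numeric(seed) * 131 + k) %% 2147483647)(m[test, , drop = FALSE])
    }
  }
  r <- m[[target]] - pred
  r - mean(r)
}

#' @rdname crossfit_residuals
#' @export
default_learner <- function() {
  list(type = "ranger", num.trees = 500, min.node.size = 20)
}

# returns a prediction closure trained on `train`
fit_nuisance <- function(train, target, covariates, learner, seed) {
  type <- learner$type %||% "ranger"
  fml <- stats::reformulate(covariates, response = target)
  if (type == "lm") {
    fit <- stats::lm(fml, data = train)
    function(newdata) stats::predict(fit, newdata = newdata)
  } else if (type == "ranger") {
    args <- learner[setdiff(names(learner), "type")]
    fit <- do.call(ranger::ranger,
                   c(list(formula = fml, data = train, seed = seed,
                          num.threads = 1), args))
    function(newdata) stats::predict(fit, data = newdata)$predictions
  } else {
    stop("unknown learner type: ", type)
  }
}

#' Double machine learning ACE (partially linear residual ratio)
#'
#' Estimates the total average causal effect of a treatment on an outcome as
#' the ratio of the covariance to the variance of the cross-fitted residuals:
#' outcome and treatment are each regressed flexibly on the covariates, and
#' `theta = Cov(resid_outcome, resid_treatment) / Var(resid_treatment)`.
#' The standard error comes from the influence function of the partially
#' linear estimator. Cross-fitting (sample splitting) makes the plug-in
#' valid with machine-learning nuisances; `n_folds = 1` reproduces the naive
#' in-sample plug-in.
#'
#' @inheritParams crossfit_residuals
#' @param treatment,outcome column names; `covariates` must exclude both.
#' @param covariates covariate columns; default: all remaining columns.
#' @return a `dml_result`: `theta`, `se`, `n_folds`, residual vectors,
#'   learner descriptor.
#' @export
dml_ace <- function(data, treatment, outcome, covariates = NULL,
                    learner = default_learner(), n_folds = 5, seed = 1) {
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c(treatment, outcome))
  }
  if (any(c(treatment, outcome) %in% covariates)) {
    stop("covariates must exclude treatment and outcome")
  }
  if (n_folds == 1) {
    m <- as.data.frame(as_numeric_dataset(data))
    ry <- in_sample_residual(m, outcome, covariates, learner, seed)
    rt <- in_sample_residual(m, treatment, covariates, learner, seed + 1L)
  } else {
    ry <- crossfit_residuals(data, outcome, covariates, learner, n_folds, seed)
    rt <- crossfit_residuals(data, treatment, covariates, learner, n_folds, seed)
  }
  v <- mean(rt^2)
  if (v < 1e-8) {
    stop("degenerate: treatment is (numerically) fully explained by the covariates")
  }
  theta <- mean(rt * ry) / v
  psi <- rt * (ry - theta * rt)
  se <- sqrt(mean(psi^2) / v^2 / length(rt))
  structure(list(treatment = treatment, outcome = outcome, theta = theta,
                 se = se, n_folds = n_folds,
                 resid_outcome = ry, resid_treatment = rt,
                 learner = learner),
            class = "dml_result")
}

in_sample_residual <- function(m, target, covariates, learner, seed) {
  pred <- if (!length(covariates)) rep(mean(m[[target]]), nrow(m)) else
    fit_nuisance(m, target, covariates, learner, seed)(m)
  r <- m[[target]] - pred
  r - mean(r)
}

#' @export
print.dml_result <- function(x, ...) {
  cat(sprintf("DML ACE of %s on %s: theta = %.4f (se %.4f), %d folds, %s\n",
              x$treatment, x$outcome, x$theta, x$se, x$n_folds,
              x$learner$type %||% "ranger"))
  invisible(x)
}

#' Convert a DML result to a `causal_effect`
#' @param x a `dml_result`.
#' @param units unit tag (default "natural").
#' @export
as_causal_effect <- function(x, units = "natural") {
  new_causal_effect(x$treatment, x$outcome, kind = "total",
                    estimate = x$theta, se = x$se, method = "dml",
                    adjustment = NULL, units = units)
}
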