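#' Bagged-tree quality model with out-of-bag bookkeeping
#'
#' Fits a bootstrap-bagged forest (ranger backend) of `n_trees` decision
#' trees with `mtry` candidate variables per split, storing the per-tree
#' bootstrap counts so that out-of-bag (OOB) predictions can be computed —
#' and audited — in this package: each row's OOB prediction aggregates only
#' trees whose bootstrap resample excluded that row.
#'
#' @param data data frame.
#' @param target target column; factors (or `task = "classification"`) give a
#'   classification forest, numeric targets a regression forest.
#' @param n_trees number of trees (default 500).
#' @param mtry candidate variables per split (default 3; must not exceed the
#'   number of predictors).
#' @param task `"auto"`, `"regression"` or `"classification"`.
#' @param seed integer seed.
#' @param min_node_size minimum node size (default 5).
#' @return a `forest_model`: the fitted ranger object, the in-bag count
#'   matrix (rows x trees), OOB predictions, and task metadata.
#' @export
fit_forest <- function(data, target, n_trees = 500, mtry = 3,
                       task = c("auto", "regression", "classification"),
                       seed = 1, min_node_size = 5) {
  task <- match.arg(task)
  stopifnot(target %in% names(data))
  df <- data
  ycol <- df[[target]]
  if (task == "auto") {
    task <- if (is.factor(ycol) || is.character(ycol) ||
                dataset_kinds(data)[[target]] %in% c("binary", "ordinal"))
      "classification" else "regression"
  }
  if (task == "classification") {
    df[[target]] <- factor(ycol, ordered = FALSE)
    if (nlevels(df[[target]]) < 2) stop("classification target has a single class")
  } else {
    df[[target]] <- as.numeric(as_numeric_dataset(df[, target, drop = FALSE]))
  }
  preds <- setdiff(names(df), target)
  # predictors numerically coded (ordinal as level codes) for splitting
  for (v in preds) df[[v]] <- as_numeric_dataset(df[, v, drop = FALSE])[, 1]
  if (mtry > length(preds)) stop("mtry exceeds the number of predictors")
  fit <- ranger::ranger(stats::reformulate(preds, response = target),
                        data = df, num.trees = n_trees, mtry = mtry,
                        min.node.size = min_node_size, keep.inbag = TRUE,
                        seed = seed, num.threads = 1)
  inbag <- do.call(cbind, fit$inbag.counts)   # n x n_trees bootstrap counts
  model <- structure(list(fit = fit, inbag = inbag, task = task,
                          target = target, predictors = preds,
                          n_trees = n_trees, mtry = mtry, data_coded = df),
                     class = "forest_model")
  model$oob <- oob_predictions(model)
  model
}

# OOB aggregation from stored bootstrap counts: regression averages, a
# classification majority-votes, over the trees that did not see the row
oob_predictions <- function(model) {
  all_pred <- stats::predict(model$fit, data = model$data_coded,
                             predict.all = TRUE, num.threads = 1)$predictions
  oob_mask <- model$inbag == 0
  n <- nrow(oob_mask)
  never_oob <- rowSums(oob_mask) == 0
  if (any(never_oob)) {
    warning(sum(never_oob), " row(s) in-bag for every tree; excluded from OOB metrics")
  }
  if (model$task == "regression") {
    out <- rep(NA_real_, n)
    for (i in which(!never_oob)) out[i] <- mean(all_pred[i, oob_mask[i, ]])
  } else {
    lev <- levels(model$data_coded[[model$target]])
    out <- rep(NA_character_, n)
    for (i in which(!never_oob)) {
      votes <- table(all_pred[i, oob_mask[i, ]])
      out[i] <- lev[as.integer(names(votes)[which.max(votes)])]
    }
    out <- factor(out, levels = lev)
  }
  out
}

#' @export
print.forest_model <- function(x, ...) {
  cat("bagged forest (", x$task, "): ", x$n_trees, " trees, mtry ", x$mtry,
      ", target '", x$target, "'\n", sep = "")
  invisible(x)
}

#' Out-of-bag performance metrics
#'
#' Regression: OOB R^2 = 1 - SSE_oob / SST. Classification: OOB
#' misclassification rate plus the confusion table. Rows that were in-bag
#' for every tree are excluded (with the warning raised at fit time).
#'
#' @param model a [fit_forest()] model.
#' @param data the data the model was fitted on.
#' @return list of class `oob_metrics`; for regression `r_squared`, for
#'   classification `error_rate` and `confusion`.
#' @export
oob_metrics <- function(model, data) {
  ok <- !is.na(model$oob)
  if (model$task == "regression") {
    y <- as_numeric_dataset(data[, model$target, drop = FALSE])[, 1][ok]
    pred <- model$oob[ok]
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum((y - pred)^2) / sst else
      as.numeric(all(pred == y))   # constant target: exact prediction = 1
    structure(list(task = "regression", r_squared = r2, n_used = sum(ok)),
              class = "oob_metrics")
  } else {
    y <- factor(data[[model$target]], ordered = FALSE)[ok]
    pred <- factor(model$oob[ok], levels = levels(y))
    err <- mean(pred != y)
    structure(list(task = "classification", error_rate = err,
                   confusion = table(observed = y, predicted = pred),
                   n_used = sum(ok)),
              class = "oob_metrics")
  }
}

#' @export
print.oob_metrics <- function(x, ...) {
  if (x$task == "regression") {
    cat(sprintf("OOB R^2: %.3f (%d rows)\n", x$r_squared, x$n_used))
  } else {
    cat(sprintf("OOB error rate: %.4f (%d rows)\n", x$error_rate, x$n_used))
    print(x$confusion)
  }
  invisible(x)
}
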