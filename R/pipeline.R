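#' Run the full causal-analysis pipeline from a declarative configuration
#'
#' Orchestrates simulate/load -> elastic-net selection -> structure learning
#' -> effect estimation -> DML cross-check -> predictive model, from one
#' config, writing per-stage CSV artifacts, a Markdown report and a JSON
#' summary into the output directory. One global seed determines every stage
#' seed deterministically, so rerunning an identical config reproduces all
#' numeric outputs bit-exactly.
#'
#' Config fields (list, or a YAML/JSON file path):
#' \describe{
#' \item{input}{either `list(csv = "file.csv")` (with optional sidecar
#'   schema, see [read_dataset()]) or `list(template = "dairy", n = 5000)`.}
#' \item{response}{outcome column name.}
#' \item{stages}{ordered subset of `select`, `learn`, `effects`, `dml`,
#'   `predict`. `effects` needs a DAG from `learn` or a `dag_file`
#'   (edge-list CSV).}
#' \item{seed}{global integer seed.}
#' \item{output_dir}{directory for artifacts (created if missing).}
#' \item{params}{optional per-stage parameter lists, e.g.
#'   `params$select$alpha`, `params$learn$n_restarts`,
#'   `params$dml$learner$num.trees`, `params$predict$mtry`.}
#' }
#'
#' @param config a list or a path to a YAML/JSON config file.
#' @return (invisibly) the summary list that is also written as
#'   `summary.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)
  stage_seed <- function(k) (cfg$seed + 7919L * k) %% 2147483647L

  summary <- list(config = cfg[c("response", "stages", "seed")],
                  stages = list())

  # ---- input ----
  if (!is.null(cfg$input$template)) {
    scm <- food_template(cfg$input$template)
    data <- sample_dataset(scm, cfg$input$n %||% 1000, seed = stage_seed(0L))
    log_line("simulated ", nrow(data), " rows from template '",
             cfg$input$template, "' (seed ", stage_seed(0L), ")")
    write_dataset(data, file.path(cfg$output_dir, "data.csv"))
    true_dag <- scm$dag
  } else {
    data <- read_dataset(cfg$input$csv)
    log_line("loaded ", nrow(data), " rows from ", cfg$input$csv)
    true_dag <- NULL
  }
  if (!cfg$response %in% names(data)) {
    stop("configuration error: response column '", cfg$response,
         "' not in the data")
  }

  learned_dag <- NULL
  if (!is.null(cfg$dag_file)) learned_dag <- read_dag_csv(cfg$dag_file)

  for (stage in cfg$stages) {
    log_line("stage '", stage, "' started")
    if (stage == "select") {
      p <- cfg$params$select
      X <- data[, setdiff(names(data), cfg$response), drop = FALSE]
      y <- data[[cfg$response]]
      fit <- select_features_cv(X, y, alpha = p$alpha %||% 0.5,
                                n_folds = p$n_folds %||% 10,
                                seed = stage_seed(1L))
      utils::write.csv(data.frame(feature = fit$selected,
                                  beta_std = fit$beta[fit$selected],
                                  beta_natural = fit$beta_natural[fit$selected]),
                       file.path(cfg$output_dir, "selected_features.csv"),
                       row.names = FALSE)
      utils::write.csv(fit$cv_table, file.path(cfg$output_dir, "cv_curve.csv"),
                       row.names = FALSE)
      summary$stages$select <- list(n_selected = length(fit$selected),
                                    lambda = fit$lambda,
                                    variance_explained = fit$variance_explained,
                                    selected = fit$selected)
    } else if (stage == "learn") {
      p <- cfg$params$learn
      hc <- hill_climb(data, max_iter = p$max_iter %||% 200,
                       n_restarts = p$n_restarts %||% 10,
                       seed = stage_seed(2L),
                       score = p$score %||% "gaussian")
      learned_dag <- hc$dag
      write_dag_csv(learned_dag, file.path(cfg$output_dir, "dag.csv"))
      dag_to_dot(learned_dag, file.path(cfg$output_dir, "dag.dot"))
      summary$stages$learn <- list(n_edges = nrow(dag_edges(learned_dag)),
                                   bic = hc$score$total,
                                   parents_of_response =
                                     dag_parents(learned_dag, cfg$response))
    } else if (stage == "effects") {
      if (is.null(learned_dag)) {
        stop("configuration error: stage 'effects' needs a DAG from a prior ",
             "'learn' stage or a 'dag_file' entry")
      }
      pc <- path_coefficients(data, learned_dag)
      utils::write.csv(pc, file.path(cfg$output_dir, "path_coefficients.csv"),
                       row.names = FALSE)
      treatments <- setdiff(names(data), cfg$response)
      sdata <- standardize(data)
      eff <- do.call(rbind, lapply(treatments, function(tr) {
        te <- total_effect(learned_dag, pc, tr, cfg$response)
        adj <- tryCatch(ace_adjusted(sdata_with_kinds(sdata), learned_dag, tr,
                                     cfg$response),
                        error = function(e) NULL)
        data.frame(treatment = tr,
                   path_sum = te$estimate, path_sum_se = te$se,
                   adjusted = if (is.null(adj)) NA else adj$estimate,
                   adjusted_se = if (is.null(adj)) NA else adj$se)
      }))
      utils::write.csv(eff, file.path(cfg$output_dir, "effects.csv"),
                       row.names = FALSE)
      summary$stages$effects <- eff
    } else if (stage == "dml") {
      p <- cfg$params$dml
      treatments <- setdiff(names(data), cfg$response)
      sdata <- standardize(data)
      dml_tab <- do.call(rbind, lapply(seq_along(treatments), function(i) {
        res <- dml_ace(sdata, treatments[i], cfg$response,
                       learner = p$learner %||% default_learner(),
                       n_folds = p$n_folds %||% 5,
                       seed = stage_seed(3L) + i)
        data.frame(treatment = treatments[i], theta = res$theta, se = res$se)
      }))
      utils::write.csv(dml_tab, file.path(cfg$output_dir, "dml_effects.csv"),
                       row.names = FALSE)
      summary$stages$dml <- dml_tab
    } else if (stage == "predict") {
      p <- cfg$params$predict
      model <- fit_forest(data, cfg$response,
                          n_trees = p$n_trees %||% 500,
                          mtry = p$mtry %||% 3,
                          seed = stage_seed(4L))
      met <- oob_metrics(model, data)
      summary$stages$predict <- if (met$task == "regression")
        list(task = "regression", oob_r_squared = met$r_squared)
      else list(task = "classification", oob_error_rate = met$error_rate)
      utils::write.csv(data.frame(oob_prediction = as.character(model$oob)),
                       file.path(cfg$output_dir, "oob_predictions.csv"),
                       row.names = FALSE)
    } else {
      stop("configuration error: unknown stage '", stage, "'")
    }
    log_line("stage '", stage, "' finished")
  }

  jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  write_report_md(summary, file.path(cfg$output_dir, "report.md"))
  invisible(summary)
}

sdata_with_kinds <- function(sdata) {
  attr(sdata, "kinds") <- stats::setNames(rep("continuous", ncol(sdata)),
                                          names(sdata))
  sdata
}

load_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$input) ||
      (is.null(config$input$csv) && is.null(config$input$template))) {
    stop("configuration error: 'input' needs a 'csv' path or a 'template' name")
  }
  if (is.null(config$response)) stop("configuration error: 'response' missing")
  stages <- config$stages %||% character(0)
  known <- c("select", "learn", "effects", "dml", "predict")
  if (!all(stages %in% known)) {
    stop("configuration error: unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "))
  }
  if ("effects" %in% stages && !("learn" %in% stages) &&
      is.null(config$dag_file)) {
    stop("configuration error: stage 'effects' requires a 'learn' stage ",
         "before it or a 'dag_file'")
  }
  config$stages <- stages
  config$seed <- as.integer(config$seed %||% 1L)
  config$output_dir <- config$output_dir %||% "pipeline_out"
  config$params <- config$params %||% list()
  config
}

write_report_md <- function(summary, path) {
  lines <- c("# Causal food-quality pipeline report", "",
             paste0("Response: `", summary$config$response, "`; seed ",
                    summary$config$seed),
             "")
  s <- summary$stages
  if (!is.null(s$select)) {
    lines <- c(lines, "## Feature selection",
               paste0("- selected ", s$select$n_selected, " features at lambda = ",
                      signif(s$select$lambda, 4)),
               paste0("- variance explained by the selected set (OLS R^2): ",
                      sprintf("%.3f", s$select$variance_explained)),
               paste0("- features: ", paste(s$select$selected, collapse = ", ")),
               "")
  }
  if (!is.null(s$learn)) {
    lines <- c(lines, "## Structure learning",
               paste0("- hill-climbing DAG with ", s$learn$n_edges,
                      " edges (BIC ", sprintf("%.1f", s$learn$bic), ")"),
               paste0("- parents of the response: ",
                      paste(s$learn$parents_of_response, collapse = ", ")),
               "")
  }
  if (!is.null(s$effects)) {
    lines <- c(lines, "## Causal effects (path-sum vs adjusted OLS)",
               "See `effects.csv`; every numeric table in this report is also a CSV.",
               "")
  }
  if (!is.null(s$dml)) {
    lines <- c(lines, "## DML cross-check", "See `dml_effects.csv`.", "")
  }
  if (!is.null(s$predict)) {
    metric <- if (identical(s$predict$task, "regression"))
      paste0("OOB R^2 = ", sprintf("%.3f", s$predict$oob_r_squared))
    else paste0("OOB error rate = ", sprintf("%.4f", s$predict$oob_error_rate))
    lines <- c(lines, "## Predictive model", paste0("- ", metric), "")
  }
  writeLines(lines, path)
  invisible(path)
}
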