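#' Scoring context for Bayesian-network structure learning
#'
#' Precomputes what the decomposable BIC needs — the sample covariance of the
#' numerically coded table for Gaussian nodes, the raw discrete columns for
#' multinomial nodes — and holds a memo cache keyed by (node, parent set), so
#' hill climbing and MCMC never score the same family twice.
#'
#' @param data a data frame (see [dataset_kinds()]).
#' @param score `"cglogit"` (default) scores each node with its natural
#'   conditional family: linear-Gaussian for continuous nodes, logistic for
#'   binary nodes, cumulative-logit (proportional odds) for ordinal nodes,
#'   each on numerically coded parents — so edge orientations adjacent to
#'   discrete nodes are judged by the correct likelihood rather than a
#'   misspecified Gaussian. `"gaussian"` scores every node as a
#'   linear-Gaussian family on the numerically coded table (ordinal grades as
#'   level codes; the convention used throughout effect estimation).
#'   `"mixed"` scores binary/ordinal nodes with a multinomial family over
#'   discrete parent configurations and enforces the conditional-Gaussian
#'   admissibility rule that discrete nodes have only discrete parents.
#' @return an object of class `bic_context`.
#' @export
bic_context <- function(data, score = c("cglogit", "gaussian", "mixed")) {
  score <- match.arg(score)
  kinds <- dataset_kinds(data)
  m <- as_numeric_dataset(data)
  structure(list(n = nrow(m), S = stats::cov(m), m = m, kinds = kinds,
                 discrete = lapply(data[kinds != "continuous"], function(col)
                   factor(col)),
                 score = score, cache = new.env(parent = emptyenv())),
            class = "bic_context")
}

#' Local BIC score of one node given a parent set
#'
#' Decomposable network score, larger is better:
#' log-likelihood minus `(k/2) log n`. A Gaussian node scores the maximized
#' likelihood of its linear regression on the parents with `k = #parents + 2`
#' (coefficients, intercept, variance). A discrete node (score `"mixed"`)
#' scores the multinomial likelihood per parent configuration with
#' `k = (levels - 1) * #configurations`; a discrete node with a continuous
#' parent is inadmissible and raises an error.
#'
#' @param node node (column) name.
#' @param parents character vector of parent names (possibly empty).
#' @param data data frame, or an existing [bic_context()] via `context`.
#' @param score see [bic_context()]; ignored when `context` is supplied.
#' @param context optional precomputed [bic_context()].
#' @return the local score (numeric scalar).
#' @export
local_bic <- function(node, parents = character(0), data = NULL,
                      score = c("cglogit", "gaussian", "mixed"), context = NULL) {
  ctx <- context %||% bic_context(data, match.arg(score))
  key <- paste(node, paste(sort(parents), collapse = ","), sep = "|")
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- compute_local_bic(ctx, node, parents)
  assign(key, val, envir = ctx$cache)
  val
}

compute_local_bic <- function(ctx, node, parents) {
  n <- ctx$n
  if (ctx$score == "cglogit" && ctx$kinds[[node]] != "continuous") {
    y <- ctx$discrete[[node]]
    if (!length(parents)) {
      # intercept-only multinomial likelihood, k = levels - 1
      cnt <- table(y)
      ll <- sum(cnt[cnt > 0] * log(cnt[cnt > 0] / n))
      return(ll - (nlevels(y) - 1) / 2 * log(n))
    }
    X <- ctx$m[, parents, drop = FALSE]
    if (ctx$kinds[[node]] == "binary" || nlevels(droplevels(y)) == 2) {
      yy <- as.integer(y) - 1L
      if (nlevels(droplevels(y)) == 2) yy <- as.integer(droplevels(y)) - 1L
      fit <- suppressWarnings(stats::glm.fit(cbind(1, X), yy,
                                             family = stats::binomial()))
      ll <- -fit$deviance / 2
      k <- length(parents) + 1
    } else {
      df <- as.data.frame(X)
      df$.y <- y
      fit <- tryCatch(
        suppressWarnings(MASS::polr(stats::reformulate(parents, ".y"),
                                    data = df, method = "logistic")),
        error = function(e) NULL)
      if (is.null(fit)) return(gaussian_local_bic(ctx, node, parents))
      ll <- -fit$deviance / 2
      k <- length(parents) + nlevels(y) - 1
    }
    return(ll - (k / 2) * log(n))
  }
  if (ctx$score == "mixed" && ctx$kinds[[node]] != "continuous") {
    cont_par <- parents[ctx$kinds[parents] == "continuous"]
    if (length(cont_par)) {
      stop("admissibility: discrete node '", node,
           "' may not have continuous parent(s): ",
           paste(cont_par, collapse = ", "))
    }
    y <- ctx$discrete[[node]]
    cfg <- if (length(parents)) interaction(ctx$discrete[parents], drop = FALSE)
           else factor(rep(1, n))
    tab <- table(cfg, y)
    nj <- rowSums(tab)
    ll <- sum(tab[tab > 0] * log(tab[tab > 0] /
                                   nj[row(tab)][tab > 0]))
    k <- (nlevels(y) - 1) * nlevels(cfg)
    return(ll - (k / 2) * log(n))
  }
  gaussian_local_bic(ctx, node, parents)
}

# linear-Gaussian family computed from the cached covariance matrix
gaussian_local_bic <- function(ctx, node, parents) {
  n <- ctx$n
  S <- ctx$S
  syy <- S[node, node]
  sig2 <- if (length(parents)) {
    Spp <- S[parents, parents, drop = FALSE]
    spy <- S[parents, node]
    resid_var <- syy - drop(crossprod(spy, solve(Spp, spy)))
    max(resid_var, 1e-12)
  } else syy
  sig2_ml <- sig2 * (n - 1) / n
  ll <- -n / 2 * (log(2 * pi * sig2_ml) + 1)
  k <- length(parents) + 2
  ll - (k / 2) * log(n)
}

#' Total decomposable BIC of a DAG
#' @param data data frame or [bic_context()].
#' @param dag a [dag()].
#' @param score see [bic_context()].
#' @return a `score_result`: `total` and per-node `local` scores.
#' @export
dag_score <- function(data, dag, score = c("cglogit", "gaussian", "mixed")) {
  ctx <- if (inherits(data, "bic_context")) data else bic_context(data, match.arg(score))
  local <- vapply(dag_nodes(dag), function(v)
    local_bic(v, dag_parents(dag, v), context = ctx), 0)
  structure(list(total = sum(local), local = local), class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat("total BIC score:", format(x$total), "over", length(x$local), "nodes\n")
  invisible(x)
}

# ---- legal single-edge moves ------------------------------------------------

blocked <- function(bl, from, to) {
  !is.null(bl) && any(bl$from == from & bl$to == to)
}

# deterministic lexicographic move list: add < delete < reverse, then (from,
# to) alphabetical; only acyclicity-preserving, list-respecting moves
legal_moves <- function(amat, nodes, whitelist = NULL, blacklist = NULL) {
  moves <- list()
  for (i in order(nodes)) for (j in order(nodes)) {
    if (i == j) next
    f <- nodes[i]; t <- nodes[j]
    if (!amat[f, t] && !amat[t, f] && !blocked(blacklist, f, t) &&
        !has_directed_path(amat, match(t, nodes), match(f, nodes))) {
      moves[[length(moves) + 1]] <- list(type = "add", from = f, to = t)
    }
  }
  for (i in order(nodes)) for (j in order(nodes)) {
    f <- nodes[i]; t <- nodes[j]
    if (f != t && amat[f, t] && !blocked(whitelist, f, t)) {
      moves[[length(moves) + 1]] <- list(type = "delete", from = f, to = t)
    }
  }
  for (i in order(nodes)) for (j in order(nodes)) {
    f <- nodes[i]; t <- nodes[j]
    if (f != t && amat[f, t] && !blocked(whitelist, f, t) &&
        !blocked(blacklist, t, f)) {
      a2 <- amat; a2[f, t] <- FALSE
      if (!has_directed_path(a2, match(f, nodes), match(t, nodes))) {
        moves[[length(moves) + 1]] <- list(type = "reverse", from = f, to = t)
      }
    }
  }
  moves
}

apply_move <- function(amat, mv) {
  if (mv$type == "add") amat[mv$from, mv$to] <- TRUE
  else if (mv$type == "delete") amat[mv$from, mv$to] <- FALSE
  else { amat[mv$from, mv$to] <- FALSE; amat[mv$to, mv$from] <- TRUE }
  amat
}

move_delta <- function(ctx, amat, nodes, mv, local) {
  pa <- function(v, a) nodes[a[, v]]
  a2 <- apply_move(amat, mv)
  if (mv$type == "reverse") {
    (local_bic(mv$to, pa(mv$to, a2), context = ctx) +
       local_bic(mv$from, pa(mv$from, a2), context = ctx)) -
      (local[[mv$to]] + local[[mv$from]])
  } else {
    local_bic(mv$to, pa(mv$to, a2), context = ctx) - local[[mv$to]]
  }
}

#' Greedy hill-climbing structure search
#'
#' Repeatedly applies the best acyclicity-preserving single-edge move (add,
#' delete or reverse) until no move improves the decomposable BIC, with
#' random restarts. Ties between equal-scoring moves break lexicographically
#' on (move type, parent, child), so the result is invariant to column order.
#'
#' @param data data frame.
#' @param init optional starting [dag()] (default: empty graph).
#' @param whitelist,blacklist optional data frames (`from`, `to`) of edges
#'   forced present / forbidden.
#' @param max_iter maximum moves per restart.
#' @param n_restarts number of additional random restarts (initial DAGs with
#'   edge probability 0.2) beyond the supplied/empty start.
#' @param seed integer seed (restart generation only; the search itself is
#'   deterministic).
#' @param score see [bic_context()]; in `"mixed"` mode inadmissible families
#'   are treated as forbidden moves.
#' @return list with `dag` (best structure), `score` (its `score_result`) and
#'   `trace` (per-restart score sequences).
#' @export
hill_climb <- function(data, init = NULL, whitelist = NULL, blacklist = NULL,
                       max_iter = 200, n_restarts = 10, seed = 1,
                       score = c("cglogit", "gaussian", "mixed")) {
  score <- match.arg(score)
  ctx <- bic_context(data, score)
  nodes <- names(data)
  base_amat <- matrix(FALSE, length(nodes), length(nodes),
                      dimnames = list(nodes, nodes))
  if (!is.null(whitelist) && nrow(whitelist)) {
    wl_dag <- tryCatch(dag(nodes, as.matrix(whitelist[, c("from", "to")])),
                       error = function(e)
                         stop("whitelist forces a cycle or names unknown nodes"))
    base_amat <- wl_dag$amat
  }
  if (!is.null(init)) {
    stopifnot(setequal(dag_nodes(init), nodes))
    base_amat <- base_amat | init$amat[nodes, nodes]
    if (is.null(topo_order_amat(base_amat))) stop("init plus whitelist is cyclic")
  }

  starts <- list(base_amat)
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    a <- base_amat
    ord <- sample(nodes)
    for (i in seq_len(length(nodes) - 1)) for (j in seq((i + 1), length(nodes))) {
      if (stats::runif(1) < 0.2 && !blocked(blacklist, ord[i], ord[j]) &&
          !a[ord[j], ord[i]]) {
        a[ord[i], ord[j]] <- TRUE
      }
    }
    starts[[length(starts) + 1]] <- a
  }

  best <- NULL
  traces <- list()
  for (s in seq_along(starts)) {
    amat <- starts[[s]]
    local <- vapply(nodes, function(v)
      local_bic_safe(ctx, v, nodes[amat[, v]]), 0)
    trace <- sum(local)
    for (it in seq_len(max_iter)) {
      moves <- legal_moves(amat, nodes, whitelist, blacklist)
      if (!length(moves)) break
      deltas <- vapply(moves, function(mv) {
        d <- tryCatch(move_delta(ctx, amat, nodes, mv, as.list(local)),
                      error = function(e) -Inf)  # inadmissible in mixed mode
        d
      }, 0)
      k <- which.max(deltas)   # first maximum = lexicographic tie-break
      if (deltas[k] <= 1e-10) break
      mv <- moves[[k]]
      amat <- apply_move(amat, mv)
      for (v in unique(c(mv$from, mv$to))) {
        local[[v]] <- local_bic(v, nodes[amat[, v]], context = ctx)
      }
      trace <- c(trace, sum(local))
    }
    traces[[s]] <- trace
    if (is.null(best) || sum(local) > best$total) {
      best <- list(total = sum(local), amat = amat)
    }
  }
  g <- dag(nodes, which_edges(best$amat, nodes))
  list(dag = g, score = dag_score(ctx, g), trace = traces)
}

local_bic_safe <- function(ctx, v, parents) {
  tryCatch(local_bic(v, parents, context = ctx), error = function(e) -Inf)
}

which_edges <- function(amat, nodes) {
  idx <- which(amat, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  cbind(nodes[idx[, 1]], nodes[idx[, 2]])
}

#' Structure MCMC over DAGs
#'
#' Metropolis-Hastings on DAG space with uniform single-edge proposals (add /
#' delete / reverse, acyclicity-preserving) and a Hastings correction for the
#' neighbourhood sizes. The posterior surrogate is `exp(BIC)` under a uniform
#' structure prior; edge inclusion frequencies after burn-in approximate the
#' posterior probability of each directed edge.
#'
#' @param data data frame.
#' @param n_samples total MCMC iterations (> `burn_in`).
#' @param burn_in iterations discarded before accumulating edge frequencies.
#' @param seed integer seed.
#' @param score see [bic_context()].
#' @return an `edge_posterior`: `prob` (matrix of edge probabilities),
#'   `n_samples`, `burn_in`, `acceptance_rate`.
#' @export
structure_mcmc <- function(data, n_samples = 20000, burn_in = 2000, seed = 1,
                           score = c("cglogit", "gaussian", "mixed")) {
  stopifnot(n_samples > burn_in)
  ctx <- bic_context(data, match.arg(score))
  nodes <- names(data)
  p <- length(nodes)
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  local <- vapply(nodes, function(v) local_bic_safe(ctx, v, character(0)), 0)
  freq <- matrix(0, p, p, dimnames = list(nodes, nodes))
  set.seed(seed)
  accepted <- 0L
  kept <- 0L
  moves <- legal_moves(amat, nodes)
  for (it in seq_len(n_samples)) {
    if (length(moves)) {
      mv <- moves[[sample.int(length(moves), 1)]]
      delta <- tryCatch(move_delta(ctx, amat, nodes, mv, as.list(local)),
                        error = function(e) -Inf)
      a2 <- apply_move(amat, mv)
      moves2 <- legal_moves(a2, nodes)
      log_acc <- delta + log(length(moves)) - log(length(moves2))
      if (is.finite(log_acc) && log(stats::runif(1)) < log_acc) {
        amat <- a2
        moves <- moves2
        for (v in unique(c(mv$from, mv$to))) {
          local[[v]] <- local_bic(v, nodes[amat[, v]], context = ctx)
        }
        accepted <- accepted + 1L
      }
    }
    if (it > burn_in) { freq <- freq + amat; kept <- kept + 1L }
  }
  structure(list(prob = freq / max(kept, 1), n_samples = n_samples,
                 burn_in = burn_in,
                 acceptance_rate = accepted / n_samples),
            class = "edge_posterior")
}

#' @export
print.edge_posterior <- function(x, ...) {
  cat("structure-MCMC edge posterior over", nrow(x$prob), "nodes;",
      "acceptance rate", sprintf("%.2f", x$acceptance_rate), "\n")
  top <- which(x$prob > 0.5, arr.ind = TRUE)
  if (nrow(top)) {
    cat("edges with posterior > 0.5:\n")
    for (r in seq_len(nrow(top))) {
      cat(sprintf("  %s -> %s : %.2f\n", rownames(x$prob)[top[r, 1]],
                  colnames(x$prob)[top[r, 2]], x$prob[top[r, 1], top[r, 2]]))
    }
  }
  invisible(x)
}

#' Enumerate all DAGs over a small node set
#'
#' Every unordered node pair independently carries no edge or one of the two
#' orientations; cyclic assignments are discarded. Counts grow super-
#' exponentially (25 DAGs on 3 nodes, 543 on 4), so this is capped at 5
#' nodes; it exists as the exact oracle for the MCMC edge posterior.
#'
#' @param nodes character vector (<= 5).
#' @return list of [dag()] objects.
#' @export
enumerate_dags <- function(nodes) {
  p <- length(nodes)
  if (p > 5) stop("exact enumeration capped at 5 nodes")
  pairs <- utils::combn(p, 2)
  n_pairs <- ncol(pairs)
  out <- list()
  states <- rep(0L, n_pairs)
  repeat {
    amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
    for (k in seq_len(n_pairs)) {
      if (states[k] == 1L) amat[pairs[1, k], pairs[2, k]] <- TRUE
      if (states[k] == 2L) amat[pairs[2, k], pairs[1, k]] <- TRUE
    }
    if (!is.null(topo_order_amat(amat))) {
      out[[length(out) + 1]] <- dag(nodes, which_edges(amat, nodes))
    }
    k <- 1
    while (k <= n_pairs) {
      states[k] <- states[k] + 1L
      if (states[k] <= 2L) break
      states[k] <- 0L; k <- k + 1
    }
    if (k > n_pairs) break
  }
  out
}

#' Exact BIC-weighted edge posterior by full enumeration
#'
#' Scores every DAG over the data's columns, weights by `exp(BIC)` (uniform
#' structure prior) and returns exact edge-inclusion probabilities — the
#' ground truth that [structure_mcmc()] must match on small problems.
#'
#' @param data data frame with <= 5 columns.
#' @param score see [bic_context()].
#' @return matrix of exact edge probabilities.
#' @export
exact_edge_posterior <- function(data, score = c("cglogit", "gaussian", "mixed")) {
  ctx <- bic_context(data, match.arg(score))
  nodes <- names(data)
  dags <- enumerate_dags(nodes)
  scores <- vapply(dags, function(g) {
    tryCatch(dag_score(ctx, g)$total, error = function(e) -Inf)
  }, 0)
  w <- exp(scores - max(scores))
  w <- w / sum(w)
  prob <- matrix(0, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  for (i in seq_along(dags)) prob <- prob + w[i] * dags[[i]]$amat
  prob
}
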