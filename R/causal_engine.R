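#' d-separation by reachability (Bayes-ball)
#'
#' Tests whether every path between the node sets `X` and `Y` is blocked
#' given `Z`: chains and forks are blocked when their middle node is in `Z`;
#' colliders block unless the collider or one of its descendants is in `Z`.
#' Implemented as the standard reachability sweep over (node, direction)
#' states, linear in the number of edges per query.
#'
#' @param dag a [dag()].
#' @param X,Y,Z pairwise disjoint node sets (`Z` may be empty).
#' @return TRUE iff `X` and `Y` are d-separated given `Z`.
#' @export
d_separated <- function(dag, X, Y, Z = character(0)) {
  nodes <- dag_nodes(dag)
  stopifnot(all(c(X, Y, Z) %in% nodes))
  if (length(intersect(X, Y)) || length(intersect(X, Z)) ||
      length(intersect(Y, Z))) {
    stop("X, Y and Z must be pairwise disjoint")
  }
  amat <- dag$amat
  inZ <- nodes %in% Z
  # ancestors of Z (including Z): colliders in this set pass the ball upward
  anc <- inZ
  if (any(inZ)) {
    queue <- which(inZ)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      pa <- which(amat[, v] & !anc)
      anc[pa] <- TRUE
      queue <- c(queue, pa)
    }
  }
  targets <- nodes %in% Y
  # states: (node, direction); direction 1 = arrived from a child ("up"),
  # 2 = arrived from a parent ("down")
  visited <- matrix(FALSE, length(nodes), 2)
  queue_v <- match(X, nodes)
  queue_d <- rep(1L, length(queue_v))
  while (length(queue_v)) {
    v <- queue_v[1]; d <- queue_d[1]
    queue_v <- queue_v[-1]; queue_d <- queue_d[-1]
    if (visited[v, d]) next
    visited[v, d] <- TRUE
    if (!inZ[v] && targets[v]) return(FALSE)
    if (d == 1L && !inZ[v]) {
      pa <- which(amat[, v]); ch <- which(amat[v, ])
      queue_v <- c(queue_v, pa, ch)
      queue_d <- c(queue_d, rep(1L, length(pa)), rep(2L, length(ch)))
    } else if (d == 2L) {
      if (!inZ[v]) {
        ch <- which(amat[v, ])
        queue_v <- c(queue_v, ch)
        queue_d <- c(queue_d, rep(2L, length(ch)))
      }
      if (anc[v]) {   # collider with evidence below: ball bounces to parents
        pa <- which(amat[, v])
        queue_v <- c(queue_v, pa)
        queue_d <- c(queue_d, rep(1L, length(pa)))
      }
    }
  }
  TRUE
}

#' Backdoor adjustment sets
#'
#' A set Z is a valid backdoor adjustment set for (treatment, outcome) when
#' it contains no descendant of the treatment and d-separates treatment from
#' outcome in the graph with the treatment's outgoing edges removed. All
#' candidate subsets of the treatment's non-descendants are enumerated
#' (exponential in their number; intended for the modest graphs of these
#' studies), optionally filtered to inclusion-minimal sets, and sorted by
#' size then lexicographically.
#'
#' @param dag a [dag()].
#' @param treatment,outcome distinct node names.
#' @param minimal_only return only inclusion-minimal sets (default TRUE).
#' @return list of `adjustment_set` objects (fields `treatment`, `outcome`,
#'   `Z`, `minimal`); empty list if no valid set exists.
#' @export
backdoor_sets <- function(dag, treatment, outcome, minimal_only = TRUE) {
  stopifnot(treatment != outcome,
            all(c(treatment, outcome) %in% dag_nodes(dag)))
  candidates <- setdiff(dag_nodes(dag),
                        c(treatment, outcome, dag_descendants(dag, treatment)))
  g_minus <- remove_outgoing(dag, treatment)
  valid <- list()
  for (k in 0:length(candidates)) {
    sets_k <- if (k == 0) list(character(0)) else
      utils::combn(sort(candidates), k, simplify = FALSE)
    for (Z in sets_k) {
      if (d_separated(g_minus, treatment, outcome, Z)) {
        valid[[length(valid) + 1]] <- Z
      }
    }
  }
  if (minimal_only && length(valid)) {
    keep <- vapply(valid, function(Z) {
      !any(vapply(valid, function(W)
        length(W) < length(Z) && all(W %in% Z), TRUE))
    }, TRUE)
    valid <- valid[keep]
  }
  ord <- order(lengths(valid),
               vapply(valid, function(Z) paste(Z, collapse = ","), ""))
  lapply(valid[ord], function(Z) {
    structure(list(treatment = treatment, outcome = outcome, Z = Z,
                   minimal = minimal_only),
              class = "adjustment_set")
  })
}

remove_outgoing <- function(dag, node) {
  a <- dag$amat
  a[node, ] <- FALSE
  dag(dag_nodes(dag), which_edges(a, dag_nodes(dag)))
}

#' Verify the backdoor criterion for a given set
#' @param dag a [dag()]; `treatment`, `outcome`, `Z` node names.
#' @param treatment,outcome node names.
#' @param Z candidate adjustment set (character vector, possibly empty).
#' @return TRUE iff `Z` satisfies the backdoor criterion.
#' @export
is_valid_adjustment <- function(dag, treatment, outcome, Z) {
  if (any(Z %in% c(treatment, outcome))) return(FALSE)
  if (any(Z %in% dag_descendants(dag, treatment))) return(FALSE)
  d_separated(remove_outgoing(dag, treatment), treatment, outcome, Z)
}

#' @export
print.adjustment_set <- function(x, ...) {
  cat("backdoor adjustment for ", x$treatment, " -> ", x$outcome, ": {",
      paste(x$Z, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Standardized path coefficients of a linear SCM
#'
#' Regresses every node on all of its parents by ordinary least squares on
#' the standardized (numerically coded) data; the fitted coefficients are the
#' edge path coefficients. Collinear parent sets trigger a warning and a
#' pseudo-inverse solution flagged in the output.
#'
#' @param data data frame.
#' @param dag a [dag()] over the data's columns.
#' @param standardized set FALSE if `data` is already on the scale you want;
#'   by default columns are standardized first (path-coefficient convention).
#' @return data frame with columns `from`, `to`, `estimate`, `se`, `flag`.
#' @export
path_coefficients <- function(data, dag, standardized = TRUE) {
  stopifnot(setequal(dag_nodes(dag), names(data)))
  df <- if (standardized) standardize(data) else as.data.frame(as_numeric_dataset(data))
  out <- data.frame(from = character(0), to = character(0),
                    estimate = numeric(0), se = numeric(0),
                    flag = character(0))
  for (v in dag_nodes(dag)) {
    pa <- dag_parents(dag, v)
    if (!length(pa)) next
    Xp <- as.matrix(df[, pa, drop = FALSE])
    y <- df[[v]]
    qrX <- qr(cbind(1, Xp))
    if (qrX$rank < ncol(Xp) + 1) {
      warning("collinear parents of '", v, "': pseudo-inverse solution used")
      if (!requireNamespace("MASS", quietly = TRUE)) {
        stop("MASS is required for the pseudo-inverse fallback")
      }
      co <- MASS::ginv(cbind(1, Xp)) %*% y
      est <- drop(co)[-1]
      ses <- rep(NA_real_, length(pa))
      flag <- "collinear"
    } else {
      fit <- stats::lm(y ~ Xp)
      sm <- summary(fit)$coefficients
      est <- sm[-1, 1]
      ses <- sm[-1, 2]
      flag <- "ok"
    }
    out <- rbind(out, data.frame(from = pa, to = v, estimate = unname(est),
                                 se = unname(ses), flag = flag))
  }
  rownames(out) <- NULL
  out
}

# all directed paths treatment -> ... -> outcome as lists of node sequences
directed_paths <- function(dag, from, to) {
  paths <- list()
  walk <- function(v, trail) {
    if (v == to) { paths[[length(paths) + 1]] <<- c(trail, v); return() }
    for (w in dag_children(dag, v)) {
      if (!(w %in% trail)) walk(w, c(trail, v))
    }
  }
  walk(from, character(0))
  paths
}

#' Total causal effect as a sum over directed paths
#'
#' Under a linear SCM the total effect of a treatment on an outcome is the
#' sum over all directed paths of the product of edge path coefficients
#' along each path. The standard error propagates the per-edge OLS standard
#' errors to first order (delta method, edges treated as independent — an
#' approximation recorded in the result).
#'
#' @param dag a [dag()].
#' @param path_coeffs output of [path_coefficients()].
#' @param treatment,outcome node names.
#' @return a `causal_effect` (kind "total", method "path-ols").
#' @export
total_effect <- function(dag, path_coeffs, treatment, outcome) {
  key <- paste0(path_coeffs$from, "->", path_coeffs$to)
  bhat <- stats::setNames(path_coeffs$estimate, key)
  bse <- stats::setNames(path_coeffs$se, key)
  paths <- directed_paths(dag, treatment, outcome)
  est <- 0
  grad <- stats::setNames(rep(0, length(bhat)), key)
  for (pp in paths) {
    ek <- paste0(pp[-length(pp)], "->", pp[-1])
    prod_all <- prod(bhat[ek])
    est <- est + prod_all
    for (e in ek) grad[e] <- grad[e] + prod_all / bhat[e]
  }
  se <- sqrt(sum((grad * bse)^2, na.rm = TRUE))
  new_causal_effect(treatment, outcome, kind = "total", estimate = est,
                    se = se, method = "path-ols",
                    adjustment = NULL, units = "standardized")
}

new_causal_effect <- function(treatment, outcome, kind, estimate, se, method,
                              adjustment, units) {
  structure(list(treatment = treatment, outcome = outcome, kind = kind,
                 estimate = unname(estimate), se = unname(se), method = method,
                 adjustment = adjustment, units = units),
            class = "causal_effect")
}

#' @export
print.causal_effect <- function(x, ...) {
  cat(sprintf("%s effect of %s on %s [%s]: %.4f (se %.4f, %s units)\n",
              x$kind, x$treatment, x$outcome, x$method, x$estimate, x$se,
              x$units))
  if (!is.null(x$adjustment)) {
    cat("  adjustment set: {", paste(x$adjustment, collapse = ", "), "}\n")
  }
  invisible(x)
}

# find one open backdoor path for an error message (brute force over the
# skeleton; used only on refusal, so clarity beats speed)
open_backdoor_path <- function(dag, treatment, outcome, Z) {
  g_minus <- remove_outgoing(dag, treatment)
  paths <- all_undirected_paths(g_minus, treatment, outcome)
  for (pp in paths) {
    if (path_is_active(g_minus, pp, Z)) return(pp)
  }
  NULL
}

all_undirected_paths <- function(dag, from, to) {
  sk <- dag$amat | t(dag$amat)
  nodes <- dag_nodes(dag)
  paths <- list()
  walk <- function(v, trail) {
    if (v == to) { paths[[length(paths) + 1]] <<- c(trail, v); return() }
    for (w in nodes[sk[v, ]]) if (!(w %in% trail)) walk(w, c(trail, v))
  }
  walk(from, character(0))
  paths
}

path_is_active <- function(dag, path, Z) {
  if (length(path) < 3) return(!any(path %in% Z))
  a <- dag$amat
  for (i in 2:(length(path) - 1)) {
    l <- path[i - 1]; m <- path[i]; r <- path[i + 1]
    collider <- a[l, m] && a[r, m]
    if (collider) {
      if (!(m %in% Z || any(dag_descendants(dag, m) %in% Z))) return(FALSE)
    } else {
      if (m %in% Z) return(FALSE)
    }
  }
  TRUE
}

#' Deconfounded ACE by backdoor-adjusted regression
#'
#' Regresses the outcome on the treatment plus a valid backdoor adjustment
#' set; the treatment coefficient is the average causal effect under the
#' linear SCM (the derivative of `E[Y | do(x)]`). An invalid adjustment set
#' is refused, naming an open backdoor path.
#'
#' @param data data frame.
#' @param dag a [dag()] over the data's columns.
#' @param treatment,outcome node names.
#' @param adjustment an `adjustment_set`, a character vector Z, or NULL to
#'   use the smallest minimal backdoor set (lexicographic tie-break).
#' @return a `causal_effect` (kind "total", method "adjusted-ols", natural
#'   units of the supplied data).
#' @export
ace_adjusted <- function(data, dag, treatment, outcome, adjustment = NULL) {
  if (is.null(adjustment)) {
    sets <- backdoor_sets(dag, treatment, outcome, minimal_only = TRUE)
    if (!length(sets)) stop("no valid backdoor adjustment set exists")
    Z <- sets[[1]]$Z
  } else {
    Z <- if (inherits(adjustment, "adjustment_set")) adjustment$Z else adjustment
    if (!is_valid_adjustment(dag, treatment, outcome, Z)) {
      pp <- open_backdoor_path(dag, treatment, outcome, Z)
      stop("invalid adjustment set {", paste(Z, collapse = ", "),
           "}: open backdoor path ",
           if (!is.null(pp)) paste(pp, collapse = " - ") else
             "(contains a descendant of the treatment)")
    }
  }
  m <- as.data.frame(as_numeric_dataset(data))
  fml <- stats::reformulate(c(treatment, Z), response = outcome)
  fit <- stats::lm(fml, data = m)
  sm <- summary(fit)$coefficients
  new_causal_effect(treatment, outcome, kind = "total",
                    estimate = sm[treatment, 1], se = sm[treatment, 2],
                    method = "adjusted-ols", adjustment = Z,
                    units = "natural")
}
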