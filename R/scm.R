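#' Structural causal models with known ground truth
#'
#' An `scm_spec` couples a [dag()] with per-node mechanisms and noise so that
#' datasets with a known causal structure can be simulated. Each node k is
#' generated in topological order as
#'
#'   latent_k = intercept_k + sum_over_parents b_{p->k} * g_{p->k}(x_p) + eps_k
#'
#' with `eps_k ~ N(0, noise_sd_k^2)`. The per-edge transform `g` is the
#' identity by default; `saturating` applies a softplus ramp
#' `tau * log(1 + exp((x - center)/tau))` (smooth change point at `center`),
#' and `quadratic` applies `(x - center)^2`. Continuous nodes report the
#' latent value; binary nodes threshold it; ordinal nodes bin it at fixed cut
#' points into ordered levels. Thresholded latent Gaussians keep closed-form
#' covariance oracles available for the purely linear continuous case.
#'
#' @param dag a [dag()].
#' @param coefficients named numeric vector of edge coefficients, names in the
#'   form `"parent->child"`; every edge of `dag` must be covered.
#' @param noise_sd named numeric vector of positive noise standard deviations,
#'   one per node (unnamed scalar recycles to all nodes).
#' @param kinds named list; each element is `list(kind = "continuous")`,
#'   `list(kind = "binary", threshold = t)` or `list(kind = "ordinal",
#'   cut_points = c(...), labels = c(...))`. Nodes absent from the list are
#'   continuous.
#' @param intercepts named numeric vector of node intercepts (default 0).
#' @param transforms optional named list keyed `"parent->child"`, each element
#'   `list(type = "saturating"|"quadratic", center = , scale = )`.
#' @return an object of class `scm_spec` with the topological order cached.
#' @export
make_scm <- function(dag, coefficients = NULL, noise_sd = 1, kinds = list(),
                     intercepts = NULL, transforms = list()) {
  stopifnot(inherits(dag, "dag"))
  e <- dag_edges(dag)
  keys <- if (nrow(e)) paste0(e$from, "->", e$to) else character(0)
  coefficients <- coefficients %||% stats::setNames(numeric(0), character(0))
  extra <- setdiff(names(coefficients), keys)
  if (length(extra)) {
    stop("coefficient supplied for non-edge pair(s): ", paste(extra, collapse = ", "))
  }
  missing_coef <- setdiff(keys, names(coefficients))
  if (length(missing_coef)) {
    stop("missing coefficient for edge(s): ", paste(missing_coef, collapse = ", "))
  }
  nodes <- dag_nodes(dag)
  if (length(noise_sd) == 1 && is.null(names(noise_sd))) {
    noise_sd <- stats::setNames(rep(noise_sd, length(nodes)), nodes)
  }
  if (!all(nodes %in% names(noise_sd))) stop("noise_sd missing for some nodes")
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  if (is.null(intercepts)) intercepts <- stats::setNames(rep(0, length(nodes)), nodes)
  ic <- stats::setNames(rep(0, length(nodes)), nodes)
  ic[names(intercepts)] <- intercepts
  bad_tr <- setdiff(names(transforms), keys)
  if (length(bad_tr)) stop("transform supplied for non-edge pair(s): ",
                           paste(bad_tr, collapse = ", "))
  kinds_full <- lapply(stats::setNames(nodes, nodes), function(v) {
    k <- kinds[[v]] %||% list(kind = "continuous")
    if (!k$kind %in% c("continuous", "binary", "ordinal")) {
      stop("unknown kind for node ", v)
    }
    if (k$kind == "binary" && is.null(k$threshold)) k$threshold <- 0
    if (k$kind == "ordinal") {
      if (is.null(k$cut_points) || is.null(k$labels)) {
        stop("ordinal node ", v, " needs cut_points and labels")
      }
      if (is.unsorted(k$cut_points, strictly = TRUE)) {
        stop("ordinal cut_points must be strictly increasing for node ", v)
      }
      if (length(k$labels) != length(k$cut_points) + 1) {
        stop("ordinal node ", v, ": need one more label than cut points")
      }
    }
    k
  })
  structure(list(dag = dag, coefficients = coefficients,
                 noise_sd = noise_sd[nodes], intercepts = ic,
                 kinds = kinds_full, transforms = transforms,
                 order = topo_sort(dag)),
            class = "scm_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scm_spec <- function(x, ...) {
  kk <- vapply(x$kinds, `[[`, "", "kind")
  cat("SCM over", length(dag_nodes(x$dag)), "nodes (",
      sum(kk == "continuous"), "continuous,", sum(kk == "binary"), "binary,",
      sum(kk == "ordinal"), "ordinal ) with",
      length(x$coefficients), "edges\n")
  invisible(x)
}

edge_transform <- function(tr, x) {
  if (is.null(tr)) return(x)
  softplus_ramp <- function(x, center, tau) {
    z <- (x - center) / tau
    tau * (pmax(z, 0) + log1p(exp(-abs(z))))   # numerically stable softplus
  }
  switch(tr$type,
         identity = x,
         saturating = softplus_ramp(x, tr$center, tr$scale %||% 1),
         # linear trend plus a softplus ramp `ratio` times as steep beyond the
         # change point: g(x) = x + ratio * softplus_ramp(x)
         linear_saturating = x + (tr$ratio %||% 1) *
           softplus_ramp(x, tr$center, tr$scale %||% 1),
         quadratic = (x - (tr$center %||% 0))^2,
         stop("unknown transform type: ", tr$type))
}

#' Sample a dataset from a structural causal model
#'
#' Ancestral sampling in topological order; the global seed is split
#' deterministically into one stream per node, so identical
#' `(scm, n, seed)` calls return bit-identical tables.
#'
#' @param scm an [make_scm()] spec.
#' @param n number of rows (>= 1).
#' @param seed integer seed.
#' @return a data frame with a `kinds` attribute (see [dataset_kinds()]);
#'   binary columns are 0/1 integers, ordinal columns ordered factors.
#' @export
sample_dataset <- function(scm, n, seed = 1) {
  stopifnot(inherits(scm, "scm_spec"), n >= 1)
  nodes <- dag_nodes(scm$dag)
  # numeric observed values as seen by child mechanisms:
  # continuous -> value, binary -> 0/1, ordinal -> level code
  vals <- matrix(NA_real_, n, length(nodes), dimnames = list(NULL, nodes))
  out <- vector("list", length(nodes))
  names(out) <- nodes
  # deterministic per-node streams: node seeds are drawn from the global
  # stream (arithmetic seed derivations give detectably correlated
  # Mersenne-Twister streams)
  set.seed(as.integer(seed))
  node_seeds <- sample.int(2147483647L, length(nodes))
  for (i in seq_along(scm$order)) {
    v <- scm$order[i]
    set.seed(node_seeds[match(v, nodes)])
    mu <- rep(scm$intercepts[[v]], n)
    for (p in dag_parents(scm$dag, v)) {
      key <- paste0(p, "->", v)
      mu <- mu + scm$coefficients[[key]] *
        edge_transform(scm$transforms[[key]], vals[, p])
    }
    latent <- mu + stats::rnorm(n, 0, scm$noise_sd[[v]])
    k <- scm$kinds[[v]]
    if (k$kind == "continuous") {
      out[[v]] <- latent
      vals[, v] <- latent
    } else if (k$kind == "binary") {
      out[[v]] <- as.integer(latent > k$threshold)
      vals[, v] <- out[[v]]
    } else {
      of <- discretize_ordinal(latent, k$cut_points, k$labels)
      out[[v]] <- of
      vals[, v] <- as.integer(of)
    }
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  kinds <- vapply(scm$kinds, `[[`, "", "kind")
  attr(df, "kinds") <- kinds
  attr(df, "provenance") <- list(seed = seed, n = n)
  df
}

#' Bin a continuous vector into ordered levels
#'
#' Monotone binning at strictly increasing cut points: values at or below the
#' first cut point map to the first label, and so on.
#'
#' @param values numeric vector.
#' @param cut_points strictly increasing numeric vector.
#' @param labels ordered level labels, one more than `cut_points`.
#' @return an ordered factor.
#' @export
discretize_ordinal <- function(values, cut_points, labels) {
  if (length(labels) != length(cut_points) + 1) {
    stop("need exactly one more label than cut points")
  }
  if (length(cut_points) && is.unsorted(cut_points, strictly = TRUE)) {
    stop("cut_points must be strictly increasing")
  }
  idx <- findInterval(values, cut_points) + 1L
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Implied covariance of a linear-Gaussian SCM
#'
#' For a purely continuous, identity-transform SCM with coefficient matrix B
#' (`B[parent, child]`) and noise variances D, the joint covariance is the
#' closed form `(I - B)^-T D (I - B)^-1`. Serves as the analytic oracle for
#' the ancestral sampler.
#'
#' @param scm a linear-Gaussian [make_scm()] spec (all nodes continuous, all
#'   transforms identity).
#' @return covariance matrix over the nodes.
#' @export
implied_covariance <- function(scm) {
  kk <- vapply(scm$kinds, `[[`, "", "kind")
  if (any(kk != "continuous")) stop("implied covariance requires all-continuous nodes")
  if (length(scm$transforms)) {
    types <- vapply(scm$transforms, `[[`, "", "type")
    if (any(types != "identity")) stop("implied covariance requires identity mechanisms")
  }
  nodes <- dag_nodes(scm$dag)
  p <- length(nodes)
  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  e <- dag_edges(scm$dag)
  for (i in seq_len(nrow(e))) {
    B[e$from[i], e$to[i]] <- scm$coefficients[[paste0(e$from[i], "->", e$to[i])]]
  }
  D <- diag(scm$noise_sd[nodes]^2, p)
  IB <- solve(diag(p) - B)
  S <- t(IB) %*% D %*% IB
  dimnames(S) <- list(nodes, nodes)
  S
}

#' Serialize / restore an SCM spec as JSON
#' @param scm an `scm_spec`; `file` a path.
#' @param file path to a JSON file.
#' @export
write_scm_json <- function(scm, file) {
  obj <- list(
    nodes = dag_nodes(scm$dag),
    edges = dag_edges(scm$dag),
    coefficients = as.list(scm$coefficients),
    noise_sd = as.list(scm$noise_sd),
    intercepts = as.list(scm$intercepts),
    kinds = scm$kinds,
    transforms = scm$transforms
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_scm_json
#' @export
read_scm_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  g <- dag(obj$nodes, as.matrix(obj$edges[, c("from", "to")]))
  kinds <- lapply(obj$kinds, function(k) {
    k$cut_points <- unlist(k$cut_points)
    k$labels <- unlist(k$labels)
    k
  })
  transforms <- lapply(obj$transforms, function(tr) tr)
  make_scm(g,
           coefficients = unlist(obj$coefficients),
           noise_sd = unlist(obj$noise_sd),
           kinds = kinds,
           intercepts = unlist(obj$intercepts),
           transforms = transforms)
}
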