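#' Directed acyclic graphs over named variables
#'
#' A `dag` is the structure of a Bayesian network: a set of named nodes and a
#' set of directed edges with no directed cycle. Internally it is stored as a
#' logical adjacency matrix `amat` with `amat[i, j] = TRUE` meaning an edge
#' i -> j; a topological order is cached at construction time.
#'
#' @param nodes character vector of unique node names.
#' @param edges edge set: a two-column matrix or data frame (from, to), or
#'   `NULL` for the empty graph.
#' @return an object of class `dag`.
#' @examples
#' g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' dag_parents(g, "C")
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  p <- length(nodes)
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns (from, to)")
    bad <- !(edges[, 1] %in% nodes) | !(edges[, 2] %in% nodes)
    if (any(bad)) {
      stop("edge endpoints not among declared nodes: ",
           paste(unique(c(edges[bad, 1], edges[bad, 2])), collapse = ", "))
    }
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    amat[cbind(edges[, 1], edges[, 2])] <- TRUE
  }
  ord <- topo_order_amat(amat)
  if (is.null(ord)) stop("cycle detected: edge set does not define a DAG")
  structure(list(nodes = nodes, amat = amat, order = nodes[ord]),
            class = "dag")
}

# Kahn's algorithm; returns an integer order or NULL if the graph is cyclic.
topo_order_amat <- function(amat) {
  p <- nrow(amat)
  indeg <- colSums(amat)
  ord <- integer(0)
  avail <- which(indeg == 0)
  indeg[avail] <- NA
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    ord <- c(ord, v)
    for (w in which(amat[v, ])) {
      indeg[w] <- indeg[w] - 1L
      if (!is.na(indeg[w]) && indeg[w] == 0L) { avail <- c(avail, w); indeg[w] <- NA }
    }
  }
  if (length(ord) < p) NULL else ord
}

#' @export
print.dag <- function(x, ...) {
  e <- dag_edges(x)
  cat("DAG with", length(x$nodes), "nodes and", nrow(e), "edges\n")
  if (nrow(e)) cat(paste0("  ", e$from, " -> ", e$to, collapse = "\n"), "\n")
  invisible(x)
}

#' @rdname dag
#' @param x a `dag`.
#' @export
dag_nodes <- function(x) x$nodes

#' Edge list of a DAG
#' @param x a `dag`.
#' @return data frame with columns `from`, `to` (lexicographic by from, to).
#' @export
dag_edges <- function(x) {
  idx <- which(x$amat, arr.ind = TRUE)
  e <- data.frame(from = x$nodes[idx[, 1]], to = x$nodes[idx[, 2]],
                  stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' @rdname dag_edges
#' @param node a node name.
#' @export
dag_parents <- function(x, node) x$nodes[x$amat[, node]]

#' @rdname dag_edges
#' @export
dag_children <- function(x, node) x$nodes[x$amat[node, ]]

#' Topological order of a DAG
#' @param x a `dag`.
#' @export
topo_sort <- function(x) x$order

#' Descendants / ancestors of a node (the node itself excluded)
#' @param x a `dag`; `node` a node name.
#' @param node node name.
#' @export
dag_descendants <- function(x, node) {
  reach <- reachable_from(x$amat, match(node, x$nodes))
  setdiff(x$nodes[reach], node)
}

#' @rdname dag_descendants
#' @export
dag_ancestors <- function(x, node) {
  reach <- reachable_from(t(x$amat), match(node, x$nodes))
  setdiff(x$nodes[reach], node)
}

# BFS reachability (including start) on an adjacency matrix.
reachable_from <- function(amat, start) {
  seen <- logical(nrow(amat))
  queue <- start
  seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(amat[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  seen
}

# TRUE if a directed path from -> to exists in amat.
has_directed_path <- function(amat, from, to) {
  reachable_from(amat, from)[to]
}

#' Sample a random DAG
#'
#' Draws edges independently over a random node permutation, so the result is
#' acyclic by construction. Used for property tests of the graphical
#' machinery.
#'
#' @param n_nodes number of nodes (named V1..Vn).
#' @param p_edge probability of including each forward edge.
#' @param seed integer seed.
#' @export
random_dag <- function(n_nodes, p_edge = 0.3, seed = 1) {
  set.seed(seed)
  nodes <- paste0("V", seq_len(n_nodes))
  perm <- sample(nodes)
  edges <- NULL
  for (i in seq_len(n_nodes - 1)) {
    for (j in seq((i + 1), n_nodes)) {
      if (stats::runif(1) < p_edge) edges <- rbind(edges, c(perm[i], perm[j]))
    }
  }
  dag(nodes, edges)
}

#' Export a DAG in DOT format
#' @param x a `dag`.
#' @param file optional path; if `NULL` the DOT string is returned.
#' @export
dag_to_dot <- function(x, file = NULL) {
  e <- dag_edges(x)
  lines <- c("digraph G {",
             paste0("  \"", x$nodes, "\";"),
             if (nrow(e)) paste0("  \"", e$from, "\" -> \"", e$to, "\";"),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Write / read a DAG as a two-column edge-list CSV
#'
#' Isolated nodes are written as rows with an empty `to` field so the node set
#' round-trips.
#' @param x a `dag`; `file` a path.
#' @param file path to a CSV file.
#' @export
write_dag_csv <- function(x, file) {
  e <- dag_edges(x)
  iso <- setdiff(x$nodes, unique(c(e$from, e$to)))
  if (length(iso)) e <- rbind(e, data.frame(from = iso, to = ""))
  utils::write.csv(e, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dag_csv
#' @export
read_dag_csv <- function(file) {
  e <- utils::read.csv(file, stringsAsFactors = FALSE, colClasses = "character")
  real <- e$to != ""
  dag(unique(c(e$from, e$to[real])), e[real, c("from", "to"), drop = FALSE])
}

#' Completed partially directed acyclic graph (CPDAG)
#'
#' Returns the Markov-equivalence class representative of a DAG: the skeleton
#' with v-structure edges directed, closed under the Meek orientation rules.
#' Undirected edges are encoded as `TRUE` in both directions of the adjacency
#' matrix.
#'
#' @param x a `dag`.
#' @return an object of class `cpdag` holding the mixed adjacency matrix.
#' @export
cpdag_of <- function(x) {
  p <- length(x$nodes)
  d <- x$amat            # directed (compelled so far)
  # start: skeleton undirected except v-structure edges
  u <- (d | t(d))        # skeleton, symmetric
  compelled <- matrix(FALSE, p, p, dimnames = dimnames(d))
  for (k in seq_len(p)) {
    pa <- which(d[, k])
    if (length(pa) >= 2) {
      for (a in pa) for (b in pa) {
        if (a < b && !u[a, b]) { compelled[a, k] <- TRUE; compelled[b, k] <- TRUE }
      }
    }
  }
  g <- u
  g[t(compelled)] <- FALSE           # remove the reversed direction of compelled edges
  # Meek rules to closure
  repeat {
    changed <- FALSE
    und <- which(g & t(g), arr.ind = TRUE)   # undirected pairs (both dirs)
    for (r in seq_len(nrow(und))) {
      a <- und[r, 1]; b <- und[r, 2]
      if (!(g[a, b] && g[b, a])) next        # may have been oriented this sweep
      orient <- FALSE
      # Rule 1: c -> a, c not adjacent to b  =>  a -> b
      for (cc in which(g[, a] & !g[a, ])) {
        if (!g[cc, b] && !g[b, cc]) { orient <- TRUE; break }
      }
      # Rule 2: directed path a -> c -> b  =>  a -> b
      if (!orient) {
        for (cc in which(g[a, ] & !g[, a])) {
          if (g[cc, b] && !g[b, cc]) { orient <- TRUE; break }
        }
      }
      # Rule 3: a - c -> b and a - e -> b with c, e nonadjacent  =>  a -> b
      if (!orient) {
        mid <- which(g[a, ] & g[, a] & g[, b] & !g[b, ])
        if (length(mid) >= 2) {
          for (i in seq_along(mid)) for (j in seq_along(mid)) {
            c1 <- mid[i]; c2 <- mid[j]
            if (c1 < c2 && !g[c1, c2] && !g[c2, c1]) { orient <- TRUE }
          }
        }
      }
      # Meek's rule 4 is only needed with external background knowledge;
      # rules 1-3 are complete when closing the pattern of a DAG.
      if (orient) { g[b, a] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  structure(list(nodes = x$nodes, amat = g), class = "cpdag")
}

#' @export
print.cpdag <- function(x, ...) {
  g <- x$amat
  dir <- which(g & !t(g), arr.ind = TRUE)
  und <- which(g & t(g), arr.ind = TRUE)
  und <- und[und[, 1] < und[, 2], , drop = FALSE]
  cat("CPDAG with", length(x$nodes), "nodes;",
      nrow(dir), "directed and", nrow(und), "undirected edges\n")
  if (nrow(dir)) cat(paste0("  ", x$nodes[dir[, 1]], " -> ", x$nodes[dir[, 2]],
                            collapse = "\n"), "\n")
  if (nrow(und)) cat(paste0("  ", x$nodes[und[, 1]], " -- ", x$nodes[und[, 2]],
                            collapse = "\n"), "\n")
  invisible(x)
}

#' Test equality of two CPDAGs (same nodes, same mixed edge set)
#' @param a,b `cpdag` objects.
#' @export
cpdag_equal <- function(a, b) {
  if (!setequal(a$nodes, b$nodes)) return(FALSE)
  m <- b$amat[a$nodes, a$nodes]
  identical(unname(a$amat), unname(m))
}
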