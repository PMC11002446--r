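# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: d-separation is re-derived by enumerating all
# simple undirected paths and applying the blocking rules path by path, and
# equivalence checks go through likelihood equality on shared data.

# all simple paths between x and y in the skeleton of `dag`
oracle_paths <- function(dag, x, y) {
  sk <- dag$amat | t(dag$amat)
  nodes <- dag_nodes(dag)
  paths <- list()
  walk <- function(v, trail) {
    if (v == y) {
      paths[[length(paths) + 1]] <<- c(trail, v)
      return()
    }
    for (w in nodes[sk[v, ]]) if (!(w %in% trail)) walk(w, c(trail, v))
  }
  walk(x, character(0))
  paths
}

# blocking rules applied to one path: non-collider blocked iff in Z,
# collider blocked unless it or a descendant is in Z
oracle_path_active <- function(dag, path, Z) {
  if (length(path) < 3) return(TRUE)
  a <- dag$amat
  for (i in 2:(length(path) - 1)) {
    l <- path[i - 1]; m <- path[i]; r <- path[i + 1]
    if (a[l, m] && a[r, m]) {
      if (!(m %in% Z || any(dag_descendants(dag, m) %in% Z))) return(FALSE)
    } else if (m %in% Z) return(FALSE)
  }
  TRUE
}

oracle_d_separated <- function(dag, x, y, Z) {
  for (p in oracle_paths(dag, x, y)) {
    if (oracle_path_active(dag, p, Z)) return(FALSE)
  }
  TRUE
}

# the three-node confounded design used throughout: T = Z + e, Y = 0.5 T + Z + u
confounded_scm <- function() {
  g <- dag(c("Z", "T", "Y"), rbind(c("Z", "T"), c("Z", "Y"), c("T", "Y")))
  make_scm(g, c("Z->T" = 1, "Z->Y" = 1, "T->Y" = 0.5), noise_sd = 1)
}
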