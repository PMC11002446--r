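test_that("penalty rejects a spurious parent for independent Gaussians", {
  set.seed(1)
  d <- data.frame(A = rnorm(5000), B = rnorm(5000))
  expect_lt(local_bic("B", "A", d, score = "gaussian"),
            local_bic("B", character(0), d, score = "gaussian"))
})

test_that("score cache returns bit-identical values and decomposability holds", {
  set.seed(2)
  d <- data.frame(A = rnorm(500), B = rnorm(500), C = rnorm(500))
  ctx <- bic_context(d, "gaussian")
  s1 <- local_bic("C", c("A", "B"), context = ctx)
  s2 <- local_bic("C", c("B", "A"), context = ctx)   # cached under sorted key
  expect_identical(s1, s2)
  expect_identical(s1, local_bic("C", c("A", "B"), d, score = "gaussian"))
  # decomposability: changing one node's parents leaves other locals intact
  g1 <- dag(names(d), rbind(c("A", "B")))
  g2 <- dag(names(d), rbind(c("A", "B"), c("A", "C")))
  l1 <- dag_score(d, g1, score = "gaussian")
  l2 <- dag_score(d, g2, score = "gaussian")
  expect_identical(l1$local[["A"]], l2$local[["A"]])
  expect_identical(l1$local[["B"]], l2$local[["B"]])
  expect_equal(l1$total, sum(l1$local))
})

test_that("chain data scores the true DAG above the empty DAG, matching a direct likelihood oracle", {
  g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  scm <- make_scm(g, c("A->B" = 1, "B->C" = 1))
  d <- sample_dataset(scm, 2000, seed = 7)
  empty <- dag(c("A", "B", "C"))
  s_true <- dag_score(d, g, score = "gaussian")$total
  s_empty <- dag_score(d, empty, score = "gaussian")$total
  expect_gt(s_true, s_empty)
  # oracle: total Gaussian log-likelihood computed per node by direct lm
  n <- nrow(d)
  ll_node <- function(fml) {
    r <- stats::resid(stats::lm(fml, data = d))
    s2 <- sum(r^2) / n
    -n / 2 * (log(2 * pi * s2) + 1)
  }
  oracle_true <- ll_node(A ~ 1) + ll_node(B ~ A) + ll_node(C ~ B) -
    (2 + 3 + 3) / 2 * log(n)
  expect_equal(s_true, oracle_true, tolerance = 1e-8)
})

test_that("the mixed score enforces conditional-Gaussian admissibility", {
  d <- sample_dataset(food_template("dairy"), 300, seed = 3)
  expect_error(local_bic("taste", "temperature", d, score = "mixed"),
               "admissibility")
  # discrete-on-discrete multinomial score works
  expect_true(is.finite(local_bic("grade", c("odour", "turbidity"), d,
                                  score = "mixed")))
  # continuous node may take any parents
  expect_true(is.finite(local_bic("pH", c("temperature", "odour"), d,
                                  score = "mixed")))
})

test_that("hill climbing leaves independent columns unconnected", {
  set.seed(4)
  d <- data.frame(X = rnorm(2000), Y = rnorm(2000))
  hc <- hill_climb(d, n_restarts = 2, seed = 1)
  expect_equal(nrow(dag_edges(hc$dag)), 0)
})

test_that("hill climbing recovers the chain equivalence class, matching exhaustive search", {
  g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  scm <- make_scm(g, c("A->B" = 1, "B->C" = 1))
  d <- sample_dataset(scm, 5000, seed = 5)
  hc <- hill_climb(d, n_restarts = 2, seed = 1)
  expect_true(cpdag_equal(cpdag_of(hc$dag), cpdag_of(g)))
  # exhaustive oracle: best of all 25 three-node DAGs
  all_dags <- enumerate_dags(c("A", "B", "C"))
  expect_length(all_dags, 25)
  best <- max(vapply(all_dags, function(gg) dag_score(d, gg)$total, 0))
  expect_equal(hc$score$total, best, tolerance = 1e-9)
})

test_that("hill-climb score traces are nondecreasing and column order is irrelevant", {
  scm <- confounded_scm()
  d <- sample_dataset(scm, 2000, seed = 6)
  hc <- hill_climb(d, n_restarts = 3, seed = 2)
  for (tr in hc$trace) expect_true(all(diff(tr) >= -1e-9))
  hc_perm <- hill_climb(d[, c("Y", "Z", "T")], n_restarts = 3, seed = 2)
  expect_equal(dag_edges(hc_perm$dag), dag_edges(hc$dag))
})

test_that("whitelists are kept, blacklists respected, forced cycles refused", {
  scm <- confounded_scm()
  d <- sample_dataset(scm, 2000, seed = 8)
  wl <- data.frame(from = "Z", to = "T")
  bl <- data.frame(from = "T", to = "Y")
  hc <- hill_climb(d, whitelist = wl, blacklist = bl, n_restarts = 2, seed = 1)
  e <- dag_edges(hc$dag)
  expect_true(any(e$from == "Z" & e$to == "T"))
  expect_false(any(e$from == "T" & e$to == "Y"))
  expect_error(hill_climb(d, whitelist = data.frame(from = c("Z", "T"),
                                                    to = c("T", "Z"))),
               "cycle")
})

test_that("structure MCMC matches the exact enumerated posterior on small problems", {
  # strongly correlated pair: nearly all posterior mass on the two
  # single-edge orientations
  set.seed(2)
  x <- rnorm(2000)
  d2 <- data.frame(A = x, B = 0.9 * x + rnorm(2000, 0, sqrt(1 - 0.81)))
  ep <- structure_mcmc(d2, n_samples = 20000, burn_in = 2000, seed = 4)
  expect_gt(ep$prob["A", "B"] + ep$prob["B", "A"], 0.95)
  expect_true(all(diag(ep$prob) == 0))
  # 3-node data: edge frequencies within 0.05 of the BIC-weighted enumeration
  g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  scm <- make_scm(g, c("A->B" = 1, "B->C" = 1))
  d3 <- sample_dataset(scm, 2000, seed = 12)
  ep3 <- structure_mcmc(d3, n_samples = 20000, burn_in = 2000, seed = 5)
  exact <- exact_edge_posterior(d3)
  expect_lt(max(abs(ep3$prob - exact)), 0.05)
})

test_that("a single-column dataset yields an empty posterior", {
  d <- data.frame(A = rnorm(100))
  ep <- structure_mcmc(d, n_samples = 500, burn_in = 100, seed = 1)
  expect_equal(dim(ep$prob), c(1, 1))
  expect_true(all(ep$prob == 0))
})
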