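test_that("d-separation handles the canonical chain and collider", {
  chain <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_true(d_separated(chain, "A", "C", "B"))
  expect_false(d_separated(chain, "A", "C"))
  coll <- dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  expect_true(d_separated(coll, "A", "B"))
  expect_false(d_separated(coll, "A", "B", "C"))
  # conditioning on a collider's descendant also opens the path
  coll2 <- dag(c("A", "B", "C", "D"),
               rbind(c("A", "C"), c("B", "C"), c("C", "D")))
  expect_false(d_separated(coll2, "A", "B", "D"))
  expect_error(d_separated(chain, "A", "A"), "disjoint")
})

test_that("Bayes-ball agrees with brute-force path blocking on random DAGs", {
  n_queries <- 0
  for (s in 1:30) {
    g <- random_dag(sample(4:8, 1), 0.35, seed = s)
    nodes <- dag_nodes(g)
    for (x in nodes) for (y in nodes) {
      if (x >= y) next
      zs <- c(list(character(0)), as.list(setdiff(nodes, c(x, y))))
      for (Z in zs) {
        expect_identical(d_separated(g, x, y, Z),
                         oracle_d_separated(g, x, y, Z))
        n_queries <- n_queries + 1
      }
    }
  }
  expect_gt(n_queries, 2000)
})

test_that("d-separation is symmetric and satisfies the local Markov property", {
  for (s in 1:10) {
    g <- random_dag(6, 0.4, seed = 100 + s)
    nodes <- dag_nodes(g)
    x <- nodes[1]; y <- nodes[4]
    Z <- nodes[c(2, 6)]
    expect_identical(d_separated(g, x, y, Z), d_separated(g, y, x, Z))
    # each node given its parents is separated from non-descendant non-parents
    for (v in nodes) {
      pa <- dag_parents(g, v)
      others <- setdiff(nodes, c(v, pa, dag_descendants(g, v)))
      for (w in others) expect_true(d_separated(g, v, w, pa))
    }
  }
})

test_that("backdoor sets: canonical confounder and randomized treatment", {
  tri <- dag(c("Z", "T", "Y"), rbind(c("Z", "T"), c("Z", "Y"), c("T", "Y")))
  sets <- backdoor_sets(tri, "T", "Y")
  expect_length(sets, 1)
  expect_equal(sets[[1]]$Z, "Z")
  exo <- dag(c("T", "Y", "M"), rbind(c("T", "M"), c("M", "Y")))
  sets2 <- backdoor_sets(exo, "T", "Y")
  expect_equal(sets2[[1]]$Z, character(0))
})

test_that("returned backdoor sets verify and brute force finds nothing smaller", {
  for (s in 1:20) {
    g <- random_dag(6, 0.4, seed = 200 + s)
    nodes <- dag_nodes(g)
    for (pair in list(nodes[c(1, 6)], nodes[c(2, 4)])) {
      t <- pair[1]; y <- pair[2]
      sets <- backdoor_sets(g, t, y, minimal_only = TRUE)
      cand <- setdiff(nodes, c(t, y, dag_descendants(g, t)))
      all_valid_sizes <- integer(0)
      for (k in 0:length(cand)) {
        combos <- if (k == 0) list(character(0)) else
          utils::combn(cand, k, simplify = FALSE)
        for (Z in combos) {
          if (is_valid_adjustment(g, t, y, Z)) {
            all_valid_sizes <- c(all_valid_sizes, length(Z))
          }
        }
      }
      if (length(sets)) {
        for (a in sets) expect_true(is_valid_adjustment(g, t, y, a$Z))
        expect_equal(min(lengths(lapply(sets, `[[`, "Z"))),
                     min(all_valid_sizes))
      } else {
        expect_length(all_valid_sizes, 0)
      }
    }
  }
})

test_that("path coefficients recover a planted edge weight", {
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  scm <- make_scm(g, c("A->B" = 0.7), noise_sd = 1)
  d <- sample_dataset(scm, 10000, seed = 9)
  pc <- path_coefficients(d, g)
  # standardized coefficient: 0.7 / sd(B) with sd(B) = sqrt(1.49)
  expect_equal(pc$estimate, 0.7 / sqrt(1.49), tolerance = 0.03)
  expect_true(all(pc$flag == "ok"))
  pc_nat <- path_coefficients(d, g, standardized = FALSE)
  expect_equal(pc_nat$estimate, 0.7, tolerance = 0.03)
  # edgeless DAG: empty map
  expect_equal(nrow(path_coefficients(d, dag(c("A", "B")))), 0)
})

test_that("collinear parents trigger a warning and a flagged pseudo-inverse fit", {
  set.seed(10)
  a <- rnorm(200)
  d <- data.frame(A = a, B = a, C = a + rnorm(200))
  g <- dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  expect_warning(pc <- path_coefficients(d, g, standardized = FALSE),
                 "collinear")
  expect_true(all(pc$flag == "collinear"))
})

test_that("total effect sums coefficient products over directed paths", {
  g <- dag(c("T", "M", "Y"), rbind(c("T", "M"), c("M", "Y"), c("T", "Y")))
  pc <- data.frame(from = c("T", "M", "T"), to = c("M", "Y", "Y"),
                   estimate = c(0.5, 0.4, 0.3), se = c(0.01, 0.01, 0.01),
                   flag = "ok")
  te <- total_effect(g, pc, "T", "Y")
  expect_equal(te$estimate, 0.5 * 0.4 + 0.3)
  expect_equal(te$kind, "total")
  # single edge: the effect is the coefficient itself
  te2 <- total_effect(g, pc, "M", "Y")
  expect_equal(te2$estimate, 0.4)
  # no directed path: a valid zero
  te3 <- total_effect(g, pc, "Y", "T")
  expect_equal(te3$estimate, 0)
})

test_that("path-sum total effect matches regression under do-randomized sampling", {
  # 6-node SCM; randomizing T = cutting its incoming edges, then the slope of
  # Y on T in interventional data is the total effect
  nodes <- c("U", "T", "M1", "M2", "Y", "W")
  g <- dag(nodes, rbind(c("U", "T"), c("U", "Y"), c("T", "M1"), c("M1", "Y"),
                        c("T", "M2"), c("M2", "Y"), c("W", "M2")))
  cf <- c("U->T" = 0.8, "U->Y" = 0.5, "T->M1" = 0.6, "M1->Y" = 0.5,
          "T->M2" = 0.4, "M2->Y" = -0.3, "W->M2" = 0.5)
  scm <- make_scm(g, cf, noise_sd = 1)
  d <- sample_dataset(scm, 20000, seed = 14)
  pc <- path_coefficients(d, g, standardized = FALSE)
  te <- total_effect(g, pc, "T", "Y")
  # interventional oracle: same SCM with U->T cut (T exogenous)
  g_do <- dag(nodes, rbind(c("U", "Y"), c("T", "M1"), c("M1", "Y"),
                           c("T", "M2"), c("M2", "Y"), c("W", "M2")))
  scm_do <- make_scm(g_do, cf[names(cf) != "U->T"], noise_sd = 1)
  d_do <- sample_dataset(scm_do, 20000, seed = 15)
  fit <- summary(stats::lm(Y ~ T, data = d_do))$coefficients
  expect_lt(abs(te$estimate - fit["T", 1]),
            2 * sqrt(te$se^2 + fit["T", 2]^2))
  expect_equal(te$estimate, 0.6 * 0.5 + 0.4 * (-0.3), tolerance = 0.05)
})

test_that("adjusted ACE: null recovery under randomization, deconfounding when adjusted", {
  scm <- confounded_scm()
  g <- scm$dag
  d <- sample_dataset(scm, 5000, seed = 16)
  # naive (unadjusted formula oracle): 0.5 + Cov(T, Z)/Var(T) = 1.0
  naive <- stats::coef(stats::lm(Y ~ T, as.data.frame(as_numeric_dataset(d))))["T"]
  expect_equal(unname(naive), 1.0, tolerance = 0.05)
  adj <- ace_adjusted(d, g, "T", "Y")
  expect_equal(adj$adjustment, "Z")
  expect_lt(abs(adj$estimate - 0.5), 2 * adj$se)
  # randomized treatment with zero planted effect
  g0 <- dag(c("T", "Y"))
  scm0 <- make_scm(g0, noise_sd = 1)
  d0 <- sample_dataset(scm0, 5000, seed = 17)
  a0 <- ace_adjusted(d0, g0, "T", "Y")
  expect_lt(abs(a0$estimate), 2 * a0$se)
})

test_that("an invalid adjustment set is refused naming an open backdoor path", {
  scm <- confounded_scm()
  d <- sample_dataset(scm, 500, seed = 18)
  err <- tryCatch(ace_adjusted(d, scm$dag, "T", "Y",
                               adjustment = character(0)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "open backdoor path")
  expect_match(err, "Z")
})
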