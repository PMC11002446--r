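test_that("make_scm validates its contract", {
  g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_error(make_scm(g, c("A->B" = 1, "B->C" = 1, "A->C" = 1)),
               "non-edge")
  expect_error(make_scm(g, c("A->B" = 1)), "missing coefficient")
  expect_error(make_scm(g, c("A->B" = 1, "B->C" = 1), noise_sd = 0),
               "positive")
  expect_error(make_scm(g, c("A->B" = 1, "B->C" = 1),
                        kinds = list(C = list(kind = "ordinal",
                                              cut_points = c(1, 0),
                                              labels = c("a", "b", "c")))),
               "strictly increasing")
  scm <- make_scm(g, c("A->B" = 1, "B->C" = 1))
  expect_equal(scm$order, c("A", "B", "C"))
})

test_that("implied covariance matches the closed form on a unit chain", {
  g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  scm <- make_scm(g, c("A->B" = 1, "B->C" = 1), noise_sd = 1)
  S <- implied_covariance(scm)
  # (I - B)^-T D (I - B)^-1 for the chain: Var(C) = 3, Cov(A, C) = 1
  expect_equal(S["C", "C"], 3)
  expect_equal(S["B", "B"], 2)
  expect_equal(S["A", "C"], 1)
})

test_that("independent nodes sample as uncorrelated columns", {
  scm <- make_scm(dag(c("X", "Y", "W")), noise_sd = 1)
  d <- sample_dataset(scm, 4000, seed = 3)
  r <- stats::cor(as_numeric_dataset(d))
  expect_lt(max(abs(r[upper.tri(r)])), 3 / sqrt(4000))
})

test_that("re-seeding reproduces tables bit-exactly", {
  scm <- food_template("dairy")
  d1 <- sample_dataset(scm, 200, seed = 9)
  d2 <- sample_dataset(scm, 200, seed = 9)
  expect_identical(d1, d2)
  d3 <- sample_dataset(scm, 200, seed = 10)
  expect_false(identical(d1$temperature, d3$temperature))
})

test_that("sample covariance converges to the implied covariance", {
  set.seed(5)
  g <- random_dag(8, 0.3, seed = 4)
  e <- dag_edges(g)
  cf <- stats::setNames(stats::runif(nrow(e), 0.4, 1),
                        paste0(e$from, "->", e$to))
  scm <- make_scm(g, cf, noise_sd = 1)
  S <- implied_covariance(scm)
  Shat <- stats::cov(as_numeric_dataset(sample_dataset(scm, 50000, seed = 11)))
  expect_lt(norm(Shat - S[colnames(Shat), colnames(Shat)], "F") / norm(S, "F"),
            0.02)
})

test_that("discretize_ordinal bins monotonically with exact edge handling", {
  out <- discretize_ordinal(c(-1, 0.5, 2), c(0, 1), c("low", "med", "high"))
  expect_equal(as.character(out), c("low", "med", "high"))
  expect_true(is.ordered(out))
  const <- discretize_ordinal(rep(-5, 4), c(0, 1), c("low", "med", "high"))
  expect_equal(as.character(const), rep("low", 4))
  expect_error(discretize_ordinal(1:3, c(1, 1), c("a", "b", "c")),
               "strictly increasing")
  expect_error(discretize_ordinal(1:3, c(0, 1), c("a", "b")), "label")
})

test_that("tercile cut points of a standard normal give equal level frequencies", {
  set.seed(8)
  n <- 20000
  x <- stats::rnorm(n)
  lv <- discretize_ordinal(x, stats::qnorm(c(1/3, 2/3)), c("l", "m", "h"))
  freq <- as.numeric(table(lv)) / n
  expect_true(all(abs(freq - 1/3) < 3 / sqrt(n)))
})

test_that("binary and ordinal kinds produce the declared codings", {
  d <- sample_dataset(food_template("dairy"), 5000, seed = 2)
  expect_setequal(levels(d$grade), c("low", "medium", "high"))
  expect_equal(nlevels(d$grade), 3)
  expect_true(all(d$odour %in% c(0L, 1L)))
  expect_equal(unname(dataset_kinds(d)[c("taste", "grade", "pH")]),
               c("binary", "ordinal", "continuous"))
})

test_that("SCM JSON serialization round-trips and reproduces samples", {
  scm <- food_template("dairy")
  f <- tempfile(fileext = ".json")
  write_scm_json(scm, f)
  scm2 <- read_scm_json(f)
  expect_equal(dag_edges(scm2$dag), dag_edges(scm$dag))
  expect_identical(sample_dataset(scm, 50, seed = 4),
                   sample_dataset(scm2, 50, seed = 4))
})

test_that("dataset CSV round-trips with its sidecar schema", {
  d <- sample_dataset(food_template("dairy"), 100, seed = 6)
  f <- tempfile(fileext = ".csv")
  write_dataset(d, f)
  d2 <- read_dataset(f)
  expect_equal(dataset_kinds(d2), dataset_kinds(d))
  expect_true(is.ordered(d2$grade))
  expect_equal(as.character(d2$grade), as.character(d$grade))
  expect_equal(d2$temperature, d$temperature, tolerance = 1e-12)
})
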