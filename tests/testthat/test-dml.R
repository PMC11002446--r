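test_that("cross-fitted residuals satisfy their contracts", {
  set.seed(1)
  n <- 600
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$indep <- rnorm(n)
  d$linear <- 2 * d$x1 - d$x2
  # independent target: nothing to explain
  r_ind <- crossfit_residuals(d, "indep", c("x1", "x2"),
                              learner = list(type = "lm"), seed = 2)
  expect_equal(stats::var(r_ind), stats::var(d$indep), tolerance = 0.1 * stats::var(d$indep))
  # exact linear signal with a flexible learner: most variance removed
  d2 <- data.frame(x1 = rnorm(5000), x2 = rnorm(5000))
  d2$y <- d2$x1 + 0.5 * d2$x2
  r_lin <- crossfit_residuals(d2, "y", c("x1", "x2"), n_folds = 5, seed = 3)
  expect_lt(stats::var(r_lin) / stats::var(d2$y), 0.1)
  # centring
  expect_lt(abs(mean(r_ind)), 1e-10)
  expect_lt(abs(mean(r_lin)), 1e-10)
  expect_error(crossfit_residuals(d, "indep", "indep"), "exclude")
  expect_error(crossfit_residuals(d[1:8, ], "indep", "x1", n_folds = 2),
               "at least 5 rows")
})

test_that("dml_ace removes confounding where the naive slope is biased", {
  scm <- confounded_scm()
  d <- sample_dataset(scm, 5000, seed = 21)
  m <- as.data.frame(as_numeric_dataset(d))
  naive <- stats::coef(stats::lm(Y ~ T, m))["T"]
  expect_equal(unname(naive), 1.0, tolerance = 0.05)  # 0.5 + Cov(T,Z)/Var(T)
  res <- dml_ace(d, "T", "Y", "Z", seed = 4)
  expect_equal(res$theta, 0.5, tolerance = 0.05)
  expect_lt(res$se, 0.05)
  expect_length(res$resid_treatment, nrow(d))
})

test_that("theta is shift-invariant and inversely scales with the treatment", {
  scm <- confounded_scm()
  d <- as.data.frame(as_numeric_dataset(sample_dataset(scm, 2000, seed = 22)))
  base <- dml_ace(d, "T", "Y", "Z", learner = list(type = "lm"), seed = 5)
  shifted <- d; shifted$T <- shifted$T + 100; shifted$Y <- shifted$Y - 7
  s <- dml_ace(shifted, "T", "Y", "Z", learner = list(type = "lm"), seed = 5)
  expect_equal(s$theta, base$theta, tolerance = 1e-10)
  scaled <- d; scaled$T <- scaled$T * 4
  sc <- dml_ace(scaled, "T", "Y", "Z", learner = list(type = "lm"), seed = 5)
  expect_equal(sc$theta, base$theta / 4, tolerance = 1e-10)
})

test_that("re-splitting folds moves theta by less than two standard errors", {
  scm <- confounded_scm()
  d <- sample_dataset(scm, 4000, seed = 23)
  r1 <- dml_ace(d, "T", "Y", "Z", seed = 31)
  r2 <- dml_ace(d, "T", "Y", "Z", seed = 77)
  expect_lt(abs(r1$theta - r2$theta), 2 * sqrt(r1$se^2 + r2$se^2))
})

test_that("single-fold DML reproduces the naive in-sample plug-in", {
  scm <- confounded_scm()
  d <- sample_dataset(scm, 1500, seed = 24)
  r_lm <- dml_ace(d, "T", "Y", "Z", learner = list(type = "lm"),
                  n_folds = 1, seed = 1)
  # with a linear nuisance the in-sample residual ratio is the partialled
  # OLS coefficient (Frisch-Waugh)
  m <- as.data.frame(as_numeric_dataset(d))
  expect_equal(r_lm$theta,
               unname(stats::coef(stats::lm(Y ~ T + Z, m))["T"]),
               tolerance = 1e-8)
})

test_that("a treatment fully explained by covariates is a degeneracy error", {
  set.seed(6)
  d <- data.frame(z = rnorm(300))
  d$t <- 2 * d$z          # deterministic given covariates
  d$y <- d$t + rnorm(300)
  expect_error(dml_ace(d, "t", "y", "z", learner = list(type = "lm"),
                       seed = 1),
               "degenerate")
})

test_that("randomized null treatment is covered by the 2-se interval in most seeds", {
  hits <- 0
  for (s in 1:10) {
    set.seed(700 + s)
    n <- 1200
    d <- data.frame(Z = rnorm(n))
    d$T <- rnorm(n)                       # randomized, theta = 0
    d$Y <- d$Z + rnorm(n)
    r <- dml_ace(d, "T", "Y", "Z", learner = list(type = "lm"), seed = s)
    if (abs(r$theta) < 2 * r$se) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
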