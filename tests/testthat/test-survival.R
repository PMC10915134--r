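test_that("median split sends ties to low and rejects constant scores", {
  expect_equal(as.character(medianSplit(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(medianSplit(c(1, 2, 3))),
               c("low", "low", "high"))  # the median itself goes low
  expect_error(medianSplit(c(5, 5, 5)), "identical")
  expect_error(medianSplit(3), ">= 2")
})

test_that("log-rank reproduces the hand-computed two-group chi-square", {
  # groups A {1,2} and B {3,4}, all events: O - E = 2 - 0.8333,
  # variance 0.4722 -> chi-square 2.882
  r <- kmLogrank(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(r$chisq, 2.882, tolerance = 1e-3)
  expect_equal(r$df, 1L)

  # duplicated identical groups give chi-square 0, p 1
  same <- kmLogrank(rep(c(1, 3, 5), 2), rep(c(1, 0, 1), 2),
                    rep(c("A", "B"), each = 3))
  expect_equal(same$chisq, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1, tolerance = 1e-10)

  expect_error(kmLogrank(1:4, rep(0, 4), rep(c("A", "B"), 2)), "no events")
})

test_that("Cox fit maximizes the partial likelihood", {
  # mirrored data: every subject duplicated with the covariate flipped
  tm <- rep(c(2, 5, 7, 9), 2); ev <- rep(c(1, 1, 0, 1), 2)
  x <- c(0, 1, 0, 1, 1, 0, 1, 0)
  r <- coxFit(tm, ev, data.frame(x = x))
  expect_equal(r$coefficients$coef, 0, tolerance = 1e-8)
  expect_equal(r$coefficients$hr, 1, tolerance = 1e-8)
  expect_true(r$converged)

  # random small datasets vs a grid/golden-section oracle (Breslow ties)
  set.seed(5)
  for (i in 1:15) {
    n <- 8
    tm <- sample(20, n); ev <- rbinom(n, 1, 0.8)
    if (sum(ev) == 0) ev[1] <- 1
    x <- rnorm(n)
    fit <- coxFit(tm, ev, data.frame(x = x), ties = "breslow")
    expect_equal(fit$coefficients$coef, naiveCoxBeta(tm, ev, x),
                 tolerance = 1e-4)
  }

  expect_error(coxFit(1:4, c(1, 1, 0, 1), data.frame(x = rep(2, 4))),
               "constant")
})

test_that("complete separation is flagged as non-convergence", {
  # binary covariate perfectly ordering the event times
  tm <- c(1, 2, 3, 10, 11, 12); ev <- rep(1, 6)
  x <- c(1, 1, 1, 0, 0, 0)
  r <- coxFit(tm, ev, data.frame(x = x))
  expect_false(r$converged)
})

test_that("Harrell's C follows the usable-pair contract", {
  expect_equal(harrellC(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)), 1)
  expect_equal(harrellC(c(1, 2, 3), c(1, 0, 1), c(1, 3, 2)), 0)
  expect_equal(harrellC(c(1, 2, 3), c(1, 1, 1), c(2, 2, 2)), 0.5)
  expect_error(harrellC(c(3, 1), c(0, 0), c(1, 2)), "usable")

  set.seed(17)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    tm <- sample(50, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.7)
    if (!any(ev == 1)) ev[1] <- 1
    rk <- sample(5, n, replace = TRUE)
    got <- tryCatch(harrellC(tm, ev, rk), error = function(e) NA)
    want <- tryCatch(naiveHarrellC(tm, ev, rk), error = function(e) NA)
    expect_equal(got, want)
  }
})

test_that("cross-validated comparison is seeded, paired and self-consistent", {
  set.seed(23)
  n <- 120
  dat <- data.frame(os_time = rexp(n, 0.05 * exp(0.8 * rnorm(n))),
                    os_event = rbinom(n, 1, 0.7),
                    x = rnorm(n), y = rnorm(n))
  dat$os_time <- rexp(n, 0.05 * exp(1 * dat$x))
  r1 <- cvCompareModels(dat, list(a = "x", b = "y"),
                        repeats = 4, folds = 4, seed = 9)
  r2 <- cvCompareModels(dat, list(a = "x", b = "y"),
                        repeats = 4, folds = 4, seed = 9)
  expect_identical(r1$c_values, r2$c_values)
  # invariant to sample order under the same seed
  perm <- sample(n)
  r3 <- cvCompareModels(dat[perm, ], list(a = "x", b = "y"),
                        repeats = 4, folds = 4, seed = 9)
  expect_equal(r1$c_values, r3$c_values)
  # a model compared with itself ties exactly
  self <- cvCompareModels(dat, list(a = "x", a2 = "x"),
                          repeats = 3, folds = 4, seed = 2)
  expect_identical(self$c_values[, "a"], self$c_values[, "a2"])
  expect_equal(self$pairwise_p["a", "a2"], 1)
  # the informative covariate wins
  expect_gt(r1$mean_c[["a"]], r1$mean_c[["b"]])
})

test_that("staging rules encode ISS, R-ISS and R2-ISS", {
  expect_equal(stageISS(6.0, 4.0), 3L)
  expect_equal(stageISS(3.0, 3.6), 1L)
  expect_equal(stageISS(4.0, 4.0), 2L)
  expect_true(is.na(stageISS(NA, 4.0)))

  expect_equal(stageRISS(1L, FALSE, FALSE), 1L)
  expect_equal(stageRISS(3L, TRUE, FALSE), 3L)
  expect_equal(stageRISS(2L, TRUE, TRUE), 2L)
  expect_equal(stageRISS(3L, FALSE, FALSE), 2L)

  r2 <- stageR2ISS(c(1L, 3L, 2L), c(FALSE, TRUE, FALSE),
                   c(FALSE, FALSE, FALSE), c(FALSE, FALSE, TRUE),
                   c(FALSE, TRUE, FALSE))
  expect_equal(r2$score, c(0, 3.5, 1.5))
  expect_equal(as.character(r2$group), c("Low", "High", "Int-High"))
})
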