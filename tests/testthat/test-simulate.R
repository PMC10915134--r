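test_that("expression generator builds the documented marker structure", {
  sim0 <- simulateExpression(40, nGenes = 600, nMarkers = 30,
                             lambda = rep(0, 40), seed = 2)
  markers <- sim0$signature@genes
  bg <- setdiff(rownames(sim0$expr), markers)
  # at lambda 0 markers sit ~2 log2-units above background
  diffMean <- mean(sim0$expr[markers, ]) - mean(sim0$expr[bg, ])
  se <- sqrt(1.5^2 / length(markers) + 1.5^2 / length(bg)) # gene-mean noise
  expect_lt(abs(diffMean - 2), 3 * se + 0.2)
  # reproducibility
  simB <- simulateExpression(40, nGenes = 600, nMarkers = 30,
                             lambda = rep(0, 40), seed = 2)
  expect_identical(sim0$expr, simB$expr)
  expect_error(simulateExpression(10, nGenes = 20, nMarkers = 20), "<")
})

test_that("extreme malignancy separates PBM scores pair by pair", {
  sim <- simulateExpression(40, nGenes = 800, nMarkers = 40, delta = 4,
                            noiseSd = 0.1,
                            lambda = rep(c(0, 1), each = 20), seed = 5)
  z <- scoreSignature(sim$expr, sim$signature, nPerm = 300, seed = 3)
  pbm <- -z
  expect_true(min(pbm[21:40]) > max(pbm[1:20]))
})

test_that("survival generator hits the censoring target and the null", {
  lam <- runif(400)
  truth <- new("SimTruth", lambda = setNames(lam, sprintf("S%04d", 1:400)),
               params = list(), seed = 1L)
  s <- simulateSurvival(truth, beta = log(1.72), censorFrac = 0.3, seed = 4)
  expect_true(abs(mean(s$os_event == 0) - 0.3) < 0.08)
  s0 <- simulateSurvival(truth, censorFrac = 0, seed = 4)
  expect_true(all(s0$os_event == 1))
  # beta = 0: mean estimated log-HR of a median split is near 0
  set.seed(71)
  est <- replicate(30, {
    tr <- new("SimTruth",
              lambda = setNames(runif(300), sprintf("S%04d", 1:300)),
              params = list(), seed = 1L)
    sv <- simulateSurvival(tr, beta = 0, censorFrac = 0.3,
                           seed = sample.int(1e6, 1))
    grp <- medianSplit(simLambda(tr))
    coxFit(sv$os_time, sv$os_event,
           data.frame(g = as.integer(grp == "high")))$coefficients$coef
  })
  expect_lt(abs(mean(est)), 0.08)
  expect_error(simulateSurvival(truth, censorFrac = 1), "censorFrac")
})

test_that("stage assignment follows the thresholds on lambda", {
  lam <- c(a = 0, b = 0.2, c = 0.4, d = 0.6, e = 1)
  truth <- new("SimTruth", lambda = lam, params = list(), seed = 1L)
  st <- simulateStages(truth)
  expect_equal(as.character(st),
               c("Healthy", "MGUS", "SMM", "NDMM", "RRMM"))
  expect_true(is.ordered(st))
  expect_error(simulateStages(truth, thresholds = c(0.3, 0.2, 0.5, 0.7)),
               "increasing")
})

test_that("mutation generator couples carriers and TMB to lambda", {
  lam <- setNames(rep(c(0.05, 0.95), each = 200), sprintf("S%04d", 1:400))
  truth <- new("SimTruth", lambda = lam, params = list(), seed = 1L)
  drv <- data.frame(gene = "TP53", intercept = -2, slope = 4)
  mt <- simulateMutations(truth, drv, tmbSlope = 1, seed = 6)
  expect_identical(mt, simulateMutations(truth, drv, tmbSlope = 1, seed = 6))
  carr <- unique(mt$sample_id[mt$gene == "TP53"])
  rateHigh <- mean(names(lam)[lam > 0.5] %in% carr)
  rateLow <- mean(names(lam)[lam < 0.5] %in% carr)
  expect_gt(rateHigh, rateLow + 0.2)
  tmb <- computeTMB(mt, names(lam))
  expect_gt(mean(tmb[lam > 0.5]), mean(tmb[lam < 0.5]))
  # zero slope: carrier rate independent of lambda
  mt0 <- simulateMutations(truth,
                           data.frame(gene = "G", intercept = -1, slope = 0),
                           seed = 7)
  carr0 <- unique(mt0$sample_id[mt0$gene == "G"])
  tab <- table(lam > 0.5, names(lam) %in% carr0)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})

test_that("WBM generator ties fractions to coupling and archetypes to markers", {
  sigs <- simulateSignatures(6, 20, 600)
  lam <- setNames(runif(120), sprintf("S%04d", 1:120))
  truth <- new("SimTruth", lambda = lam, params = list(), seed = 1L)
  coup <- setNames(rep(0, 6), names(sigs))
  coup["NKresting"] <- -2; coup["CD8T"] <- 2
  w <- simulateWBM(truth, sigs, coupling = coup, nGenes = 600, seed = 9)
  expect_lt(cor(lam, w$fractions[, "NKresting"], method = "spearman"), 0)
  expect_gt(cor(lam, w$fractions[, "CD8T"], method = "spearman"), 0)
  # one cell type at fraction ~1 with no noise tops its own signature score
  # at lambda 1 the +25 coupling concentrates all mass on the first type
  one <- new("SimTruth", lambda = c(X0001 = 1, X0002 = 1),
             params = list(), seed = 1L)
  w1 <- simulateWBM(one, sigs,
                    coupling = setNames(c(25, rep(-25, 5)), names(sigs)),
                    concentration = 1e4, noiseSd = 0, nGenes = 600,
                    seed = 10)
  expect_gt(w1$fractions[1, 1], 0.99)
  tm <- suppressMessages(estimateTIME(w1$wbm, sigs, nPerm = 150, seed = 2))
  expect_equal(unname(which.max(tm[1, ])), 1L)
})

test_that("progression cohort matches its binormal design", {
  d <- simulateProgressionCohort(seed = 3)
  expect_equal(nrow(d), 358L)
  expect_equal(sum(d$progressed), 39L)
  expect_identical(d, simulateProgressionCohort(seed = 3))
  # null delta gives AUC near 0.5 at large n
  d0 <- simulateProgressionCohort(n = 2000, nProgressors = 600, delta = 0,
                                  seed = 4)
  expect_lt(abs(rocAuc(d0$score, d0$progressed)$auc - 0.5), 0.05)
})

test_that("stage-gap discrimination grows with latent separation", {
  set.seed(80)
  sim <- simulateCohort(n = 400, seed = 13)
  z <- scoreSignature(sim$expr, sim$signature, nPerm = 300, seed = 2)
  auc <- stageDiscrimination(-z, sim$clinical$stage_label)
  # later-vs-earlier pairs with wider lambda gaps discriminate at least as well
  expect_gt(auc["Healthy", "RRMM"], auc["Healthy", "MGUS"] - 0.02)
  expect_gt(auc["Healthy", "RRMM"], 0.95)
  expect_gt(auc["MGUS", "NDMM"], auc["MGUS", "SMM"] - 0.02)
})
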