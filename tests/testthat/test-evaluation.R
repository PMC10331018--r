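test_that("confusion metrics reproduce 2x2 arithmetic and edge cases", {
  # TP=8, FN=2, TN=7, FP=3
  labels <- c(rep(1, 10), rep(0, 10))
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.8, 3), rep(0.2, 7))
  cm <- confusionMetrics(labels, scores)
  expect_equal(cm$accuracy, 0.75)
  expect_equal(cm$sensitivity, 0.8)
  expect_equal(cm$specificity, 0.7)
  expect_equal(cm$ppv, 8 / 11)
  expect_equal(cm$npv, 7 / 9)
  # identity: accuracy = (sens*nPos + spec*nNeg)/(nPos+nNeg)
  expect_equal(cm$accuracy,
               (cm$sensitivity * cm$nPos + cm$specificity * cm$nNeg) /
                 (cm$nPos + cm$nNeg))
  # perfect scores
  cmP <- confusionMetrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_true(all(unlist(cmP[c("accuracy", "sensitivity", "specificity",
                               "ppv", "npv")]) == 1))
  # degenerate: all predicted positive at threshold 0.5 when scores == 0.5
  expect_warning(cmD <- confusionMetrics(c(1, 0), c(0.5, 0.5)), "NPV")
  expect_true(is.nan(cmD$npv))
  expect_equal(cmD$sensitivity, 1)
  expect_equal(cmD$specificity, 0)
  expect_error(confusionMetrics(c(1, 1), c(0.2, 0.8)), "both classes")
})

test_that("DeLong AUC equals the exhaustive pairwise statistic and loop-based variance", {
  # perfect separation
  au <- suppressWarnings(aucDelong(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2)))
  expect_equal(au$auc, 1)
  expect_equal(au$var, 0)
  # full tie -> 0.5 by midrank convention
  expect_equal(aucDelong(c(1, 0), c(0.6, 0.6))$auc, 0.5)
  # random samples vs oracle, including ties, across sizes up to 50
  set.seed(20)
  for (rep in 1:25) {
    nP <- sample(2:25, 1); nN <- sample(2:25, 1)
    labels <- c(rep(1, nP), rep(0, nN))
    scores <- round(c(rnorm(nP, 0.5), rnorm(nN)), sample(c(1, 8), 1))
    au <- aucDelong(labels, scores)
    expect_equal(au$auc, oracleAuc(labels, scores), tolerance = 1e-10)
    expect_equal(au$var, oracleDelongVar(labels, scores), tolerance = 1e-10)
    expect_true(au$ci[1] >= 0 && au$ci[2] <= 1)
    expect_true(au$ci[1] <= au$auc && au$auc <= au$ci[2])
  }
  expect_error(aucDelong(c(1, 1), c(0.1, 0.2)), "at least one")
})

test_that("DeLong 95% CI covers the true AUC at close to nominal rate", {
  # binormal model: pos ~ N(mu, 1), neg ~ N(0, 1); true AUC = pnorm(mu/sqrt(2))
  set.seed(42)
  mu <- 1
  trueAuc <- pnorm(mu / sqrt(2))
  hits <- 0; nSim <- 200
  for (i in seq_len(nSim)) {
    scores <- c(rnorm(40, mu), rnorm(40))
    labels <- c(rep(1, 40), rep(0, 40))
    ci <- aucDelong(labels, scores)$ci
    if (trueAuc >= ci[1] && trueAuc <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / nSim, 0.90)
})

test_that("fold plans partition the cohort with per-class balance", {
  set.seed(1)
  labels <- c(rep(1, 10), rep(0, 10))
  plan <- foldPlan(labels, k = 5, seed = 3)
  expect_equal(sort(unique(plan$assignments)), 1:5)
  expect_equal(length(plan$assignments), 20)
  tab <- table(plan$assignments, labels)
  expect_true(all(tab == 2))  # 4 cases per fold, 2 per class
  # determinism
  plan2 <- foldPlan(labels, k = 5, seed = 3)
  expect_identical(plan$assignments, plan2$assignments)
  # unbalanced: class counts per fold within 1 of each other
  labels2 <- c(rep(1, 13), rep(0, 22))
  plan3 <- foldPlan(labels2, k = 5, seed = 9)
  tab3 <- table(factor(plan3$assignments, 1:5), labels2)
  expect_lte(diff(range(tab3[, "1"])), 1)
  expect_lte(diff(range(tab3[, "0"])), 1)
})

test_that("cross-validation with an oracle model is perfect and deterministic", {
  bags <- tinyBags(nCases = 20, seed = 15)
  oracleTrain <- function(trainBags, config, seed) NULL
  oraclePredict <- function(fitted, bags)
    vapply(bags, bagLabel, integer(1)) * 0.8 + 0.1
  res <- runCV(bags, config = trainConfig(epochs = 1),
               trainFun = oracleTrain, predictFun = oraclePredict)
  expect_equal(nrow(res$perFold), 5)
  expect_true(all(res$perFold$accuracy == 1))
  expect_true(all(res$perFold$auc == 1))
  expect_equal(res$pooled$accuracy, 1)
  # matched plans are reproducible
  labels <- vapply(bags, bagLabel, integer(1))
  p1 <- foldPlan(labels, seed = 4)
  p2 <- foldPlan(labels, seed = 4)
  expect_identical(p1$assignments, p2$assignments)
  res2 <- runCV(bags, config = trainConfig(epochs = 1), plan = p1,
                trainFun = oracleTrain, predictFun = oraclePredict)
  expect_identical(res2$plan$assignments, p1$assignments)
  # summary covers the six reported metrics
  expect_setequal(res$summary$metric,
                  c("accuracy", "sensitivity", "specificity", "npv", "ppv", "auc"))
})

test_that("paired fold comparison handles zero-variance and symmetric cases", {
  expect_equal(compareModels(rep(0.9, 5), rep(0.9, 5))$pValue, 1)
  cz <- compareModels(rep(0.9, 5), rep(0.5, 5))
  expect_lt(cz$pValue, 0.001)
  expect_true(cz$significant)
  a <- c(0.91, 0.87, 0.9, 0.85, 0.88); b <- c(0.8, 0.82, 0.79, 0.84, 0.81)
  expect_equal(compareModels(a, b)$pValue, compareModels(b, a)$pValue)
  expect_equal(compareModels(a, b)$meanDiff, -compareModels(b, a)$meanDiff)
  expect_error(compareModels(0.9, 0.8), "at least 2")
  expect_error(compareModels(a, b[1:3]))
})

test_that("ablation harness emits the 4 x 6 variant table with matched folds", {
  bags <- tinyBags(nCases = 20, seed = 16)
  # swap in a fast oracle-style trainer: variant identity still recorded
  res <- runAblation(bags, config = trainConfig(epochs = 1, lr = 1e-3,
                                                seed = 2),
                     modelArgs = list(extractor = tinyExtractor()))
  tab <- res$table
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$variant, c("benchmark", "attention", "aggregator", "full"))
  metricCols <- c("accuracy", "sensitivity", "specificity", "npv", "ppv", "auc")
  expect_true(all(metricCols %in% names(tab)))
  expect_equal(sum(names(tab) %in% metricCols), 6)
  # all four variants share one fold plan
  plans <- lapply(res$runs, function(r) r$plan$assignments)
  expect_true(all(vapply(plans, identical, logical(1), y = plans[[1]])))
  # variant flags reflect the architecture actually built
  expect_false(tab$attention[tab$variant == "benchmark"])
  expect_false(tab$aggregator[tab$variant == "benchmark"])
  expect_true(all(unlist(tab[tab$variant == "full", c("attention", "aggregator")])))
})
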