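#' Confusion-matrix metrics at a fixed threshold
#'
#' Accuracy, sensitivity, specificity, PPV and NPV from the 2x2 table of
#' \code{scores >= threshold} against binary labels. Degenerate cells
#' (e.g. no positive predictions) yield \code{NaN} for the affected
#' predictive value, with a warning.
#'
#' @param labels binary vector (0/1).
#' @param scores numeric scores or probabilities.
#' @param threshold decision threshold on the score (default 0.5).
#' @return List with accuracy, sensitivity, specificity, ppv, npv, tp, fp,
#'   tn, fn, nPos, nNeg, threshold.
#' @export
confusionMetrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores),
            all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2)
    stop("labels must contain both classes")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0) at this threshold")
      return(NaN)
    }
    num / den
  }
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = safe(tp, tp + fp, "PPV"),
       npv = safe(tn, tn + fn, "NPV"),
       tp = tp, fp = fp, tn = tn, fn = fn,
       nPos = sum(labels == 1), nNeg = sum(labels == 0),
       threshold = threshold)
}

#' AUC with DeLong variance and 95% confidence interval
#'
#' Point estimate via the Mann-Whitney midrank statistic, variance via the
#' DeLong structural components, CI as \code{auc +/- 1.96 sd} clipped to
#' [0, 1].
#'
#' @param labels binary vector with at least one of each class.
#' @param scores numeric scores.
#' @return List: auc, var, ci (length-2), nPos, nNeg.
#' @export
aucDelong <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (sum(labels == 1) < 1 || sum(labels == 0) < 1)
    stop("need at least one positive and one negative")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  # pROC warns that var = 0 at AUC == 1 "can be misleading"; a zero
  # variance (degenerate CI) is exactly this function's documented contract
  v <- suppressWarnings(as.numeric(pROC::var(r, method = "delong")))
  half <- stats::qnorm(0.975) * sqrt(v)
  ci <- c(max(0, auc - half), min(1, auc + half))
  list(auc = auc, var = v, ci = ci,
       nPos = sum(labels == 1), nNeg = sum(labels == 0))
}

#' Stratified k-fold plan
#'
#' Partitions a labelled cohort into k folds, stratified by class: each
#' fold's size and class ratio are within one case of the global ones.
#' Deterministic given \code{seed}.
#'
#' @param labels binary label per case.
#' @param k number of folds (default 5, i.e. a 4:1 train/test split per fold).
#' @param seed integer seed.
#' @param caseIds optional identifiers used to name the assignment.
#' @return List of class \code{foldPlan}: \code{k}, \code{assignments}
#'   (fold index per case, named by caseIds), \code{seed}.
#' @export
foldPlan <- function(labels, k = 5L, seed = 1L, caseIds = NULL) {
  stopifnot(k >= 2, length(labels) >= k)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  assignments <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    assignments[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (!is.null(caseIds)) names(assignments) <- caseIds
  structure(list(k = as.integer(k), assignments = assignments,
                 seed = as.integer(seed)), class = "foldPlan")
}

.metricsRow <- function(labels, scores, threshold = 0.5) {
  cm <- suppressWarnings(confusionMetrics(labels, scores, threshold))
  au <- aucDelong(labels, scores)
  data.frame(accuracy = cm$accuracy, sensitivity = cm$sensitivity,
             specificity = cm$specificity, npv = cm$npv, ppv = cm$ppv,
             auc = au$auc, aucLo = au$ci[1], aucHi = au$ci[2])
}

#' Stratified cross-validated evaluation
#'
#' For each fold: train on the other k-1 folds, score the held-out fold.
#' Reports per-fold metrics, their mean and sd, and metrics pooled over the
#' concatenated held-out scores of all folds.
#'
#' The default \code{trainFun}/\code{predictFun} wrap
#' \code{\link{trainModel}} / \code{\link{predictCases}} on a fresh
#' \code{\link{milModel}} per fold (seeded per fold from
#' \code{trainConfig$seed}); both can be replaced, e.g. by an oracle, for
#' harness testing. When \code{valFraction > 0} the default trainer carves
#' a stratified validation subset out of each fold's training bags and
#' returns the best-validation-AUC checkpoint rather than the final epoch.
#'
#' @param bags list of \linkS4class{PreparedBag} (the full cohort).
#' @param config a \code{\link{trainConfig}}.
#' @param plan a \code{\link{foldPlan}} over the same cohort.
#' @param modelArgs arguments passed to \code{\link{milModel}} per fold.
#' @param trainFun function(trainBags, config, seed) -> fitted object.
#' @param predictFun function(fitted, bags) -> numeric probabilities.
#' @param threshold decision threshold for the confusion metrics.
#' @param valFraction fraction of each fold's training bags held out for
#'   best-checkpoint selection by the default trainer (default 0.2; set 0
#'   to keep the final epoch).
#' @return List of class \code{cvResult}: \code{perFold} (data.frame, one
#'   row per fold), \code{summary} (mean and sd across folds),
#'   \code{pooled} (one row), \code{scores} (data.frame caseId, label,
#'   fold, prob), \code{plan}.
#' @export
runCV <- function(bags, config = trainConfig(), plan = NULL,
                  modelArgs = list(), trainFun = NULL, predictFun = NULL,
                  threshold = 0.5, valFraction = 0.2) {
  labels <- vapply(bags, bagLabel, integer(1))
  if (length(unique(labels)) < 2) stop("cohort must contain both classes")
  if (is.null(plan))
    plan <- foldPlan(labels, seed = config$seed,
                     caseIds = vapply(bags, caseId, character(1)))
  stopifnot(inherits(plan, "foldPlan"),
            length(plan$assignments) == length(bags))
  if (is.null(trainFun)) {
    trainFun <- function(trainBags, config, seed) {
      model <- do.call(milModel, c(modelArgs, list(seed = seed)))
      cfgF <- config; cfgF$seed <- as.integer(seed)
      valBags <- NULL
      if (valFraction > 0) {
        labs <- vapply(trainBags, bagLabel, integer(1))
        vplan <- foldPlan(labs, k = max(2L, round(1 / valFraction)),
                          seed = seed)
        valIdx <- which(vplan$assignments == 1L)
        if (length(unique(labs[-valIdx])) == 2 &&
            length(unique(labs[valIdx])) == 2) {
          valBags <- trainBags[valIdx]
          trainBags <- trainBags[-valIdx]
        }
      }
      trainModel(model, trainBags, cfgF, valBags = valBags)$model
    }
  }
  if (is.null(predictFun)) {
    predictFun <- function(fitted, bags) predictCases(fitted, bags)$prob
  }
  folds <- sort(unique(plan$assignments))
  rows <- list(); scoreRows <- list()
  for (f in folds) {
    testIdx <- which(plan$assignments == f)
    trainIdx <- setdiff(seq_along(bags), testIdx)
    if (length(unique(labels[testIdx])) < 2)
      stop("fold ", f, " has a single-class test set; use a stratified plan")
    fitted <- trainFun(bags[trainIdx], config, config$seed + f)
    probs <- predictFun(fitted, bags[testIdx])
    rows[[f]] <- cbind(fold = f, .metricsRow(labels[testIdx], probs, threshold))
    scoreRows[[f]] <- data.frame(
      caseId = vapply(bags[testIdx], caseId, character(1)),
      label = labels[testIdx], fold = f, prob = probs,
      stringsAsFactors = FALSE)
  }
  perFold <- do.call(rbind, rows)
  scores <- do.call(rbind, scoreRows)
  metricCols <- c("accuracy", "sensitivity", "specificity", "npv", "ppv", "auc")
  summ <- data.frame(metric = metricCols,
                     mean = vapply(metricCols, function(m) mean(perFold[[m]]), numeric(1)),
                     sd = vapply(metricCols, function(m) stats::sd(perFold[[m]]), numeric(1)),
                     row.names = NULL)
  pooled <- .metricsRow(scores$label, scores$prob, threshold)
  structure(list(perFold = perFold, summary = summ, pooled = pooled,
                 scores = scores, plan = plan),
            class = "cvResult")
}

#' Paired comparison of two models across folds
#'
#' Two-sided paired t-test on matched per-fold metric values (folds are
#' shared between the models). When every within-pair difference is zero
#' the p-value is 1; when the differences are constant and nonzero the t
#' statistic is unbounded and the p-value is reported as 0.
#'
#' @param metricsA,metricsB numeric per-fold metric vectors of equal length
#'   (>= 2) on matched folds.
#' @return List: pValue, meanDiff, significant (at 0.05).
#' @export
compareModels <- function(metricsA, metricsB) {
  stopifnot(length(metricsA) == length(metricsB))
  if (length(metricsA) < 2) stop("need at least 2 folds")
  d <- metricsA - metricsB
  if (stats::sd(d) == 0) {
    p <- if (mean(d) == 0) 1 else 0
  } else {
    p <- stats::t.test(metricsA, metricsB, paired = TRUE)$p.value
  }
  list(pValue = p, meanDiff = mean(d), significant = p < 0.05)
}

#' Ablation harness: benchmark, +attention, +aggregator, both
#'
#' Cross-validates four architecture variants on the same fold plan:
#' the mean-pool benchmark (no attention, no dual-stream aggregator), each
#' module alone, and the full model. Emits one row per variant with the six
#' fold-averaged metrics.
#'
#' @param bags list of \linkS4class{PreparedBag}.
#' @param config a \code{\link{trainConfig}}.
#' @param plan a \code{\link{foldPlan}}; defaults to a stratified plan
#'   seeded from \code{config$seed}.
#' @param modelArgs shared extra arguments for \code{\link{milModel}}
#'   (e.g. the extractor config).
#' @param metric "mean" (fold-averaged, default) or "pooled".
#' @return List of class \code{ablationResult}: \code{table} (4 rows x 6
#'   metric columns plus variant flags), \code{runs} (the four
#'   \code{cvResult} objects).
#' @export
runAblation <- function(bags, config = trainConfig(), plan = NULL,
                        modelArgs = list(), metric = c("mean", "pooled")) {
  metric <- match.arg(metric)
  labels <- vapply(bags, bagLabel, integer(1))
  if (is.null(plan))
    plan <- foldPlan(labels, seed = config$seed,
                     caseIds = vapply(bags, caseId, character(1)))
  variants <- list(
    benchmark = list(useAttention = FALSE, useAggregator = FALSE),
    attention = list(useAttention = TRUE, useAggregator = FALSE),
    aggregator = list(useAttention = FALSE, useAggregator = TRUE),
    full = list(useAttention = TRUE, useAggregator = TRUE))
  runs <- lapply(variants, function(v) {
    runCV(bags, config = config, plan = plan,
          modelArgs = utils::modifyList(modelArgs, v))
  })
  metricCols <- c("accuracy", "sensitivity", "specificity", "npv", "ppv", "auc")
  tab <- do.call(rbind, lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    vals <- if (metric == "mean") {
      stats::setNames(r$summary$mean, r$summary$metric)[metricCols]
    } else unlist(r$pooled[metricCols])
    data.frame(variant = nm,
               attention = variants[[nm]]$useAttention,
               aggregator = variants[[nm]]$useAggregator,
               as.list(vals), stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, runs = runs, metric = metric),
            class = "ablationResult")
}
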