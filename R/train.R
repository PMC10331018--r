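#' Training configuration
#'
#' Optimization protocol: binary cross-entropy on the sigmoid of the bag
#' logit, Adam, one bag per optimizer step (variable slice counts forbid
#' naive batching). \code{decay} is Adam L2 weight decay; an optional
#' exponential learning-rate decay mode is available via \code{lrDecay}.
#'
#' @param lr initial learning rate (default 1e-4).
#' @param decay Adam L2 weight-decay coefficient (default 5e-3).
#' @param epochs training epochs (default 100).
#' @param batchSize bags per optimizer step; must be 1.
#' @param augment logical; re-sample bag-level flip augmentation each epoch.
#' @param augmentProb flip probability (default 0.5).
#' @param lrDecay optional multiplicative per-epoch learning-rate factor
#'   (1 = constant, the default).
#' @param seed seed controlling shuffling, augmentation and any other
#'   training randomness.
#' @return A validated list of class \code{trainConfig}.
#' @export
trainConfig <- function(lr = 1e-4, decay = 5e-3, epochs = 100L,
                        batchSize = 1L, augment = TRUE, augmentProb = 0.5,
                        lrDecay = 1, seed = 1L) {
  stopifnot(lr > 0, decay >= 0, epochs >= 1, lrDecay > 0, lrDecay <= 1)
  if (batchSize != 1L) stop("batchSize must be 1 (one bag per step)")
  structure(list(lr = lr, decay = decay, epochs = as.integer(epochs),
                 batchSize = 1L, augment = isTRUE(augment),
                 augmentProb = augmentProb, lrDecay = lrDecay,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamStep <- function(params, grads, opt, lr, decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]] + decay * params[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

#' Train the model on a set of prepared bags
#'
#' Runs the Adam loop with one bag per step. If \code{valBags} is supplied,
#' validation AUC is computed each epoch and the best-validation parameters
#' are returned (with the final-epoch parameters available in
#' \code{$finalModel}); otherwise the final-epoch model is returned.
#' Deterministic given \code{config$seed} on one device.
#'
#' @param model a freshly constructed \linkS4class{MILModel}.
#' @param trainBags list of \linkS4class{PreparedBag}; must contain both
#'   classes.
#' @param config a \code{\link{trainConfig}}.
#' @param valBags optional validation bags for model selection.
#' @param verbose print one line per epoch.
#' @return List: \code{model} (selected \linkS4class{MILModel}),
#'   \code{finalModel}, \code{lossHistory} (per-epoch mean training loss),
#'   \code{valAuc} (per-epoch, if validation used), \code{bestEpoch}.
#' @export
trainModel <- function(model, trainBags, config = trainConfig(),
                       valBags = NULL, verbose = FALSE) {
  labs <- vapply(trainBags, bagLabel, integer(1))
  if (length(unique(labs)) < 2) stop("training set must contain both classes")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- model@params
  state <- model@state
  opt <- .adamInit(params)
  augCfg <- preprocessConfig(augment = TRUE, augmentProb = config$augmentProb)
  lossHistory <- numeric(config$epochs)
  valAuc <- if (!is.null(valBags)) numeric(config$epochs) else NULL
  bestAuc <- -Inf; bestEpoch <- NA_integer_
  bestParams <- params; bestState <- state
  lr <- config$lr
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(trainBags))
    losses <- numeric(length(ord))
    for (j in seq_along(ord)) {
      bag <- trainBags[[ord[j]]]
      if (config$augment) bag <- augmentBag(bag, augCfg)
      work <- new("MILModel", config = model@config, params = params,
                  state = state)
      fwd <- .forwardBag(work, bag, train = TRUE)
      state <- fwd$state
      bw <- .backwardCase(work, fwd, bagLabel(bag))
      if (!is.finite(bw$loss))
        stop("non-finite training loss at epoch ", epoch,
             " (case ", caseId(bag), "); try a smaller learning rate")
      st <- .adamStep(params, bw$grads, opt, lr, config$decay)
      params <- st$params; opt <- st$opt
      losses[j] <- bw$loss
    }
    lossHistory[epoch] <- mean(losses)
    if (!is.null(valBags)) {
      cur <- new("MILModel", config = model@config, params = params, state = state)
      pv <- predictCases(cur, valBags)
      auc <- tryCatch(aucDelong(pv$label, pv$prob)$auc, error = function(e) NA_real_)
      valAuc[epoch] <- auc
      if (is.finite(auc) && auc > bestAuc) {
        bestAuc <- auc; bestEpoch <- epoch
        bestParams <- params; bestState <- state
      }
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f%s", epoch, lossHistory[epoch],
                      if (!is.null(valBags)) sprintf("  valAUC %.3f", valAuc[epoch]) else ""))
    }
    lr <- lr * config$lrDecay
  }
  finalModel <- new("MILModel", config = model@config, params = params, state = state)
  selected <- if (!is.null(valBags) && is.finite(bestAuc)) {
    new("MILModel", config = model@config, params = bestParams, state = bestState)
  } else finalModel
  list(model = selected, finalModel = finalModel, lossHistory = lossHistory,
       valAuc = valAuc, bestEpoch = bestEpoch)
}
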