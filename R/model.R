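#' Feature-extractor configuration
#'
#' A shallow CNN applied independently (shared weights) to every slice of
#' every modality. Each block is conv 3x3 (pad 1) -> ReLU -> batch norm ->
#' max-pool 2x2; a final fully connected layer maps the flattened feature
#' map to a \code{embedDim}-dimensional instance embedding. At the default
#' depth 5 with a 64x64 input the pre-flatten map is 256 x 2 x 2 (4096
#' flattened). Once the spatial side reaches 1, remaining blocks skip their
#' pool (this is what makes depth 7 legal at 64x64).
#'
#' @param nConvLayers number of conv blocks, in [3, 7] (default 5).
#' @param channels per-block channel counts; default doubles from 16,
#'   capped at 256 (16, 32, 64, 128, 256 at depth 5).
#' @param embedDim instance embedding width (default 128).
#' @param inputSize slice side in pixels (default 64).
#' @return A validated list of class \code{extractorConfig}.
#' @export
extractorConfig <- function(nConvLayers = 5L, channels = NULL,
                            embedDim = 128L, inputSize = 64L) {
  nConvLayers <- as.integer(nConvLayers)
  if (nConvLayers < 3L || nConvLayers > 7L)
    stop("nConvLayers must be between 3 and 7")
  if (is.null(channels)) channels <- pmin(16L * 2L^(seq_len(nConvLayers) - 1L), 256L)
  if (length(channels) != nConvLayers)
    stop("channels must have one entry per conv layer")
  nPools <- min(nConvLayers, floor(log2(inputSize)))
  if (inputSize %/% 2L^nPools < 1L)
    stop("input collapses below 1 pixel for this depth")
  structure(list(nConvLayers = nConvLayers, channels = as.integer(channels),
                 embedDim = as.integer(embedDim),
                 inputSize = as.integer(inputSize)),
            class = "extractorConfig")
}

# Spatial side after each block (pool skipped once the side reaches 1).
.spatialSides <- function(config) {
  side <- config$inputSize
  sides <- integer(config$nConvLayers)
  for (l in seq_len(config$nConvLayers)) {
    if (side >= 2L) side <- side %/% 2L
    sides[l] <- side
  }
  sides
}

#' Modality-attention dual-stream MIL model
#'
#' Holds the architecture description, the trainable parameters (flat named
#' list of matrices/vectors) and the non-trainable state (batch-norm running
#' moments). Construct with \code{\link{milModel}}; train with
#' \code{\link{trainModel}}; run with \code{\link{forwardCase}} or
#' \code{\link{predictCases}}.
#'
#' @slot config list: extractor config, module switches, gate choice.
#' @slot params named list of trainable arrays.
#' @slot state named list of batch-norm running moments.
#' @export
setClass("MILModel", representation(
  config = "list", params = "list", state = "list"
))

setMethod("show", "MILModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf("MILModel: depth-%d extractor (%s), embed %d, input %dx%d\n",
              cfg$extractor$nConvLayers,
              paste(cfg$extractor$channels, collapse = ","),
              cfg$extractor$embedDim, cfg$extractor$inputSize,
              cfg$extractor$inputSize))
  cat(sprintf("  modality attention: %s (gate %s); dual-stream aggregator: %s\n",
              if (cfg$useAttention) "on" else "off", cfg$gate,
              if (cfg$useAggregator) "on" else "off"))
  cat(sprintf("  trainable parameters: %d\n", np))
})

#' Construct a modality-attention dual-stream MIL model
#'
#' The full network is: shared slice feature extractor applied to each of
#' the five modality stacks, squeeze-excite modality attention producing a
#' weight per modality, fusion of the five per-modality embedding matrices
#' by the attention-weighted sum, then a dual-stream aggregator: stream one
#' scores every instance and max-pools (critical instance, score c_m);
#' stream two softmax-weights instances by query similarity to the critical
#' instance, forms the bag embedding, and scores it (c_b). The bag logit is
#' (c_m + c_b) / 2.
#'
#' Ablation switches: \code{useAttention = FALSE} fixes the modality weights
#' at 1/5 each and allocates no excitation parameters;
#' \code{useAggregator = FALSE} scores the bag as the mean of the instance
#' scores (mean-pool baseline) and allocates no query/value/bag parameters.
#'
#' @param extractor an \code{\link{extractorConfig}}.
#' @param nModalities number of input modalities (5).
#' @param useAttention enable the modality attention module.
#' @param useAggregator enable the dual-stream aggregator.
#' @param attentionHidden hidden width of the excitation MLP (default equal
#'   to \code{nModalities}, i.e. no reduction).
#' @param gate output nonlinearity of the excitation MLP: "sigmoid"
#'   (default), "softmax", or "none".
#' @param seed seed for the fan-in Gaussian weight initialization.
#' @return A \linkS4class{MILModel}.
#' @export
milModel <- function(extractor = extractorConfig(), nModalities = 5L,
                     useAttention = TRUE, useAggregator = TRUE,
                     attentionHidden = nModalities,
                     gate = c("sigmoid", "softmax", "none"), seed = 1L) {
  gate <- match.arg(gate)
  stopifnot(inherits(extractor, "extractorConfig"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  he <- function(nr, nc, fanIn) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fanIn)), nr, nc)
  L <- extractor$nConvLayers
  ch <- c(1L, extractor$channels)
  sides <- .spatialSides(extractor)
  params <- list(); state <- list()
  for (l in seq_len(L)) {
    params[[sprintf("conv%d.W", l)]] <- he(9L * ch[l], ch[l + 1L], 9L * ch[l])
    params[[sprintf("conv%d.b", l)]] <- numeric(ch[l + 1L])
    params[[sprintf("bn%d.gamma", l)]] <- rep(1, ch[l + 1L])
    params[[sprintf("bn%d.beta", l)]] <- numeric(ch[l + 1L])
    state[[sprintf("bn%d.runMean", l)]] <- numeric(ch[l + 1L])
    state[[sprintf("bn%d.runVar", l)]] <- rep(1, ch[l + 1L])
  }
  flatDim <- sides[L]^2 * ch[L + 1L]
  D <- extractor$embedDim
  params[["fc.W"]] <- he(flatDim, D, flatDim)
  params[["fc.b"]] <- numeric(D)
  if (useAttention) {
    params[["att.W1"]] <- he(nModalities, attentionHidden, nModalities)
    params[["att.b1"]] <- numeric(attentionHidden)
    params[["att.W2"]] <- he(attentionHidden, nModalities, attentionHidden)
    params[["att.b2"]] <- numeric(nModalities)
  }
  params[["w0"]] <- as.numeric(he(D, 1L, D))
  if (useAggregator) {
    params[["Wq"]] <- he(D, D, D)
    params[["Wv"]] <- he(D, D, D)
    params[["wb"]] <- as.numeric(he(D, 1L, D))
  }
  new("MILModel",
      config = list(extractor = extractor, nModalities = as.integer(nModalities),
                    useAttention = isTRUE(useAttention),
                    useAggregator = isTRUE(useAggregator),
                    attentionHidden = as.integer(attentionHidden),
                    gate = gate, seed = as.integer(seed)),
      params = params, state = state)
}

# Extractor forward over a batch of N slices given as (t*t*N) x 1 matrix.
# Returns embeddings E (N x embedDim), layer caches for backprop (train
# mode), and updated batch-norm state.
.extractorForward <- function(X, params, state, config, N, train = FALSE) {
  L <- config$nConvLayers
  side <- config$inputSize
  caches <- if (train) vector("list", L) else NULL
  for (l in seq_len(L)) {
    cf <- .convForward(X, params[[sprintf("conv%d.W", l)]],
                       params[[sprintf("conv%d.b", l)]],
                       side, side, N, keepCols = train)
    pre <- cf$Y
    A <- .cppRelu(pre)
    bn <- .bnForward(A, params[[sprintf("bn%d.gamma", l)]],
                     params[[sprintf("bn%d.beta", l)]],
                     state[[sprintf("bn%d.runMean", l)]],
                     state[[sprintf("bn%d.runVar", l)]], train)
    state[[sprintf("bn%d.runMean", l)]] <- bn$runMean
    state[[sprintf("bn%d.runVar", l)]] <- bn$runVar
    A2 <- bn$Y
    if (side >= 2L) {
      pf <- .poolForward(A2, side, side, N, keepArg = train)
      out <- pf$Y
      poolCache <- if (train) pf[c("arg", "idx", "inRows")] else NULL
      sideOut <- side %/% 2L
    } else {
      out <- A2
      poolCache <- NULL
      sideOut <- side
    }
    if (train) {
      caches[[l]] <- list(cols = cf$cols, pre = pre, bnXhat = bn$xhat,
                          bnInvstd = bn$invstd, pool = poolCache,
                          side = side)
    }
    X <- out
    side <- sideOut
  }
  hw <- side^2
  F <- .flattenSlices(X, hw, N)
  E <- F %*% params[["fc.W"]]
  E <- E + rep(params[["fc.b"]], each = N)
  list(E = E, F = F, hw = hw, caches = caches, state = state,
       preFlattenSide = side, preFlattenChannels = ncol(X))
}

# Extractor backward given dE (N x embedDim); accumulates into grads.
.extractorBackward <- function(dE, fwd, params, config, N, grads) {
  L <- config$nConvLayers
  grads[["fc.W"]] <- grads[["fc.W"]] + crossprod(fwd$F, dE)
  grads[["fc.b"]] <- grads[["fc.b"]] + colSums(dE)
  dX <- .unflattenSlices(dE %*% t(params[["fc.W"]]), fwd$hw, N)
  for (l in rev(seq_len(L))) {
    cache <- fwd$caches[[l]]
    if (!is.null(cache$pool)) dX <- .poolBackward(dX, cache$pool)
    bnb <- .bnBackward(dX, cache$bnXhat, cache$bnInvstd,
                       params[[sprintf("bn%d.gamma", l)]])
    grads[[sprintf("bn%d.gamma", l)]] <- grads[[sprintf("bn%d.gamma", l)]] + bnb$dgamma
    grads[[sprintf("bn%d.beta", l)]] <- grads[[sprintf("bn%d.beta", l)]] + bnb$dbeta
    dA <- .cppReluBwd(bnb$dX, cache$pre)
    cb <- .convBackward(dA, cache$cols, params[[sprintf("conv%d.W", l)]],
                        cache$side, cache$side, N)
    grads[[sprintf("conv%d.W", l)]] <- grads[[sprintf("conv%d.W", l)]] + cb$dW
    grads[[sprintf("conv%d.b", l)]] <- grads[[sprintf("conv%d.b", l)]] + cb$db
    dX <- cb$dX
  }
  grads
}

#' Extract per-slice embeddings for one modality stack
#'
#' Runs the shared feature extractor on a stack of slices (evaluation mode,
#' running batch-norm statistics).
#'
#' @param model a \linkS4class{MILModel}.
#' @param slices t x t x s array of z-scored slices.
#' @return s x embedDim matrix of instance embeddings.
#' @export
extractFeatures <- function(model, slices) {
  cfg <- model@config$extractor
  d <- dim(slices)
  stopifnot(length(d) == 3, d[1] == cfg$inputSize, d[2] == cfg$inputSize)
  X <- matrix(as.numeric(slices), d[1] * d[2] * d[3], 1)
  .extractorForward(X, model@params, model@state, cfg, d[3], train = FALSE)$E
}

#' Squeeze: modality-wise descriptors
#'
#' Global average pooling of each modality's instance-embedding matrix to a
#' scalar descriptor: \code{d_k} is the grand mean of \code{M[[k]]}.
#'
#' @param M list of per-modality s x embedDim matrices.
#' @return Numeric vector of descriptors, one per modality.
#' @export
squeezeDescriptor <- function(M) {
  stopifnot(length(M) >= 1, nrow(M[[1]]) >= 1)
  vapply(M, mean, numeric(1))
}

#' Excite: descriptors to modality attention weights
#'
#' Two fully connected layers with a ReLU between them, followed by the
#' configured output gate: \code{a = gate(W2' relu(W1' d + b1) + b2)}.
#'
#' @param d descriptor vector (length = number of modalities).
#' @param W1 nModalities x hidden weight matrix.
#' @param b1 hidden bias.
#' @param W2 hidden x nModalities weight matrix.
#' @param b2 output bias.
#' @param gate "sigmoid" (default), "softmax", or "none".
#' @return Attention vector \code{a}, one weight per modality.
#' @export
exciteWeights <- function(d, W1, b1 = numeric(ncol(W1)), W2,
                          b2 = numeric(ncol(W2)),
                          gate = c("sigmoid", "softmax", "none")) {
  gate <- match.arg(gate)
  if (length(d) != nrow(W1) || ncol(W1) != nrow(W2))
    stop("dimension mismatch in excitation weights")
  u <- as.numeric(d %*% W1) + b1
  r <- pmax(u, 0)
  z <- as.numeric(r %*% W2) + b2
  switch(gate,
         sigmoid = 1 / (1 + exp(-z)),
         softmax = { e <- exp(z - max(z)); e / sum(e) },
         none = z)
}

#' Reweight: fuse modalities by the attention-weighted sum
#'
#' \code{H = sum_k a_k M[[k]]}: the five per-modality embedding matrices are
#' collapsed to a single s x embedDim fused instance-embedding matrix.
#'
#' @param M list of per-modality s x embedDim matrices.
#' @param a attention vector, one weight per modality.
#' @return s x embedDim fused matrix.
#' @export
reweightModalities <- function(M, a) {
  stopifnot(length(M) == length(a))
  H <- a[1] * M[[1]]
  for (k in seq_along(M)[-1]) {
    if (!identical(dim(M[[k]]), dim(M[[1]]))) stop("modality shape mismatch")
    H <- H + a[k] * M[[k]]
  }
  H
}

#' Instance stream: score every instance and max-pool
#'
#' Stream one of the dual-stream aggregator: \code{score_i = <w0, h_i>},
#' \code{c_m = max_i score_i}; the critical instance is the argmax (lowest
#' index on ties).
#'
#' @param H s x embedDim fused instance-embedding matrix.
#' @param w0 instance-classifier weight vector (no bias).
#' @return List: \code{scores} (length s), \code{criticalIndex}, \code{cM}.
#' @export
instanceStream <- function(H, w0) {
  if (nrow(H) < 1) stop("empty bag")
  scores <- as.numeric(H %*% w0)
  m <- which.max(scores)   # lowest index on ties
  list(scores = scores, criticalIndex = m, cM = scores[m])
}

#' Bag stream: similarity-weighted bag embedding
#'
#' Stream two: queries \code{q_i = Wq' h_i} and values \code{v_i = Wv' h_i};
#' softmax similarity to the critical query,
#' \code{U_i = exp(<q_i, q_m>) / sum_k exp(<q_k, q_m>)} (computed with
#' max-subtraction); bag embedding \code{b = sum_i U_i v_i}; bag score
#' \code{c_b = <wb, b>}.
#'
#' @param H s x embedDim fused instance-embedding matrix.
#' @param criticalIndex index of the critical instance.
#' @param Wq,Wv embedDim x embedDim projection matrices (no bias).
#' @param wb bag-classifier weight vector (no bias).
#' @return List: \code{U} (probability vector over instances), \code{b}
#'   (bag embedding), \code{cB}.
#' @export
bagStream <- function(H, criticalIndex, Wq, Wv, wb) {
  s <- nrow(H)
  if (criticalIndex < 1 || criticalIndex > s) stop("critical index out of range")
  Q <- H %*% Wq
  V <- H %*% Wv
  logits <- as.numeric(Q %*% Q[criticalIndex, ])
  e <- exp(logits - max(logits))
  U <- e / sum(e)
  b <- as.numeric(crossprod(V, U))
  list(U = U, b = b, cB = sum(wb * b), Q = Q, V = V, logits = logits)
}

#' Fuse the two stream scores
#'
#' The bag logit is the average of the max-pooled instance score and the
#' bag-embedding score: \code{c = (c_m + c_b) / 2}.
#'
#' @param cM,cB stream scores.
#' @return The fused bag logit.
#' @export
fuseScores <- function(cM, cB) {
  stopifnot(is.finite(cM), is.finite(cB))
  (cM + cB) / 2
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Full forward pass over one prepared bag. In train mode every
# intermediate needed by .backwardCase is cached and batch-norm uses batch
# statistics (returned via $state).
.forwardBag <- function(model, bag, train = FALSE) {
  cfg <- model@config
  ext <- cfg$extractor
  nm <- cfg$nModalities
  s <- nSlices(bag)
  t <- ext$inputSize
  # modality-major batch of all slices: modality k occupies rows
  # ((k-1)s+1)..(ks) of the embedding matrix
  X <- matrix(0, t * t * s * nm, 1)
  for (k in seq_len(nm)) {
    X[((k - 1) * t * t * s + 1):(k * t * t * s), 1] <- as.numeric(bag@slices[[k]])
  }
  fwd <- .extractorForward(X, model@params, model@state, ext, s * nm, train = train)
  E <- fwd$E
  M <- lapply(seq_len(nm), function(k) E[((k - 1) * s + 1):(k * s), , drop = FALSE])
  if (cfg$useAttention) {
    d <- squeezeDescriptor(M)
    u <- as.numeric(d %*% model@params[["att.W1"]]) + model@params[["att.b1"]]
    r <- pmax(u, 0)
    z <- as.numeric(r %*% model@params[["att.W2"]]) + model@params[["att.b2"]]
    a <- switch(cfg$gate,
                sigmoid = .sigmoid(z),
                softmax = { e <- exp(z - max(z)); e / sum(e) },
                none = z)
  } else {
    d <- squeezeDescriptor(M)
    u <- r <- z <- NULL
    a <- rep(1 / nm, nm)
  }
  H <- reweightModalities(M, a)
  inst <- instanceStream(H, model@params[["w0"]])
  if (cfg$useAggregator) {
    bs <- bagStream(H, inst$criticalIndex, model@params[["Wq"]],
                    model@params[["Wv"]], model@params[["wb"]])
    c_final <- fuseScores(inst$cM, bs$cB)
  } else {
    bs <- list(U = rep(1 / s, s), b = NULL, cB = NA_real_)
    c_final <- mean(inst$scores)
  }
  list(cFinal = c_final, prob = .sigmoid(c_final), a = a, d = d,
       inst = inst, bags = bs, H = H, M = M, E = E,
       attCache = list(u = u, r = r, z = z),
       extractorFwd = fwd, s = s, state = fwd$state)
}

#' Run the full network on one prepared bag
#'
#' Composes the shared extractor, modality attention, and dual-stream
#' aggregation (evaluation mode) and returns the bag logit together with
#' interpretability diagnostics.
#'
#' @param model a \linkS4class{MILModel}.
#' @param bag a \linkS4class{PreparedBag}.
#' @return List: \code{cFinal} (bag logit), \code{prob} (sigmoid of it),
#'   \code{attention} (modality weights a), \code{U} (instance similarity
#'   weights), \code{criticalIndex}, \code{instanceScores}, \code{cM},
#'   \code{cB}.
#' @export
forwardCase <- function(model, bag) {
  f <- .forwardBag(model, bag, train = FALSE)
  list(cFinal = f$cFinal, prob = f$prob, attention = f$a,
       U = f$bags$U, criticalIndex = f$inst$criticalIndex,
       instanceScores = f$inst$scores, cM = f$inst$cM, cB = f$bags$cB)
}

#' Predict a set of prepared bags
#'
#' @param model a fitted \linkS4class{MILModel}.
#' @param bags list of \linkS4class{PreparedBag}.
#' @return data.frame (caseId, label, prob) with the per-case modality
#'   attention matrix as attribute \code{"attention"} (cases x modalities)
#'   and the per-case instance weights as attribute \code{"U"} (list).
#' @export
predictCases <- function(model, bags) {
  res <- lapply(bags, function(b) forwardCase(model, b))
  out <- data.frame(caseId = vapply(bags, caseId, character(1)),
                    label = vapply(bags, bagLabel, integer(1)),
                    prob = vapply(res, function(r) r$prob, numeric(1)),
                    stringsAsFactors = FALSE)
  att <- do.call(rbind, lapply(res, function(r) r$attention))
  colnames(att) <- modalityNames()[seq_len(ncol(att))]
  attr(out, "attention") <- att
  attr(out, "U") <- lapply(res, function(r) r$U)
  out
}

#' Save / load a model checkpoint
#'
#' A single archive embedding the architecture config, parameters, and
#' batch-norm state.
#'
#' @param model a \linkS4class{MILModel}.
#' @param path checkpoint file path.
#' @return \code{saveModel}: the path, invisibly. \code{loadModel}: the
#'   \linkS4class{MILModel}.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params,
               state = model@state, format = 1L), path, compress = "gzip")
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || is.null(x$config) || is.null(x$params))
    stop("not a model checkpoint: ", path)
  new("MILModel", config = x$config, params = x$params, state = x$state)
}
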