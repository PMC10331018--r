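# Hand-derived backward pass for the full bag network. Gradients flow from
# the binary cross-entropy loss on the bag logit through the score fusion,
# both aggregator streams, the attention-weighted modality fusion, the
# excitation MLP and squeeze pooling, and finally the shared extractor.
# The critical-instance index (an argmax) is treated as locally constant,
# the usual max-pooling subgradient.

.zeroGrads <- function(params) lapply(params, function(p) p * 0)

# One-bag loss and gradients. fwd is .forwardBag(..., train = TRUE).
.backwardCase <- function(model, fwd, y) {
  cfg <- model@config
  params <- model@params
  nm <- cfg$nModalities
  s <- fwd$s
  grads <- .zeroGrads(params)
  p <- fwd$prob
  dc <- p - y                      # d BCE / d logit
  H <- fwd$H
  dH <- matrix(0, s, ncol(H))
  m <- fwd$inst$criticalIndex
  if (cfg$useAggregator) {
    dcM <- dc / 2
    dcB <- dc / 2
    bs <- fwd$bags
    grads[["wb"]] <- grads[["wb"]] + dcB * bs$b
    db <- dcB * params[["wb"]]
    U <- bs$U; V <- bs$V; Q <- bs$Q
    dV <- U %o% db                      # s x D
    dU <- as.numeric(V %*% db)          # s
    dlog <- U * (dU - sum(U * dU))      # softmax backward
    qm <- Q[m, ]
    dQ <- dlog %o% qm
    dQ[m, ] <- dQ[m, ] + as.numeric(crossprod(Q, dlog))
    dH <- dH + dQ %*% t(params[["Wq"]]) + dV %*% t(params[["Wv"]])
    grads[["Wq"]] <- grads[["Wq"]] + crossprod(H, dQ)
    grads[["Wv"]] <- grads[["Wv"]] + crossprod(H, dV)
    # instance stream (max-pool: only the critical instance)
    dH[m, ] <- dH[m, ] + dcM * params[["w0"]]
    grads[["w0"]] <- grads[["w0"]] + dcM * H[m, ]
  } else {
    # mean-pool: c = mean(<w0, h_i>)
    dscore <- dc / s
    dH <- dH + matrix(dscore, s, 1) %*% matrix(params[["w0"]], 1)
    grads[["w0"]] <- grads[["w0"]] + dscore * colSums(H)
  }
  # fusion H = sum_k a_k M_k
  a <- fwd$a
  M <- fwd$M
  dM <- lapply(seq_len(nm), function(k) a[k] * dH)
  if (cfg$useAttention) {
    da <- vapply(seq_len(nm), function(k) sum(dH * M[[k]]), numeric(1))
    ac <- fwd$attCache
    dz <- switch(cfg$gate,
                 sigmoid = da * a * (1 - a),
                 softmax = a * (da - sum(a * da)),
                 none = da)
    grads[["att.W2"]] <- grads[["att.W2"]] + ac$r %o% dz
    grads[["att.b2"]] <- grads[["att.b2"]] + dz
    dr <- as.numeric(params[["att.W2"]] %*% dz)
    du <- dr * (ac$u > 0)
    grads[["att.W1"]] <- grads[["att.W1"]] + fwd$d %o% du
    grads[["att.b1"]] <- grads[["att.b1"]] + du
    dd <- as.numeric(params[["att.W1"]] %*% du)
    # squeeze: d_k is the grand mean of M_k
    for (k in seq_len(nm)) {
      dM[[k]] <- dM[[k]] + dd[k] / (s * ncol(H))
    }
  }
  dE <- do.call(rbind, dM)   # modality-major rows, matching the batch order
  grads <- .extractorBackward(dE, fwd$extractorFwd, params, cfg$extractor,
                              s * nm, grads)
  loss <- .bceLoss(fwd$cFinal, y)
  list(grads = grads, loss = loss)
}

# Numerically stable binary cross-entropy on a logit.
.bceLoss <- function(logit, y) {
  max(logit, 0) - logit * y + log1p(exp(-abs(logit)))
}
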