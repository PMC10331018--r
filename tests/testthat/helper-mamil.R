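# Shared fixture builders. All fixtures are generated in code; sizes are
# kept small so the heavy checks (training runs) dominate the suite budget.

tinyPhantom <- function(nCases = 8, seed = 7, imageSize = 32,
                        sliceRange = c(3, 6), signalAmplitude = 5,
                        witnessRate = 0.5, ...) {
  phantomConfig(nCases = nCases, imageSize = imageSize,
                sliceRange = sliceRange, signalAmplitude = signalAmplitude,
                witnessRate = witnessRate, seed = seed, ...)
}

tinyExtractor <- function(inputSize = 16, depth = 3,
                          channels = c(8, 16, 32), embedDim = 32) {
  extractorConfig(nConvLayers = depth, channels = channels,
                  embedDim = embedDim, inputSize = inputSize)
}

tinyBags <- function(nCases = 8, seed = 7, targetSize = 16, ...) {
  cases <- generateCohort(tinyPhantom(nCases = nCases, seed = seed, ...))
  prepareCohort(cases, preprocessConfig(targetSize = targetSize))
}

# A random prepared bag (no phantom structure) for pure-architecture tests.
randomBag <- function(s = 3, t = 16, seed = 1, label = 1) {
  set.seed(seed)
  sl <- lapply(seq_len(5), function(k) array(rnorm(t * t * s), c(t, t, s)))
  names(sl) <- modalityNames()
  preparedBag(sl, caseId = sprintf("rand_%d", seed), label = label)
}

# Independent brute-force oracles -----------------------------------------

oracleSqueeze <- function(M) {
  vapply(M, function(m) {
    acc <- 0
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) acc <- acc + m[i, j]
    acc / (nrow(m) * ncol(m))
  }, numeric(1))
}

oracleExcite <- function(d, W1, b1, W2, b2, gate = "sigmoid") {
  hid <- numeric(ncol(W1))
  for (h in seq_len(ncol(W1))) {
    acc <- b1[h]
    for (k in seq_along(d)) acc <- acc + d[k] * W1[k, h]
    hid[h] <- max(acc, 0)
  }
  z <- numeric(ncol(W2))
  for (k in seq_len(ncol(W2))) {
    acc <- b2[k]
    for (h in seq_along(hid)) acc <- acc + hid[h] * W2[h, k]
    z[k] <- acc
  }
  if (gate == "sigmoid") 1 / (1 + exp(-z)) else z
}

oracleBagStream <- function(H, m, Wq, Wv, wb) {
  s <- nrow(H)
  Q <- matrix(0, s, ncol(Wq)); V <- matrix(0, s, ncol(Wv))
  for (i in seq_len(s)) for (j in seq_len(ncol(Wq))) {
    Q[i, j] <- sum(H[i, ] * Wq[, j])
    V[i, j] <- sum(H[i, ] * Wv[, j])
  }
  lg <- numeric(s)
  for (i in seq_len(s)) lg[i] <- sum(Q[i, ] * Q[m, ])
  e <- exp(lg - max(lg))
  U <- e / sum(e)
  b <- numeric(ncol(Wv))
  for (j in seq_along(b)) b[j] <- sum(U * V[, j])
  list(U = U, b = b, cB = sum(wb * b))
}

# Exhaustive pairwise AUC with midrank tie handling.
oracleAuc <- function(labels, scores) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (n in sn) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(sp) * length(sn))
}

# DeLong variance from structural components, by explicit loops.
oracleDelongVar <- function(labels, scores) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  m <- length(sp); n <- length(sn)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  V10 <- vapply(sp, function(x) mean(vapply(sn, function(y) psi(x, y), numeric(1))), numeric(1))
  V01 <- vapply(sn, function(y) mean(vapply(sp, function(x) psi(x, y), numeric(1))), numeric(1))
  s10 <- if (m > 1) var(V10) else 0
  s01 <- if (n > 1) var(V01) else 0
  s10 / m + s01 / n
}
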