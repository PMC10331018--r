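test_that("extractor spatial arithmetic matches the architecture worked example", {
  # depth 5 at 64x64: pre-flatten 256 x 2 x 2, flattened 4096, embedding 128
  ex5 <- extractorConfig(nConvLayers = 5)
  m5 <- milModel(extractor = ex5, seed = 1)
  s <- 2
  set.seed(3)
  sl <- array(rnorm(64 * 64 * s), c(64, 64, s))
  X <- matrix(as.numeric(sl), 64 * 64 * s, 1)
  fwd <- mamil:::.extractorForward(X, m5@params, m5@state, ex5, s)
  expect_equal(fwd$preFlattenSide, 2)
  expect_equal(fwd$preFlattenChannels, 256)
  # flatten of a 256 x 2 x 2 map
  expect_equal(ncol(fwd$F), 256 * 2 * 2)
  expect_equal(dim(fwd$E), c(s, 128))
  expect_equal(ex5$channels, c(16, 32, 64, 128, 256))
  # depth 3 at 64x64: pre-flatten 64 x 8 x 8
  ex3 <- extractorConfig(nConvLayers = 3, channels = c(16, 32, 64))
  m3 <- milModel(extractor = ex3, seed = 1)
  fwd3 <- mamil:::.extractorForward(X, m3@params, m3@state, ex3, s)
  expect_equal(fwd3$preFlattenSide, 8)
  expect_equal(fwd3$preFlattenChannels, 64)
})

test_that("extractor weights are shared across instances", {
  ex <- tinyExtractor()
  m <- milModel(extractor = ex, seed = 2)
  set.seed(4)
  one <- matrix(rnorm(16 * 16), 16, 16)
  sl <- array(0, c(16, 16, 3))
  sl[, , 1] <- one; sl[, , 2] <- matrix(rnorm(256), 16); sl[, , 3] <- one
  E <- extractFeatures(m, sl)
  expect_equal(E[1, ], E[3, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(E[1, ], E[2, ])))
})

test_that("invalid extractor configurations are rejected before use", {
  expect_error(extractorConfig(nConvLayers = 8), "between 3 and 7")
  expect_error(extractorConfig(nConvLayers = 2), "between 3 and 7")
  expect_error(extractorConfig(nConvLayers = 5, channels = c(16, 32)), "one entry per")
  # depth 7 is legal at 64x64 thanks to the pool-skip convention
  ex7 <- extractorConfig(nConvLayers = 7, inputSize = 64)
  expect_equal(mamil:::.spatialSides(ex7), c(32, 16, 8, 4, 2, 1, 1))
})

test_that("squeeze equals the grand mean (constants and brute-force oracle)", {
  s <- 4; D <- 16
  M <- lapply(c(2, -1, 0.5, 3, 7), function(cst) matrix(cst, s, D))
  expect_equal(squeezeDescriptor(M), c(2, -1, 0.5, 3, 7))
  M2 <- list(rbind(matrix(1, 1, 128), matrix(3, 1, 128)))
  expect_equal(squeezeDescriptor(M2), 2)
  set.seed(9)
  for (rep in 1:20) {
    M <- lapply(1:5, function(k) matrix(rnorm(s * D), s, D))
    expect_equal(squeezeDescriptor(M), oracleSqueeze(M), tolerance = 1e-6)
  }
})

test_that("excitation matches identity composition, zero input, and the loop oracle", {
  I5 <- diag(5)
  d <- c(0.5, 1, 0.2, 0.7, 0.1)
  expect_equal(exciteWeights(d, I5, numeric(5), I5, numeric(5), gate = "none"), d)
  expect_equal(exciteWeights(numeric(5), I5, numeric(5), I5, numeric(5),
                             gate = "sigmoid"), rep(0.5, 5))
  set.seed(10)
  for (rep in 1:20) {
    W1 <- matrix(rnorm(25), 5, 5); W2 <- matrix(rnorm(25), 5, 5)
    b1 <- rnorm(5); b2 <- rnorm(5); d <- rnorm(5)
    expect_equal(exciteWeights(d, W1, b1, W2, b2, gate = "sigmoid"),
                 oracleExcite(d, W1, b1, W2, b2), tolerance = 1e-6)
  }
  expect_error(exciteWeights(rnorm(4), diag(5), numeric(5), diag(5)),
               "dimension mismatch")
})

test_that("reweight implements the attention-weighted sum", {
  set.seed(11)
  M <- lapply(1:5, function(k) matrix(rnorm(12), 3, 4))
  oneHot <- c(0, 1, 0, 0, 0)
  expect_equal(reweightModalities(M, oneHot), M[[2]])
  expect_equal(reweightModalities(M, rep(0.2, 5)),
               Reduce(`+`, M) / 5)
  expect_equal(reweightModalities(M, rep(0, 5)), matrix(0, 3, 4))
})

test_that("instance stream max-pools with lowest-index tie-break", {
  H <- diag(3)
  w0 <- c(0.2, 0.9, 0.4)
  st <- instanceStream(H, w0)
  expect_equal(st$scores, c(0.2, 0.9, 0.4))
  expect_equal(st$cM, 0.9)
  expect_equal(st$criticalIndex, 2)
  # singleton bag
  st1 <- instanceStream(H[1, , drop = FALSE], w0)
  expect_equal(st1$criticalIndex, 1)
  expect_equal(st1$cM, 0.2)
  # duplicate max at indices 1 and 3 -> index 1
  H2 <- rbind(c(1, 0, 0), c(0, 0.5, 0), c(1, 0, 0))
  st2 <- instanceStream(H2, c(1, 1, 1))
  expect_equal(st2$criticalIndex, 1)
})

test_that("bag stream matches singleton/uniform closed forms and the loop oracle", {
  D <- 16
  set.seed(12)
  Wq <- matrix(rnorm(D * D, 0, 0.3), D); Wv <- matrix(rnorm(D * D, 0, 0.3), D)
  wb <- rnorm(D)
  # singleton: U = 1, b = v0
  h <- matrix(rnorm(D), 1)
  bs <- bagStream(h, 1, Wq, Wv, wb)
  expect_equal(bs$U, 1)
  expect_equal(bs$b, as.numeric(h %*% Wv))
  expect_equal(bs$cB, sum(wb * as.numeric(h %*% Wv)))
  # identical instances: uniform U, b = mean of v
  H <- matrix(rep(rnorm(D), each = 4), 4, D, byrow = FALSE)
  H <- matrix(rep(h, 4), 4, D, byrow = TRUE)
  bsU <- bagStream(H, 1, Wq, Wv, wb)
  expect_equal(bsU$U, rep(0.25, 4))
  expect_equal(bsU$b, as.numeric(h %*% Wv), tolerance = 1e-12)
  # random bags vs brute-force double-loop softmax oracle
  for (rep in 1:20) {
    s <- sample(2:8, 1)
    H <- matrix(rnorm(s * D), s, D)
    m <- sample(s, 1)
    got <- bagStream(H, m, Wq, Wv, wb)
    want <- oracleBagStream(H, m, Wq, Wv, wb)
    expect_equal(got$U, want$U, tolerance = 1e-5)
    expect_equal(got$b, want$b, tolerance = 1e-5)
    expect_equal(got$cB, want$cB, tolerance = 1e-5)
    expect_equal(sum(got$U), 1, tolerance = 1e-12)
    expect_true(all(got$U >= 0))
  }
  expect_error(bagStream(H, 99, Wq, Wv, wb), "out of range")
})

test_that("score fusion averages the two streams", {
  expect_equal(fuseScores(0.9, 0.5), 0.7)
  expect_equal(fuseScores(1.3, 1.3), 1.3)
  expect_equal(fuseScores(0, 0), 0)
  expect_error(fuseScores(NaN, 1))
})

test_that("forward pass is deterministic and permutation-equivariant", {
  bag <- randomBag(s = 5, seed = 21)
  m <- milModel(extractor = tinyExtractor(), seed = 8)
  f1 <- forwardCase(m, bag)
  f2 <- forwardCase(m, bag)
  expect_identical(f1$cFinal, f2$cFinal)
  perm <- c(3, 1, 5, 2, 4)
  sl <- lapply(bag@slices, function(a) a[, , perm, drop = FALSE])
  bagP <- preparedBag(sl, caseId = "perm", label = bagLabel(bag))
  fp <- forwardCase(m, bagP)
  expect_equal(fp$cFinal, f1$cFinal, tolerance = 1e-10)
  expect_equal(fp$U, f1$U[perm], tolerance = 1e-10)
  expect_equal(fp$criticalIndex, which(perm == f1$criticalIndex))
  expect_equal(fp$instanceScores, f1$instanceScores[perm], tolerance = 1e-10)
  # singleton bag does not degenerate
  b1 <- randomBag(s = 1, seed = 22)
  fs <- forwardCase(m, b1)
  expect_true(is.finite(fs$cFinal))
  expect_equal(fs$U, 1)
})

test_that("one-hot attention reduces the network to a single-modality model", {
  bag <- randomBag(s = 4, seed = 23)
  m <- milModel(extractor = tinyExtractor(), seed = 9)
  # run the fused pipeline by hand with a forced one-hot attention vector
  M <- lapply(bag@slices, function(sl) extractFeatures(m, sl))
  aHot <- c(0, 0, 1, 0, 0)
  H <- reweightModalities(M, aHot)
  expect_equal(H, M[[3]])
  inst <- instanceStream(H, m@params$w0)
  instSingle <- instanceStream(M[[3]], m@params$w0)
  expect_identical(inst, instSingle)
  bs <- bagStream(H, inst$criticalIndex, m@params$Wq, m@params$Wv, m@params$wb)
  bsSingle <- bagStream(M[[3]], instSingle$criticalIndex, m@params$Wq,
                        m@params$Wv, m@params$wb)
  expect_identical(bs$cB, bsSingle$cB)
})

test_that("ablation switches remove exactly the module parameters", {
  ex <- tinyExtractor()
  full <- milModel(extractor = ex, seed = 1)
  bare <- milModel(extractor = ex, useAttention = FALSE,
                   useAggregator = FALSE, seed = 1)
  attOnly <- milModel(extractor = ex, useAttention = TRUE,
                      useAggregator = FALSE, seed = 1)
  expect_true(all(c("att.W1", "att.W2", "Wq", "Wv", "wb") %in% names(full@params)))
  expect_false(any(c("att.W1", "att.W2", "att.b1", "att.b2",
                     "Wq", "Wv", "wb") %in% names(bare@params)))
  expect_true(all(c("att.W1", "att.W2") %in% names(attOnly@params)))
  expect_false(any(c("Wq", "Wv", "wb") %in% names(attOnly@params)))
  # benchmark scores the bag as the mean instance score
  bag <- randomBag(s = 4, seed = 24)
  f <- forwardCase(bare, bag)
  expect_equal(f$attention, rep(0.2, 5))
  expect_equal(f$cFinal, mean(f$instanceScores), tolerance = 1e-12)
  expect_equal(f$U, rep(0.25, 4))
})

test_that("backward pass matches finite differences on every parameter group", {
  ex <- extractorConfig(nConvLayers = 3, channels = c(2, 3, 4), embedDim = 6,
                        inputSize = 8)
  m <- milModel(extractor = ex, seed = 3)
  bags <- tinyBags(nCases = 2, seed = 7, targetSize = 8,
                   imageSize = 24, sliceRange = c(2, 3))
  bag <- bags[[1]]; y <- bagLabel(bag)
  fwd <- mamil:::.forwardBag(m, bag, train = TRUE)
  bw <- mamil:::.backwardCase(m, fwd, y)
  lossAt <- function(params) {
    mm <- new("MILModel", config = m@config, params = params, state = m@state)
    f <- mamil:::.forwardBag(mm, bag, train = TRUE)
    mamil:::.bceLoss(f$cFinal, y)
  }
  eps <- 1e-5
  set.seed(31)
  for (nm in names(m@params)) {
    n <- length(m@params[[nm]])
    pick <- if (n > 4) sample.int(n, 4) else seq_len(n)
    for (i in pick) {
      pp <- m@params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m@params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
      ana <- bw$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("checkpoints round-trip through save/load", {
  m <- milModel(extractor = tinyExtractor(), seed = 13)
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, path)
  back <- loadModel(path)
  expect_identical(back@params, m@params)
  expect_identical(back@config, m@config)
  bag <- randomBag(s = 3, seed = 25)
  expect_identical(forwardCase(back, bag)$cFinal, forwardCase(m, bag)$cFinal)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(loadModel(bad), "not a model checkpoint")
})
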