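# Minimal trainable layer primitives used by the slice feature extractor.
#
# A batch of N single-case slices with C channels on an H x W grid is held
# as a (H*W*N) x C matrix: rows are pixels in column-major order within a
# slice, slices stacked; columns are channels. Convolutions are computed by
# gathering 3x3 neighbourhoods into a (H*W*N) x (9*C) matrix (im2col) and
# multiplying by a (9*C) x Cout weight matrix, so all heavy arithmetic runs
# through BLAS. Padding is 1 (same-size); out-of-image taps read a zero row.
# Row-vector broadcasts are spelled out with rep(v, each = n) instead of
# sweep(): at these matrix sizes dispatch overhead, not FLOPs, dominates.

.idxCache <- new.env(parent = emptyenv())

# Gather indices for the 9 kernel taps at every pixel of every slice.
# Entries pointing outside the image are redirected to row H*W*N + 1,
# which the caller appends as an all-zero row.
.im2colIdx <- function(H, W, N) {
  key <- sprintf("c%d_%d_%d", H, W, N)
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  hw <- H * W
  r <- rep(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  zero <- hw * N + 1L
  IDX <- matrix(0L, hw * N, 9L)
  off <- rep((0:(N - 1L)) * hw, each = hw)
  o <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    o <- o + 1L
    rr <- r + dr; ccc <- cc + dc
    ok <- rr >= 1L & rr <= H & ccc >= 1L & ccc <= W
    nb <- ifelse(ok, rr + (ccc - 1L) * H, NA_integer_)
    col <- rep(nb, N) + off
    col[is.na(col)] <- zero
    IDX[, o] <- col
  }
  .idxCache[[key]] <- IDX
  IDX
}

# 2x2/stride-2 max-pool candidate rows (4 index vectors per output pixel).
.poolIdx <- function(H, W, N) {
  key <- sprintf("p%d_%d_%d", H, W, N)
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  ro <- rep(seq_len(Ho), Wo)
  co <- rep(seq_len(Wo), each = Ho)
  off <- rep((0:(N - 1L)) * (H * W), each = Ho * Wo)
  lin <- function(r, c) rep(r + (c - 1L) * H, N) + off
  out <- list(i1 = lin(2L * ro - 1L, 2L * co - 1L),
              i2 = lin(2L * ro, 2L * co - 1L),
              i3 = lin(2L * ro - 1L, 2L * co),
              i4 = lin(2L * ro, 2L * co))
  .idxCache[[key]] <- out
  out
}

.convForward <- function(X, Wmat, b, H, W, N, keepCols = FALSE) {
  out <- .cppConvFwd(X, Wmat, b, .im2colIdx(H, W, N), keepCols)
  list(Y = out$Y, cols = out$cols)
}

.convBackward <- function(dY, cols, Wmat, H, W, N) {
  out <- .cppConvBwd(dY, cols, Wmat, .im2colIdx(H, W, N))
  list(dX = out$dX, dW = out$dW, db = as.numeric(out$db))
}

.poolForward <- function(X, H, W, N, keepArg = FALSE) {
  pi <- .poolIdx(H, W, N)
  out <- .cppPoolFwd(X, pi$i1, pi$i2, pi$i3, pi$i4, keepArg)
  list(Y = out$Y, arg = out$arg, idx = pi, inRows = nrow(X))
}

.poolBackward <- function(dY, cache) {
  pi <- cache$idx
  .cppPoolBwd(dY, cache$arg, pi$i1, pi$i2, pi$i3, pi$i4, cache$inRows)
}

.bnEps <- 1e-5

.bnForward <- function(X, gamma, beta, runMean, runVar, train, momentum = 0.1) {
  if (train) {
    out <- .cppBnFwdTrain(X, gamma, beta, .bnEps)
    list(Y = out$Y, xhat = out$xhat, invstd = as.numeric(out$invstd),
         runMean = (1 - momentum) * runMean + momentum * as.numeric(out$mu),
         runVar = (1 - momentum) * runVar + momentum * as.numeric(out$v))
  } else {
    scale <- gamma / sqrt(runVar + .bnEps)
    shift <- beta - runMean * scale
    list(Y = .cppBnFwdEval(X, scale, shift), xhat = NULL, invstd = NULL,
         runMean = runMean, runVar = runVar)
  }
}

.bnBackward <- function(dY, xhat, invstd, gamma) {
  out <- .cppBnBwd(dY, xhat, invstd, gamma)
  list(dX = out$dX, dgamma = as.numeric(out$dgamma),
       dbeta = as.numeric(out$dbeta))
}

# Flatten (hw*N x C) feature rows into per-slice vectors (N x hw*C),
# channel-major so all pixels of channel 1 come first.
.flattenSlices <- function(X, hw, N) {
  C <- ncol(X)
  t(matrix(aperm(array(X, c(hw, N, C)), c(1, 3, 2)), hw * C, N))
}

.unflattenSlices <- function(F, hw, N) {
  C <- ncol(F) / hw
  arr <- array(t(F), c(hw, C, N))
  matrix(aperm(arr, c(1, 3, 2)), hw * N, C)
}
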