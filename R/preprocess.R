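#' Preprocessing configuration
#'
#' Controls conversion of a raw \linkS4class{MultiModalCase} into a
#' network-ready \linkS4class{PreparedBag}: an in-plane crop of the lesion
#' bounding box expanded by \code{marginMm} millimetres, per-slice z-score
#' standardization, bilinear resize to \code{targetSize} squared, and
#' (training only) bag-level flip augmentation.
#'
#' @param marginMm margin beyond the tumor bounding box, in mm (default 10).
#' @param targetSize output slice side in pixels (default 64, minimum 8).
#' @param augment logical; enable training-time augmentation.
#' @param augmentProb probability of each flip draw (default 0.5).
#' @param rotate90 logical; additionally allow a random 90-degree rotation
#'   during augmentation (off by default).
#' @return A validated list of class \code{preprocessConfig}.
#' @export
preprocessConfig <- function(marginMm = 10, targetSize = 64L, augment = FALSE,
                             augmentProb = 0.5, rotate90 = FALSE) {
  stopifnot(marginMm >= 0, targetSize >= 8, augmentProb >= 0, augmentProb <= 1)
  structure(list(marginMm = marginMm, targetSize = as.integer(targetSize),
                 augment = isTRUE(augment), augmentProb = augmentProb,
                 rotate90 = isTRUE(rotate90)),
            class = "preprocessConfig")
}

#' Crop a case to the lesion region of interest
#'
#' Keeps only slices whose mask is nonempty, then crops all five modalities
#' (and the mask) to the in-plane bounding box of the mask expanded by
#' \code{ceiling(marginMm / pixelSpacing)} pixels on each side, clipped to
#' the volume. The margin is applied in-plane only; the through-plane extent
#' is exactly the masked slices.
#'
#' @param case a \linkS4class{MultiModalCase} with nonempty mask.
#' @param config a \code{\link{preprocessConfig}}.
#' @return The cropped \linkS4class{MultiModalCase}.
#' @export
cropROI <- function(case, config = preprocessConfig()) {
  mask <- case@mask
  keep <- which(apply(mask, 3, sum) > 0)
  if (length(keep) == 0) stop("empty mask: nothing to crop")
  mask <- mask[, , keep, drop = FALSE]
  idx <- which(mask > 0, arr.ind = TRUE)
  my <- ceiling(config$marginMm / case@voxelSpacing[2])
  mx <- ceiling(config$marginMm / case@voxelSpacing[3])
  y0 <- max(1L, min(idx[, 1]) - my); y1 <- min(dim(mask)[1], max(idx[, 1]) + my)
  x0 <- max(1L, min(idx[, 2]) - mx); x1 <- min(dim(mask)[2], max(idx[, 2]) + mx)
  vols <- lapply(case@volumes, function(v) v[y0:y1, x0:x1, keep, drop = FALSE])
  multiModalCase(caseId = case@caseId, volumes = vols,
                 mask = mask[y0:y1, x0:x1, , drop = FALSE],
                 label = case@label, voxelSpacing = case@voxelSpacing,
                 witness = case@witness[keep])
}

#' Z-score standardize one slice
#'
#' Subtracts the slice mean and divides by the population standard
#' deviation. A constant slice maps to all zeros.
#'
#' @param x 2D numeric matrix.
#' @return Matrix of the same shape with mean 0 and sd 1 (unless constant).
#' @export
normalizeSlice <- function(x) {
  stopifnot(is.matrix(x))
  mu <- mean(x)
  sdv <- sqrt(mean((x - mu)^2))
  if (sdv == 0) return(array(0, dim(x)))
  (x - mu) / sdv
}

#' Bilinearly resize one slice
#'
#' @param x 2D numeric matrix with both dimensions >= 1.
#' @param targetSize output side in pixels.
#' @return \code{targetSize x targetSize} matrix.
#' @export
resizeSlice <- function(x, targetSize = 64L) {
  stopifnot(is.matrix(x), nrow(x) >= 1, ncol(x) >= 1)
  if (nrow(x) == targetSize && ncol(x) == targetSize) return(x)
  EBImage::imageData(EBImage::resize(EBImage::Image(x),
                                     w = targetSize, h = targetSize))
}

#' Prepare one case for the network
#'
#' \code{\link{cropROI}}, then per slice and modality: z-score, bilinear
#' resize to \code{targetSize}, and re-standardization (so each retained
#' slice meets the zero-mean/unit-sd input contract exactly, independent of
#' resize artifacts).
#'
#' @param case a \linkS4class{MultiModalCase}.
#' @param config a \code{\link{preprocessConfig}}.
#' @return A \linkS4class{PreparedBag}.
#' @export
prepareBag <- function(case, config = preprocessConfig()) {
  cc <- cropROI(case, config)
  t <- config$targetSize
  s <- nSlices(cc)
  out <- lapply(cc@volumes, function(v) {
    a <- array(0, c(t, t, s))
    for (k in seq_len(s)) {
      a[, , k] <- normalizeSlice(resizeSlice(normalizeSlice(v[, , k]), t))
    }
    a
  })
  preparedBag(out, caseId = cc@caseId, label = cc@label, witness = cc@witness)
}

#' Prepare a whole cohort
#'
#' @param cases list of \linkS4class{MultiModalCase}.
#' @param config a \code{\link{preprocessConfig}}.
#' @return List of \linkS4class{PreparedBag}.
#' @export
prepareCohort <- function(cases, config = preprocessConfig()) {
  lapply(cases, prepareBag, config = config)
}

#' Bag-level flip augmentation
#'
#' With probability \code{augmentProb} flips horizontally and, independently
#' with the same probability, vertically; if \code{rotate90} is enabled, a
#' quarter-turn is additionally applied with the same probability. The same
#' transform is applied to every slice of every modality, keeping instances
#' spatially consistent. Flips permute pixels, so per-slice means, sds and
#' histograms are unchanged. Consumes the caller's RNG stream.
#'
#' @param bag a \linkS4class{PreparedBag}.
#' @param config a \code{\link{preprocessConfig}} with \code{augment = TRUE}.
#' @return The augmented \linkS4class{PreparedBag}.
#' @export
augmentBag <- function(bag, config = preprocessConfig(augment = TRUE)) {
  if (!config$augment) return(bag)
  doH <- stats::runif(1) < config$augmentProb
  doV <- stats::runif(1) < config$augmentProb
  doR <- config$rotate90 && stats::runif(1) < config$augmentProb
  if (!doH && !doV && !doR) return(bag)
  flipAll <- function(a) {
    d <- dim(a)
    if (doH) a <- a[, d[2]:1, , drop = FALSE]   # mirror columns (left-right)
    if (doV) a <- a[d[1]:1, , , drop = FALSE]   # mirror rows (up-down)
    if (doR) a <- aperm(a[d[1]:1, , , drop = FALSE], c(2, 1, 3))  # quarter turn
    a
  }
  sl <- lapply(bag@slices, flipAll)
  preparedBag(sl, caseId = bag@caseId, label = bag@label, witness = bag@witness)
}

#' Write prepared bags to disk
#'
#' One serialized archive per case plus an index CSV (caseId, label, path).
#'
#' @param bags list of \linkS4class{PreparedBag}.
#' @param outDir output directory.
#' @return Path of the index CSV, invisibly.
#' @export
writePreparedBags <- function(bags, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(bags, function(b) {
    p <- sprintf("%s_prepared.rds", caseId(b))
    saveRDS(b, file.path(outDir, p), compress = "gzip")
    p
  }, character(1))
  idx <- data.frame(caseId = vapply(bags, caseId, character(1)),
                    label = vapply(bags, bagLabel, integer(1)),
                    path = paths, stringsAsFactors = FALSE)
  idxPath <- file.path(outDir, "prepared_index.csv")
  utils::write.csv(idx, idxPath, row.names = FALSE)
  invisible(idxPath)
}

#' Read prepared bags written by \code{\link{writePreparedBags}}
#' @param indexPath path to \code{prepared_index.csv}.
#' @return List of \linkS4class{PreparedBag}.
#' @export
readPreparedBags <- function(indexPath) {
  if (!file.exists(indexPath)) stop("index not found: ", indexPath)
  idx <- utils::read.csv(indexPath, stringsAsFactors = FALSE)
  base <- dirname(indexPath)
  lapply(idx$path, function(p) {
    f <- file.path(base, p)
    if (!file.exists(f)) stop("missing prepared bag: ", p)
    readRDS(f)
  })
}
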