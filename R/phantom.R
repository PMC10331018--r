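#' Phantom cohort configuration
#'
#' Parameters of the synthetic multi-modal lesion generator. Each phantom
#' case is a stack of axial slices containing an ellipsoidal lesion mask;
#' positive cases additionally carry a localized Gaussian intensity motif
#' ("signal") on a subset of slices (the witnesses), scaled per modality by
#' \code{modalitySignalWeights}. Negative cases carry no signal anywhere, so
#' the bag label is positive iff at least one slice bears signal — the MIL
#' assumption by construction.
#'
#' Defaults encode the benchmark conditions used throughout: balanced
#' classes, 4-10 slices per lesion, arterial-dominant modality weights
#' (T2, arterial, venous, delay, ADC) = (0.3, 1.0, 0.7, 0.4, 0.5), half the
#' slices of a positive bag carrying signal, and a 5:1 signal-to-noise
#' amplitude ratio.
#'
#' @param nCases number of cases to generate.
#' @param positiveFraction fraction of positive cases in [0, 1].
#' @param sliceRange integer (min, max) slices per lesion, min >= 1.
#' @param imageSize in-plane side of the raw volume, pixels.
#' @param modalitySignalWeights 5 non-negative reals, relative informativeness
#'   of each modality; at least one must be positive.
#' @param witnessRate fraction in (0, 1] of slices carrying signal in a
#'   positive bag; a positive bag gets max(1, round(witnessRate * s)) witnesses.
#' @param signalAmplitude peak amplitude of the signal motif (>= 0).
#' @param noiseSd standard deviation of the i.i.d. Gaussian pixel noise (> 0).
#' @param voxelSpacing (dz, dy, dx) in mm.
#' @param seed integer seed; the cohort is fully determined by it.
#' @return A validated list of class \code{phantomConfig}.
#' @export
phantomConfig <- function(nCases = 100, positiveFraction = 0.5,
                          sliceRange = c(4L, 10L), imageSize = 96L,
                          modalitySignalWeights = c(0.3, 1.0, 0.7, 0.4, 0.5),
                          witnessRate = 0.5, signalAmplitude = 5,
                          noiseSd = 1, voxelSpacing = c(5, 1, 1),
                          seed = 1L) {
  stopifnot(nCases >= 1, positiveFraction >= 0, positiveFraction <= 1,
            length(sliceRange) == 2, sliceRange[1] >= 1,
            sliceRange[2] >= sliceRange[1], imageSize >= 8,
            length(modalitySignalWeights) == 5,
            all(modalitySignalWeights >= 0),
            any(modalitySignalWeights > 0),
            witnessRate > 0, witnessRate <= 1,
            signalAmplitude >= 0, noiseSd > 0)
  structure(list(nCases = as.integer(nCases),
                 positiveFraction = positiveFraction,
                 sliceRange = as.integer(sliceRange),
                 imageSize = as.integer(imageSize),
                 modalitySignalWeights = modalitySignalWeights,
                 witnessRate = witnessRate,
                 signalAmplitude = signalAmplitude,
                 noiseSd = noiseSd,
                 voxelSpacing = voxelSpacing,
                 seed = as.integer(seed)),
            class = "phantomConfig")
}

# Ellipsoidal lesion mask: center jittered around the volume center,
# in-plane semi-axes ~ 1/6..1/4 of the image side, tapered across slices.
.phantomMask <- function(n, s) {
  cy <- n / 2 + stats::runif(1, -n / 12, n / 12)
  cx <- n / 2 + stats::runif(1, -n / 12, n / 12)
  ry <- stats::runif(1, n / 6, n / 4)
  rx <- stats::runif(1, n / 6, n / 4)
  mask <- array(0, c(n, n, s))
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  for (k in seq_len(s)) {
    # through-plane taper: full radius mid-stack, >= 35% at the ends
    t_k <- if (s == 1) 1 else 0.35 + 0.65 * sqrt(pmax(0, 1 - ((k - (s + 1) / 2) / (s / 2 + 0.5))^2))
    m <- ((yy - cy) / (ry * t_k))^2 + ((xx - cx) / (rx * t_k))^2 <= 1
    mask[, , k] <- m
  }
  # guarantee nonempty per slice (tiny lesions at stack ends)
  for (k in seq_len(s)) {
    if (sum(mask[, , k]) == 0) {
      mask[round(cy), round(cx), k] <- 1
    }
  }
  mask
}

# Gaussian blob motif centered at an in-mask pixel, truncated to the mask.
.signalMotif <- function(maskSlice, amplitude) {
  idx <- which(maskSlice > 0, arr.ind = TRUE)
  ctr <- idx[sample.int(nrow(idx), 1L), ]
  n <- nrow(maskSlice)
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  sdpix <- max(2, sqrt(sum(maskSlice)) / 4)
  blob <- amplitude * exp(-(((yy - ctr[1])^2 + (xx - ctr[2])^2) / (2 * sdpix^2)))
  blob * (maskSlice > 0)
}

#' Generate a synthetic multi-modal lesion cohort
#'
#' Produces \code{nCases} \linkS4class{MultiModalCase} phantoms with exact
#' class stratification (\code{round(positiveFraction * nCases)} positives),
#' deterministic given \code{config$seed}. Positive cases carry the signal
#' motif on their witness slices in every modality, scaled by
#' \code{modalitySignalWeights}; negatives never do. I.i.d. Gaussian noise of
#' sd \code{noiseSd} is added everywhere.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @return List of \linkS4class{MultiModalCase}; the manifest data frame
#'   (caseId, label, nSlices, nWitness) is attached as attribute
#'   \code{"manifest"}.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "phantomConfig"))
  nPos <- round(config$positiveFraction * config$nCases)
  labels <- c(rep(1L, nPos), rep(0L, config$nCases - nPos))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  labels <- labels[sample.int(length(labels))]  # interleave classes
  wts <- config$modalitySignalWeights
  cases <- vector("list", config$nCases)
  for (i in seq_len(config$nCases)) {
    s <- sample(seq(config$sliceRange[1], config$sliceRange[2]), 1L)
    n <- config$imageSize
    mask <- .phantomMask(n, s)
    witness <- rep(FALSE, s)
    signal <- array(0, c(n, n, s))   # unit-amplitude motif field
    if (labels[i] == 1L) {
      nw <- max(1L, as.integer(round(config$witnessRate * s)))
      witness[sample.int(s, nw)] <- TRUE
      for (k in which(witness)) {
        signal[, , k] <- .signalMotif(mask[, , k], 1)
      }
    }
    vols <- vector("list", 5L)
    names(vols) <- modalityNames()
    for (m in 1:5) {
      noise <- array(stats::rnorm(n * n * s, 0, config$noiseSd), c(n, n, s))
      vols[[m]] <- config$signalAmplitude * wts[m] * signal + noise
    }
    cases[[i]] <- multiModalCase(
      caseId = sprintf("case_%03d", i), volumes = vols, mask = mask,
      label = labels[i], voxelSpacing = config$voxelSpacing,
      witness = witness)
  }
  manifest <- data.frame(
    caseId = vapply(cases, caseId, character(1)),
    label = vapply(cases, bagLabel, integer(1)),
    nSlices = vapply(cases, nSlices, integer(1)),
    nWitness = vapply(cases, function(x) sum(witnessSlices(x)), integer(1)),
    stringsAsFactors = FALSE)
  attr(cases, "manifest") <- manifest
  cases
}

# Save/restore the global RNG state so generators do not perturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a cohort to disk as NIfTI + CSV manifest
#'
#' One NIfTI volume per modality per case, one NIfTI mask per case, and a
#' manifest CSV with header \code{caseId,label,t2,arterial,venous,delay,adc,mask}
#' holding paths relative to \code{outDir}. Intensities are stored as float32,
#' so a read-back agrees with the in-memory cohort to float32 rounding.
#'
#' @param cases list of \linkS4class{MultiModalCase}.
#' @param outDir output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
writeCohort <- function(cases, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  rows <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    id <- caseId(cs)
    paths <- character(6)
    sp <- cs@voxelSpacing
    pix <- c(sp[3], sp[2], sp[1])  # NIfTI order (dx, dy, dz)
    for (m in 1:5) {
      paths[m] <- sprintf("%s_%s.nii.gz", id, modalityNames()[m])
      RNifti::writeNifti(structure(cs@volumes[[m]], pixdim = pix),
                         file.path(outDir, paths[m]), datatype = "float")
    }
    paths[6] <- sprintf("%s_mask.nii.gz", id)
    RNifti::writeNifti(structure(cs@mask, pixdim = pix),
                       file.path(outDir, paths[6]), datatype = "uint8")
    rows[[i]] <- data.frame(caseId = id, label = bagLabel(cs),
                            t2 = paths[1], arterial = paths[2],
                            venous = paths[3], delay = paths[4],
                            adc = paths[5], mask = paths[6],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  manifestPath <- file.path(outDir, "manifest.csv")
  utils::write.csv(manifest, manifestPath, row.names = FALSE)
  invisible(manifestPath)
}

#' Read a cohort from a manifest CSV
#'
#' Inverse of \code{\link{writeCohort}}. Paths in the manifest are resolved
#' relative to the manifest's directory; a missing file raises an error
#' naming it. Witness annotations are not stored on disk, so read-back cases
#' have \code{witnessSlices(x)} all NA.
#'
#' @param manifestPath path to \code{manifest.csv}.
#' @param voxelSpacing spacing override; by default taken from the NIfTI
#'   headers.
#' @return List of \linkS4class{MultiModalCase}.
#' @export
readCohort <- function(manifestPath, voxelSpacing = NULL) {
  if (!file.exists(manifestPath)) stop("manifest not found: ", manifestPath)
  manifest <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  base <- dirname(manifestPath)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    files <- file.path(base, unlist(row[c(modalityNames(), "mask")]))
    missing <- files[!file.exists(files)]
    if (length(missing))
      stop("missing file(s) referenced by manifest: ",
           paste(basename(missing), collapse = ", "))
    vols <- lapply(files[1:5], function(f) {
      v <- RNifti::readNifti(f)
      array(as.numeric(v), dim(v))
    })
    names(vols) <- modalityNames()
    maskImg <- RNifti::readNifti(files[6])
    mask <- array(as.numeric(maskImg), dim(maskImg))
    sp <- voxelSpacing
    if (is.null(sp)) {
      pd <- RNifti::pixdim(maskImg)
      sp <- c(pd[3], pd[2], pd[1])
    }
    multiModalCase(caseId = row$caseId, volumes = vols, mask = mask,
                   label = row$label, voxelSpacing = sp)
  })
}
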