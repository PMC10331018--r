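#' @import methods
NULL

#' Canonical MRI modality names
#'
#' The five co-registered modalities a case carries, in canonical order:
#' T2-weighted, arterial phase, venous phase, delay phase, and the apparent
#' diffusion coefficient map.
#'
#' @return Character vector of length 5.
#' @export
modalityNames <- function() c("t2", "arterial", "venous", "delay", "adc")

#' Multi-modality lesion case (a MIL bag)
#'
#' One patient's lesion: five co-registered modality volumes, a binary
#' lesion mask on the same grid, and a binary case label. Under the
#' multiple-instance view the case is a bag whose instances are the axial
#' slices; the bag is positive iff at least one slice carries the signal.
#'
#' Volumes are stored as H x W x s arrays (rows, columns, slices). The
#' \code{witness} slot records, when known (e.g. for phantoms), which slices
#' carry signal; it is all-\code{NA} for cases read from disk.
#'
#' @slot caseId character scalar.
#' @slot volumes named list of five H x W x s numeric arrays, in
#'   \code{modalityNames()} order.
#' @slot mask H x W x s binary array (lesion support).
#' @slot label integer 0 or 1.
#' @slot voxelSpacing numeric length-3 (dz, dy, dx) in mm.
#' @slot witness logical length-s; NA when unknown.
#'
#' @export
setClass("MultiModalCase", representation(
  caseId = "character",
  volumes = "list",
  mask = "array",
  label = "integer",
  voxelSpacing = "numeric",
  witness = "logical"
))

setValidity("MultiModalCase", function(object) {
  msg <- character()
  if (length(object@caseId) != 1L) msg <- c(msg, "caseId must be a single string")
  if (length(object@volumes) != 5L ||
      !identical(names(object@volumes), modalityNames()))
    msg <- c(msg, "volumes must be a named list of the 5 canonical modalities")
  dims <- lapply(object@volumes, dim)
  if (!all(vapply(dims, function(d) identical(d, dim(object@mask)), logical(1))))
    msg <- c(msg, "all volumes and the mask must share the same H x W x s shape")
  if (length(dim(object@mask)) != 3L)
    msg <- c(msg, "mask must be a 3D array")
  if (sum(object@mask) == 0) msg <- c(msg, "mask must be nonempty")
  if (!(object@label %in% c(0L, 1L))) msg <- c(msg, "label must be 0 or 1")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    msg <- c(msg, "voxelSpacing must be 3 positive numbers (dz, dy, dx)")
  if (length(object@witness) != dim(object@mask)[3])
    msg <- c(msg, "witness must have one entry per slice")
  if (length(msg)) msg else TRUE
})

#' Construct a MultiModalCase
#'
#' @param caseId case identifier.
#' @param volumes named list of five H x W x s arrays (\code{modalityNames()}
#'   order).
#' @param mask H x W x s binary array.
#' @param label 0 or 1.
#' @param voxelSpacing (dz, dy, dx) in mm; default c(5, 1, 1).
#' @param witness optional logical per-slice signal indicator.
#' @return A \linkS4class{MultiModalCase}.
#' @export
multiModalCase <- function(caseId, volumes, mask, label,
                           voxelSpacing = c(5, 1, 1), witness = NULL) {
  if (is.null(witness)) witness <- rep(NA, dim(mask)[3])
  new("MultiModalCase", caseId = as.character(caseId), volumes = volumes,
      mask = mask, label = as.integer(label),
      voxelSpacing = as.numeric(voxelSpacing), witness = as.logical(witness))
}

#' Network-ready bag of normalized slices
#'
#' Output of \code{\link{prepareBag}}: five per-modality stacks of z-scored,
#' resized slices sharing the shape t x t x s'.
#'
#' @slot slices named list of five t x t x s' numeric arrays.
#' @slot caseId character scalar.
#' @slot label integer 0 or 1.
#' @slot witness logical length-s'.
#' @export
setClass("PreparedBag", representation(
  slices = "list",
  caseId = "character",
  label = "integer",
  witness = "logical"
))

setValidity("PreparedBag", function(object) {
  msg <- character()
  if (length(object@slices) != 5L ||
      !identical(names(object@slices), modalityNames()))
    msg <- c(msg, "slices must hold the 5 canonical modalities")
  d1 <- dim(object@slices[[1]])
  if (!all(vapply(object@slices, function(x) identical(dim(x), d1), logical(1))))
    msg <- c(msg, "all modalities must share the same t x t x s' shape")
  if (length(d1) != 3L || d1[1] != d1[2])
    msg <- c(msg, "slices must be square t x t x s' arrays")
  if (d1[3] < 1L) msg <- c(msg, "bag must retain at least one slice")
  if (!(object@label %in% c(0L, 1L))) msg <- c(msg, "label must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' @rdname PreparedBag-class
#' @param slices,caseId,label,witness see slots.
#' @return A \linkS4class{PreparedBag}.
#' @export
preparedBag <- function(slices, caseId, label, witness = NULL) {
  if (is.null(witness)) witness <- rep(NA, dim(slices[[1]])[3])
  new("PreparedBag", slices = slices, caseId = as.character(caseId),
      label = as.integer(label), witness = as.logical(witness))
}

#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @export
setGeneric("bagLabel", function(x) standardGeneric("bagLabel"))
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))
#' @export
setGeneric("witnessSlices", function(x) standardGeneric("witnessSlices"))

#' Accessors for cases and bags
#'
#' \code{caseId} returns the identifier, \code{bagLabel} the binary label,
#' \code{nSlices} the number of slice instances, \code{witnessSlices} the
#' per-slice signal indicator (NA when unknown).
#'
#' @param x a \linkS4class{MultiModalCase} or \linkS4class{PreparedBag}.
#' @name bag-accessors
#' @aliases caseId bagLabel nSlices witnessSlices
NULL

#' @rdname bag-accessors
#' @export
setMethod("caseId", "MultiModalCase", function(x) x@caseId)
#' @rdname bag-accessors
#' @export
setMethod("caseId", "PreparedBag", function(x) x@caseId)
#' @rdname bag-accessors
#' @export
setMethod("bagLabel", "MultiModalCase", function(x) x@label)
#' @rdname bag-accessors
#' @export
setMethod("bagLabel", "PreparedBag", function(x) x@label)
#' @rdname bag-accessors
#' @export
setMethod("nSlices", "MultiModalCase", function(x) dim(x@mask)[3])
#' @rdname bag-accessors
#' @export
setMethod("nSlices", "PreparedBag", function(x) dim(x@slices[[1]])[3])
#' @rdname bag-accessors
#' @export
setMethod("witnessSlices", "MultiModalCase", function(x) x@witness)
#' @rdname bag-accessors
#' @export
setMethod("witnessSlices", "PreparedBag", function(x) x@witness)

setMethod("show", "MultiModalCase", function(object) {
  d <- dim(object@mask)
  cat(sprintf("MultiModalCase '%s': %d slice(s) of %dx%d, label %d\n",
              object@caseId, d[3], d[1], d[2], object@label))
  cat(sprintf("  modalities: %s\n", paste(names(object@volumes), collapse = ", ")))
  cat(sprintf("  mask voxels: %d; spacing %.1fx%.1fx%.1f mm\n",
              sum(object@mask), object@voxelSpacing[1], object@voxelSpacing[2],
              object@voxelSpacing[3]))
})

setMethod("show", "PreparedBag", function(object) {
  d <- dim(object@slices[[1]])
  cat(sprintf("PreparedBag '%s': %d instance(s) of %dx%d, label %d\n",
              object@caseId, d[3], d[1], d[2], object@label))
})
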