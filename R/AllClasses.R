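#' @useDynLib foamidl, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats pt rnorm runif sd var setNames
#' @importFrom utils head read.csv write.csv
NULL

#' Volume3D: a 3D voxel intensity grid with spacing metadata
#'
#' The unit of subject-level input: a real-valued 3D array of voxel
#' intensities plus per-axis voxel size (mm, metadata only) and a subject
#' identifier. Axis order is taken as stored on disk; no reorientation to a
#' canonical anatomical frame is performed (registration to a common
#' template is assumed upstream).
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing numeric(3), voxel size per axis in mm.
#' @slot subjectID character(1).
#' @export
setClass("Volume3D",
  representation(data = "array", spacing = "numeric", subjectID = "character"),
  prototype(spacing = c(1, 1, 1), subjectID = NA_character_))

setValidity("Volume3D", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (any(d < 1L)) return("all dimensions must be >= 1")
  if (!all(is.finite(object@data))) return("data contains NaN/Inf voxels")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)))
    return("spacing must be numeric(3)")
  TRUE
})

#' PatchSet: cubic patch locations on a volume grid
#'
#' A set of axis-aligned cubic patch locations sharing one width `W`.
#' Origins are 0-based voxel indices of the patch corner; each patch covers
#' the half-open cube `[origin, origin + W)` per axis. When produced by
#' [selectBagLocations()] the set is ordered by discriminative rank and
#' carries the normalized scores; it then plays the role of a bag
#' specification applied identically to every subject.
#'
#' @slot origins integer matrix (n x 3) of 0-based corner indices.
#' @slot width integer(1), patch width W in voxels.
#' @slot score numeric, optional per-location score (length 0 or n).
#' @export
setClass("PatchSet",
  representation(origins = "matrix", width = "integer", score = "numeric"),
  prototype(score = numeric(0)))

setValidity("PatchSet", function(object) {
  o <- object@origins
  if (ncol(o) != 3L) return("origins must have 3 columns")
  if (any(o < 0L)) return("origin components must be >= 0")
  if (length(object@width) != 1L || object@width < 1L)
    return("width must be a single integer >= 1")
  if (length(object@score) && length(object@score) != nrow(o))
    return("score length must match number of locations")
  if (nrow(o) && anyDuplicated(o)) return("locations must be pairwise distinct")
  TRUE
})

#' PValueMap: per-location group-difference significance map
#'
#' For every patch location of a uniform partition, the two-sided p-value of
#' a two-sample Welch t-test between groups, plus its min-max normalized
#' score in `[0, 1]` (0 = most discriminative).
#'
#' @slot origins integer matrix (n x 3), 0-based.
#' @slot width integer(1), patch width W.
#' @slot pRaw numeric, raw two-sided p-values in `[0, 1]`.
#' @slot pNorm numeric, normalized scores in `[0, 1]`.
#' @slot groupSizes integer(2), subjects per group (nA, nB).
#' @slot statistic character(1), per-location summary used ("patch_mean" or
#'   "voxel_wise").
#' @export
setClass("PValueMap",
  representation(origins = "matrix", width = "integer", pRaw = "numeric",
                 pNorm = "numeric", groupSizes = "integer", statistic = "character"))

setValidity("PValueMap", function(object) {
  n <- nrow(object@origins)
  if (length(object@pRaw) != n || length(object@pNorm) != n)
    return("pRaw/pNorm must match number of locations")
  if (any(object@pRaw < 0 | object@pRaw > 1, na.rm = TRUE))
    return("raw p-values must lie in [0, 1]")
  if (any(object@pNorm < 0 | object@pNorm > 1, na.rm = TRUE))
    return("normalized scores must lie in [0, 1]")
  if (length(object@groupSizes) != 2L) return("groupSizes must be length 2")
  TRUE
})

#' PatchBag: one subject's multi-instance bag
#'
#' The k fixed-size cubic patches extracted from one subject's volume at the
#' shared bag locations, in rank order, with the (weak) bag-level label.
#'
#' @slot patches list of k numeric W x W x W arrays.
#' @slot origins integer matrix (k x 3), 0-based.
#' @slot width integer(1).
#' @slot label integer(1), 0/1 or NA when unset.
#' @slot subjectID character(1).
#' @export
setClass("PatchBag",
  representation(patches = "list", origins = "matrix", width = "integer",
                 label = "integer", subjectID = "character"),
  prototype(label = NA_integer_, subjectID = NA_character_))

setValidity("PatchBag", function(object) {
  k <- length(object@patches)
  if (k < 1L) return("bag must hold at least one patch")
  if (nrow(object@origins) != k) return("origins must match patch count")
  W <- object@width
  ok <- vapply(object@patches, function(p) identical(dim(p), rep(as.integer(W), 3L)),
               logical(1))
  if (!all(ok)) return("every patch must be a W x W x W array")
  if (!is.na(object@label) && !object@label %in% c(0L, 1L))
    return("label must be 0, 1 or NA")
  TRUE
})

#' BagModel: the full bag-level classification model
#'
#' Holds one shared PatchNet parameter set (MIL weight sharing across the k
#' instances), the attention MIL pooling parameters, the global classifier
#' parameters, and a configuration snapshot (k, W, architecture sizes,
#' ablation flags). Composition follows the bag-probability decomposition
#' `Theta(X) = g(phi(f(X)))`: per-patch transform f (PatchNet), permutation
#' pooling phi (attention MIL), bag classifier g.
#'
#' @slot patchnet list of PatchNet parameters.
#' @slot amidl list of attention-pooling parameters.
#' @slot classifier list of global-classifier parameters.
#' @slot config list: k, W, channel sizes, ablation flags, etc.
#' @export
setClass("BagModel",
  representation(patchnet = "list", amidl = "list", classifier = "list",
                 config = "list"))

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume3D '%s': %d x %d x %d voxels, spacing %s mm\n",
              object@subjectID, d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d cubic patch location(s), W = %d%s\n",
              nrow(object@origins), object@width,
              if (length(object@score)) ", scored/ranked" else ""))
})

setMethod("show", "PValueMap", function(object) {
  cat(sprintf("PValueMap (%s): %d locations, W = %d, groups %d vs %d\n",
              object@statistic, nrow(object@origins), object@width,
              object@groupSizes[1], object@groupSizes[2]))
  cat(sprintf("  raw p in [%.3g, %.3g]\n", min(object@pRaw), max(object@pRaw)))
})

setMethod("show", "PatchBag", function(object) {
  cat(sprintf("PatchBag '%s': %d patch(es) of %d^3 voxels, label = %s\n",
              object@subjectID, length(object@patches), object@width,
              ifelse(is.na(object@label), "unset", object@label)))
})

setMethod("show", "BagModel", function(object) {
  cfg <- object@config
  cat(sprintf("BagModel: k = %d patches of W = %d, PatchNet channels %s\n",
              cfg$k, cfg$W, paste(cfg$channels, collapse = "-")))
  fl <- cfg$flags
  on <- names(fl)[vapply(fl, isTRUE, logical(1))]
  cat(sprintf("  ablation flags: %s\n", if (length(on)) paste(on, collapse = ", ") else "none"))
})
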