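#' Construct a Volume3D
#'
#' @param data 3D numeric array of voxel intensities.
#' @param spacing numeric(3) voxel size in mm (metadata only).
#' @param subjectID subject identifier.
#' @return A [Volume3D-class] object.
#' @export
Volume3D <- function(data, spacing = c(1, 1, 1), subjectID = NA_character_) {
  new("Volume3D", data = data, spacing = as.numeric(spacing),
      subjectID = as.character(subjectID))
}

#' Read a volume from a NIfTI-1 file
#'
#' Reads a (optionally gzip-compressed) NIfTI-1 file into a [Volume3D-class].
#' The voxel array is kept in the file's native axis order and intensities
#' are unchanged. Non-3D images and images containing NaN/Inf voxels are
#' rejected.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param subjectID optional subject identifier; defaults to the file stem.
#' @return A [Volume3D-class].
#' @export
readVolume <- function(path, subjectID = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stopf("image in %s is not 3D (dims: %s)", path, paste(dim(arr), collapse = "x"))
  if (!all(is.finite(arr)))
    stopf("image in %s contains non-finite (NaN/Inf) voxels", path)
  pd <- attr(img, "pixdim")
  sp <- if (!is.null(pd) && length(pd) >= 3) abs(pd[1:3]) else c(1, 1, 1)
  if (is.null(subjectID)) subjectID <- sub("\\.nii(\\.gz)?$", "", basename(path))
  Volume3D(array(as.numeric(arr), dim(arr)), spacing = sp, subjectID = subjectID)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param v a [Volume3D-class].
#' @param path output `.nii` or `.nii.gz` path.
#' @param datatype storage type passed to [RNifti::writeNifti()]
#'   (default `"double"` for lossless round trips).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(v, path, datatype = "double") {
  stopifnot(is(v, "Volume3D"))
  img <- RNifti::asNifti(v@data, pixdim = v@spacing)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Partition a volume into non-overlapping cubic patch locations
#'
#' Uniformly tiles the volume with cubes of width `W` starting at the
#' origin; trailing voxels that do not fill a complete patch are dropped.
#' Returns all `prod(floor(dim / W))` locations in lexicographic (x, y, z)
#' order (x fastest), as 0-based corners of half-open cubes
#' `[origin, origin + W)`.
#'
#' @param v a [Volume3D-class] (or a 3-vector of dimensions).
#' @param W patch width in voxels; must satisfy `1 <= W <= min(dim)`.
#' @return A [PatchSet-class] of all locations.
#' @export
partitionVolume <- function(v, W) {
  shape <- if (is(v, "Volume3D")) dim(v@data) else as.integer(v)
  W <- as.integer(W)
  if (length(W) != 1L || is.na(W) || W < 1L)
    stopf("patch width W must be a single integer >= 1")
  if (W > min(shape))
    stopf("patch width W = %d exceeds the smallest volume dimension (%d)", W, min(shape))
  n <- shape %/% W
  g <- expand.grid(x = seq_len(n[1]) - 1L, y = seq_len(n[2]) - 1L, z = seq_len(n[3]) - 1L)
  origins <- as.matrix(g) * W
  storage.mode(origins) <- "integer"
  dimnames(origins) <- NULL
  new("PatchSet", origins = origins, width = W)
}

#' Extract one cubic patch from a volume
#'
#' Returns the voxels of the half-open cube `[origin, origin + W)` per axis.
#'
#' @param v a [Volume3D-class].
#' @param origin integer 3-vector, 0-based patch corner.
#' @param W patch width.
#' @return A numeric `W x W x W` array.
#' @export
extractPatch <- function(v, origin, W) {
  stopifnot(is(v, "Volume3D"))
  origin <- as.integer(origin); W <- as.integer(W)
  shape <- dim(v@data)
  if (length(origin) != 3L || any(origin < 0L))
    stopf("origin must be a non-negative integer 3-vector")
  if (any(origin + W > shape))
    stopf("patch [%s] + W = %d exceeds volume shape [%s]",
          paste(origin, collapse = ","), W, paste(shape, collapse = ","))
  v@data[origin[1] + seq_len(W), origin[2] + seq_len(W), origin[3] + seq_len(W), drop = FALSE]
}

#' Read a cohort manifest
#'
#' CSV with header `subject_id,path,label` (label in \{0, 1\}); relative
#' paths are resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return data.frame with columns subject_id, path, label.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(m)))
    stopf("manifest must have columns %s", paste(need, collapse = ", "))
  if (!all(m$label %in% c(0L, 1L))) stopf("manifest labels must be 0 or 1")
  rel <- !file.exists(m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}
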