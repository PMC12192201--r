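# Synthetic two-group cohorts: every pipeline stage is testable without
# access-restricted clinical data. Each subject is a shared smooth base
# pattern (Gaussian-filtered white noise, the anatomy proxy) plus
# subject-specific i.i.d. voxel noise; group-1 subjects additionally have
# their mean intensity reduced by effect_size * noise_sd inside every
# lesion region (mimicking atrophy-driven signal loss).

#' Configuration of a synthetic cohort
#'
#' Defaults are the package's desk-scale study conditions: 48^3 volumes,
#' one 12^3 lesion aligned to the W = 12 partition grid, standardized
#' voxel-level effect d = 1.5, noise SD 0.1, blur sigma 4 voxels,
#' 60 subjects per group.
#'
#' @param shape integer(3) volume dimensions.
#' @param nPerGroup subjects per group (>= 2).
#' @param lesions list of lesions, each `list(origin = c(x, y, z), width =
#'   w)` (0-based origins, cubes fully inside the volume).
#' @param effectSize standardized mean intensity difference d inside
#'   lesions (>= 0); the group-1 reduction is `d * noiseSd`. Negative sign
#'   (intensity increase) via `lesionSign = 1`.
#' @param noiseSd voxel noise SD.
#' @param smoothness Gaussian blur sigma (voxels) of the shared base field.
#' @param lesionSign -1 (default, intensity reduction) or 1.
#' @param seed RNG seed.
#' @return Validated config list.
#' @export
syntheticCohortConfig <- function(shape = c(48, 48, 48), nPerGroup = 60,
                                  lesions = list(list(origin = c(24, 24, 24), width = 12)),
                                  effectSize = 1.5, noiseSd = 0.1,
                                  smoothness = 4, lesionSign = -1, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) stopf("shape must be 3 positive dimensions")
  if (nPerGroup < 2) stopf("need at least 2 subjects per group")
  if (effectSize < 0) stopf("effectSize must be >= 0")
  if (noiseSd <= 0) stopf("noiseSd must be > 0")
  for (L in lesions) {
    o <- as.integer(L$origin); w <- as.integer(L$width)
    if (length(o) != 3L || any(o < 0L) || any(o + w > shape))
      stopf("lesion at [%s] width %d lies outside the volume",
            paste(L$origin, collapse = ","), L$width)
  }
  if (!lesionSign %in% c(-1, 1)) stopf("lesionSign must be -1 or 1")
  list(shape = shape, nPerGroup = as.integer(nPerGroup), lesions = lesions,
       effectSize = effectSize, noiseSd = noiseSd, smoothness = smoothness,
       lesionSign = lesionSign, seed = seed)
}

# separable Gaussian blur along each axis (truncated at 3 sigma, kernel
# renormalized at the edges via a band matrix)
gaussianBlur3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  ker <- exp(-0.5 * ((-r):r / sigma)^2)
  bandMat <- function(n) {
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      B[i, j[ok]] <- ker[ok]
      B[i, ] <- B[i, ] / sum(B[i, ])
    }
    B
  }
  d <- dim(x)
  # axis 1
  x <- array(bandMat(d[1]) %*% matrix(x, d[1]), d)
  # axis 2
  x <- aperm(array(bandMat(d[2]) %*% matrix(aperm(x, c(2, 1, 3)), d[2]), d[c(2, 1, 3)]),
             c(2, 1, 3))
  # axis 3
  x <- aperm(array(bandMat(d[3]) %*% matrix(aperm(x, c(3, 1, 2)), d[3]), d[c(3, 1, 2)]),
             c(2, 3, 1))
  x
}

#' Generate a synthetic two-group cohort
#'
#' Fully reproducible from `cfg$seed`. Group 0 subjects are base + noise;
#' group 1 subjects additionally have their intensity shifted by
#' `lesionSign * effectSize * noiseSd` inside every lesion cube, so the
#' standardized voxel-level effect inside lesions is `effectSize`.
#'
#' @param cfg a [syntheticCohortConfig()] list.
#' @return list(volumes = list of [Volume3D-class], labels = integer
#'   vector, groundTruth = [PatchSet-class] of the lesion cubes).
#' @export
generateCohort <- function(cfg) {
  withSeed(cfg$seed, {
    base <- array(rnorm(prod(cfg$shape)), cfg$shape)
    base <- gaussianBlur3d(base, cfg$smoothness)
    base <- (base - mean(base)) / sd(base)
    shift <- array(0, cfg$shape)
    for (L in cfg$lesions) {
      o <- as.integer(L$origin); w <- as.integer(L$width)
      shift[o[1] + seq_len(w), o[2] + seq_len(w), o[3] + seq_len(w)] <-
        cfg$lesionSign * cfg$effectSize * cfg$noiseSd
    }
    n <- 2L * cfg$nPerGroup
    labels <- rep(c(0L, 1L), each = cfg$nPerGroup)
    volumes <- lapply(seq_len(n), function(i) {
      noise <- array(rnorm(prod(cfg$shape), sd = cfg$noiseSd), cfg$shape)
      dat <- base + noise
      if (labels[i] == 1L) dat <- dat + shift
      Volume3D(dat, subjectID = sprintf("sub-%03d", i))
    })
    origins <- do.call(rbind, lapply(cfg$lesions, function(L) as.integer(L$origin)))
    gt <- new("PatchSet", origins = origins,
              width = as.integer(cfg$lesions[[1]]$width))
    list(volumes = volumes, labels = labels, groundTruth = gt)
  })
}

#' Write a cohort as NIfTI files plus a manifest
#'
#' Each subject is written as `<subject_id>.nii.gz`; the manifest CSV
#' (`subject_id,path,label`, paths relative to the directory) is
#' consumable by [readManifest()] and the command-line interface.
#'
#' @param volumes list of [Volume3D-class].
#' @param labels 0/1 labels of equal length.
#' @param dir writable output directory (created if missing).
#' @param groundTruth optional [PatchSet-class]; written as
#'   `ground_truth.csv` when given.
#' @return Path of the manifest, invisibly.
#' @export
writeCohort <- function(volumes, labels, dir, groundTruth = NULL) {
  if (length(volumes) != length(labels)) stopf("volumes and labels must have equal length")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0 or 1")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stopf("cannot create output directory %s", dir)
  files <- vapply(seq_along(volumes), function(i) {
    f <- sprintf("%s.nii.gz", volumes[[i]]@subjectID)
    writeVolume(volumes[[i]], file.path(dir, f))
    f
  }, character(1))
  manifest <- file.path(dir, "manifest.csv")
  write.csv(data.frame(subject_id = vapply(volumes, subjectID, character(1)),
                       path = files, label = as.integer(labels)),
            manifest, row.names = FALSE)
  if (!is.null(groundTruth)) writeBagSpec(groundTruth, file.path(dir, "ground_truth.csv"))
  invisible(manifest)
}
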