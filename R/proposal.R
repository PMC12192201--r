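#' Group-difference p-value map over patch locations
#'
#' For every location of the uniform `W`-partition, tests the group
#' difference between cohorts A and B with a two-sample Welch t-test
#' (two-sided, unequal variances). The default per-subject summary at a
#' location is the mean intensity of the patch (`statistic = "patch_mean"`);
#' `statistic = "voxel_wise"` instead tests every voxel in the patch and
#' scores the location by the mean of its voxel-level p-values.
#'
#' Locations where both groups have zero variance get p = 1 (with a
#' warning): no evidence of a difference can be extracted there.
#'
#' @param groupA,groupB lists of [Volume3D-class], >= 2 each, all sharing
#'   one shape.
#' @param W patch width.
#' @param statistic `"patch_mean"` (default) or `"voxel_wise"`.
#' @return A [PValueMap-class] with raw p-values and min-max normalized
#'   scores (see [normalizePValues()]).
#' @export
groupTTestMap <- function(groupA, groupB, W, statistic = c("patch_mean", "voxel_wise")) {
  statistic <- match.arg(statistic)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stopf("each group needs at least 2 volumes")
  vols <- c(groupA, groupB)
  shapes <- vapply(vols, function(v) dim(v@data), integer(3))
  if (any(shapes != shapes[, 1]))
    stopf("all volumes must share one shape")
  ps <- partitionVolume(vols[[1]], W)
  origins <- ps@origins
  nA <- length(groupA); nB <- length(groupB)

  patchValues <- function(vol, o) {
    as.numeric(extractPatch(vol, o, W))
  }

  praw <- numeric(nrow(origins))
  degenerate <- FALSE
  for (i in seq_len(nrow(origins))) {
    o <- origins[i, ]
    if (statistic == "patch_mean") {
      a <- vapply(groupA, function(v) mean(patchValues(v, o)), numeric(1))
      b <- vapply(groupB, function(v) mean(patchValues(v, o)), numeric(1))
      res <- welchP(matrix(a, ncol = 1), matrix(b, ncol = 1))
      if (is.na(res)) { degenerate <- TRUE; res <- 1 }
      praw[i] <- res
    } else {
      A <- vapply(groupA, function(v) patchValues(v, o), numeric(W^3))
      B <- vapply(groupB, function(v) patchValues(v, o), numeric(W^3))
      pv <- welchP(t(A), t(B))          # one p per voxel
      if (anyNA(pv)) { degenerate <- TRUE; pv[is.na(pv)] <- 1 }
      praw[i] <- mean(pv)
    }
  }
  if (degenerate)
    warning("zero within-group variance in both groups at some locations; p set to 1")
  m <- new("PValueMap", origins = origins, width = ps@width, pRaw = praw,
           pNorm = rep(NA_real_, length(praw)),
           groupSizes = c(as.integer(nA), as.integer(nB)), statistic = statistic)
  normalizePValues(m)
}

# Vectorised Welch two-sample t-test p-values from group moments.
# a, b: subjects x variables matrices. Returns NA where both group
# variances are zero (caller decides the degenerate rule). Cross-checked
# against stats::t.test in the test suite.
welchP <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, var); vb <- apply(b, 2, var)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  p[se2 == 0] <- NA_real_
  unname(p)
}

#' Min-max normalize the p-values of a map
#'
#' Each score is `(p - MIN) / (MAX - MIN)` over the map's raw p-values, so
#' the most discriminative location gets 0 and the least gets 1. If all raw
#' values are identical the scores are all defined as 0.
#'
#' @param m a [PValueMap-class].
#' @return The map with `pNorm` filled in.
#' @export
normalizePValues <- function(m) {
  stopifnot(is(m, "PValueMap"))
  p <- m@pRaw
  if (!length(p)) stopf("p-value map is empty")
  lo <- min(p); hi <- max(p)
  m@pNorm <- if (hi == lo) rep(0, length(p)) else (p - lo) / (hi - lo)
  validObject(m)
  m
}

#' Select the k most discriminative bag locations
#'
#' Returns the `k` locations with the smallest normalized scores, ascending
#' by score; ties are broken by lexicographic coordinate order. The result
#' defines every subject's bag, so patch order is identical across subjects.
#'
#' @param m a [PValueMap-class].
#' @param k bag size, `1 <= k <= nrow(patchOrigins(m))`.
#' @return A ranked [PatchSet-class] carrying the selected scores.
#' @export
selectBagLocations <- function(m, k) {
  stopifnot(is(m, "PValueMap"))
  k <- as.integer(k)
  n <- nrow(m@origins)
  if (k < 1L || k > n)
    stopf("k = %d must be between 1 and the number of locations (%d)", k, n)
  o <- m@origins
  ord <- order(m@pNorm, o[, 1], o[, 2], o[, 3])[seq_len(k)]
  new("PatchSet", origins = o[ord, , drop = FALSE], width = m@width,
      score = m@pNorm[ord])
}

#' Build one subject's patch bag
#'
#' Extracts the patches of `spec` from `v` in spec order. The label slot is
#' left unset here (bags are labelled from the manifest downstream).
#'
#' @param v a [Volume3D-class].
#' @param spec a [PatchSet-class] (typically from [selectBagLocations()]).
#' @param label optional 0/1 bag label.
#' @return A [PatchBag-class].
#' @export
buildBag <- function(v, spec, label = NA_integer_) {
  stopifnot(is(v, "Volume3D"), is(spec, "PatchSet"))
  patches <- lapply(seq_len(nrow(spec@origins)), function(i)
    extractPatch(v, spec@origins[i, ], spec@width))
  new("PatchBag", patches = patches, origins = spec@origins,
      width = spec@width, label = as.integer(label), subjectID = v@subjectID)
}

#' Serialize / read a p-value map or bag spec as CSV
#'
#' Maps are written as `ox,oy,oz,W,p_raw,p_norm`; ranked patch sets as
#' `ox,oy,oz,W,rank`.
#'
#' @param m a [PValueMap-class] or [PatchSet-class].
#' @param path CSV path.
#' @return `path` invisibly (writers); the object (readers).
#' @export
writePValueMap <- function(m, path) {
  stopifnot(is(m, "PValueMap"))
  df <- data.frame(ox = m@origins[, 1], oy = m@origins[, 2], oz = m@origins[, 3],
                   W = m@width, p_raw = m@pRaw, p_norm = m@pNorm)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePValueMap
#' @export
writeBagSpec <- function(m, path) {
  stopifnot(is(m, "PatchSet"))
  df <- data.frame(ox = m@origins[, 1], oy = m@origins[, 2], oz = m@origins[, 3],
                   W = m@width, rank = seq_len(nrow(m@origins)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePValueMap
#' @param groupSizes integer(2) recorded on the rebuilt map.
#' @export
readPValueMap <- function(path, groupSizes = c(NA_integer_, NA_integer_)) {
  df <- read.csv(path)
  o <- as.matrix(df[, c("ox", "oy", "oz")]); storage.mode(o) <- "integer"
  dimnames(o) <- NULL
  new("PValueMap", origins = o, width = as.integer(df$W[1]),
      pRaw = df$p_raw, pNorm = df$p_norm,
      groupSizes = as.integer(groupSizes), statistic = "patch_mean")
}

#' @rdname writePValueMap
#' @export
readBagSpec <- function(path) {
  df <- read.csv(path)
  df <- df[order(df$rank), ]
  o <- as.matrix(df[, c("ox", "oy", "oz")]); storage.mode(o) <- "integer"
  dimnames(o) <- NULL
  new("PatchSet", origins = o, width = as.integer(df$W[1]))
}
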