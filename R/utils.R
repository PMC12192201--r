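stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic entry points route through
# this so that runs are reproducible from a single integer.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# sigmoid; plogis without the distribution-function ceremony
sigmoid <- function(x) 1 / (1 + exp(-x))

clampBox <- function(x, lb, ub) pmin(pmax(x, lb), ub)

#' Accessors for foamidl S4 containers
#'
#' Small accessor family: `volData()`, `voxelSpacing()`, `subjectID()`
#' (Volume3D); `patchOrigins()`, `patchWidth()`, `locationScores()`
#' (PatchSet, PValueMap, PatchBag); `rawPValues()`, `normScores()`
#' (PValueMap); `bagPatches()`, `bagLabel()` (PatchBag);
#' `modelConfig()` (BagModel).
#'
#' @param x the object.
#' @return The slot contents (origins as a 0-based integer matrix).
#' @name accessors
#' @aliases volData voxelSpacing subjectID patchOrigins patchWidth
#'   locationScores rawPValues normScores bagPatches bagLabel modelConfig
NULL

#' @rdname accessors
#' @export
volData <- function(x) x@data
#' @rdname accessors
#' @export
voxelSpacing <- function(x) x@spacing
#' @rdname accessors
#' @export
subjectID <- function(x) x@subjectID
#' @rdname accessors
#' @export
patchOrigins <- function(x) x@origins
#' @rdname accessors
#' @export
patchWidth <- function(x) x@width
#' @rdname accessors
#' @export
locationScores <- function(x) x@score
#' @rdname accessors
#' @export
rawPValues <- function(x) x@pRaw
#' @rdname accessors
#' @export
normScores <- function(x) x@pNorm
#' @rdname accessors
#' @export
bagPatches <- function(x) x@patches
#' @rdname accessors
#' @export
bagLabel <- function(x) x@label
#' @rdname accessors
#' @export
modelConfig <- function(x) x@config
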