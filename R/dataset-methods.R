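#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
setMethod("moleculeIds", "ActivityDataset", function(x) x@ids)

#' @rdname accessors
setMethod("activities", "ActivityDataset", function(x) x@activity)

#' @rdname accessors
setMethod("moleculeSmiles", "ActivityDataset",
          function(x) if (length(x@smiles)) x@smiles else NULL)

#' @rdname accessors
setMethod("moleculeIds", "FingerprintMatrix", function(x) rownames(x@bits))

#' @rdname accessors
setMethod("fpBits", "FingerprintMatrix", function(x) x@bits)

#' @rdname accessors
setMethod("nBits", "FingerprintMatrix", function(x) ncol(x@bits))

#' @describeIn ActivityDataset number of molecules N
#' @param x an ActivityDataset
#' @export
setMethod("length", "ActivityDataset", function(x) length(x@ids))

setMethod("show", "ActivityDataset", function(object) {
  cat(sprintf("ActivityDataset with %d molecules\n", length(object@ids)))
  if (length(object@activity)) {
    cat(sprintf("  pIC50 range: [%.3g, %.3g]%s\n",
                min(object@activity), max(object@activity),
                if (isSortedByActivity(object)) " (sorted ascending)" else ""))
  }
  cat(sprintf("  structures: %s\n",
              if (length(object@smiles)) "SMILES present" else "none"))
})

setMethod("show", "FingerprintMatrix", function(object) {
  cat(sprintf("FingerprintMatrix: %d molecules x %d bits (density %.3f)\n",
              nrow(object@bits), ncol(object@bits),
              if (length(object@bits)) mean(object@bits) else NA_real_))
})

setMethod("show", "SplitSpec", function(object) {
  cat(sprintf("SplitSpec: q = %g (%s), A = %d, seed = %d%s\n",
              object@q,
              if (object@q < 1) "quantile-activity bootstrap" else "standard bootstrap",
              object@nIterations, object@seed,
              if (is.na(object@gamma)) "" else sprintf(", gamma = %g", object@gamma)))
})

setMethod("show", "ResampleDraw", function(object) {
  cat(sprintf("ResampleDraw (iteration %d): %d train (%d unique), %d test\n",
              object@iteration, length(object@train),
              length(unique(object@train)), length(object@test)))
})

#' @rdname draw-accessors
setMethod("trainIndices", "ResampleDraw", function(x) x@train)

#' @rdname draw-accessors
setMethod("testIndices", "ResampleDraw", function(x) x@test)

#' Is a dataset sorted by ascending activity?
#'
#' The quantile-activity bootstrap indexes molecules by their activity rank
#' (y1 <= y2 <= ... <= yN); this predicate checks whether the stored row
#' order already matches that convention.
#'
#' @param x an [ActivityDataset-class].
#' @return TRUE when activities are non-decreasing in row order.
#' @export
isSortedByActivity <- function(x) {
  stopifnot(is(x, "ActivityDataset"))
  !is.unsorted(x@activity)
}

#' Sort a dataset by ascending activity
#'
#' Stable sort: molecules with tied activity keep their original relative
#' order, which makes downstream index-based splits reproducible.
#'
#' @param x an [ActivityDataset-class].
#' @return A list with `dataset` (sorted) and `order` (the permutation such
#'   that `dataset` equals the input rows in that order).
#' @export
sortByActivity <- function(x) {
  stopifnot(is(x, "ActivityDataset"))
  ord <- order(x@activity, seq_along(x@activity))
  sm <- if (length(x@smiles)) x@smiles[ord] else character()
  list(dataset = ActivityDataset(x@ids[ord], x@activity[ord], sm), order = ord)
}

#' Subset a dataset by row indices
#'
#' @param x an [ActivityDataset-class].
#' @param i integer indices (repeats allowed, e.g. bootstrap multisets are
#'   *not* valid here since ids must stay unique; use plain vectors for that).
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "ActivityDataset", function(x, i, j, ..., drop = TRUE) {
  sm <- if (length(x@smiles)) x@smiles[i] else character()
  ActivityDataset(x@ids[i], x@activity[i], sm)
})

#' Subset fingerprint rows
#'
#' @param x a [FingerprintMatrix-class].
#' @param i integer or character row indices.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "FingerprintMatrix", function(x, i, j, ..., drop = TRUE) {
  FingerprintMatrix(x@bits[i, , drop = FALSE])
})

## Align a fingerprint matrix with a dataset, erroring on mismatched ids.
alignFingerprints <- function(fps, dataset) {
  stopifnot(is(fps, "FingerprintMatrix"), is(dataset, "ActivityDataset"))
  ids <- moleculeIds(dataset)
  missing <- setdiff(ids, moleculeIds(fps))
  if (length(missing))
    stop("fingerprints missing for molecule id(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5) else "")
  fps@bits[ids, , drop = FALSE]
}
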