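#' @include AllClasses.R
NULL

#' Accessors for ActivityDataset and FingerprintMatrix
#'
#' `moleculeIds()` returns molecule identifiers; `activities()` the pIC50
#' vector; `moleculeSmiles()` the SMILES (or NULL); `fpBits()` the binary
#' matrix; `nBits()` the fingerprint length P.
#'
#' @param x an [ActivityDataset-class] or [FingerprintMatrix-class] object.
#' @return The requested component.
#' @name accessors
#' @examples
#' ds <- ActivityDataset(c("a", "b"), c(5, 6))
#' moleculeIds(ds)
NULL

#' @rdname accessors
#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))

#' @rdname accessors
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))

#' @rdname accessors
#' @export
setGeneric("moleculeSmiles", function(x) standardGeneric("moleculeSmiles"))

#' @rdname accessors
#' @export
setGeneric("fpBits", function(x) standardGeneric("fpBits"))

#' @rdname accessors
#' @export
setGeneric("nBits", function(x) standardGeneric("nBits"))

#' Accessors for resampling draws
#'
#' @param x a [ResampleDraw-class] object.
#' @return Integer index vector.
#' @name draw-accessors
NULL

#' @rdname draw-accessors
#' @export
setGeneric("trainIndices", function(x) standardGeneric("trainIndices"))

#' @rdname draw-accessors
#' @export
setGeneric("testIndices", function(x) standardGeneric("testIndices"))

#' Fit a model specification to training data
#'
#' @param spec a [ModelSpec-class].
#' @param x training design matrix (rows = molecules, columns = fingerprint
#'   bits) or [FingerprintMatrix-class].
#' @param y numeric activity vector aligned with the rows of `x`.
#' @return A [FittedModel-class].
#' @export
setGeneric("fitModel", function(spec, x, y) standardGeneric("fitModel"))

#' Predict activities from a fitted model
#'
#' @param object a [FittedModel-class].
#' @param x test design matrix or [FingerprintMatrix-class]; column count
#'   must match training.
#' @return Numeric vector of predicted activities, one per row.
#' @export
setGeneric("predictActivity", function(object, x) standardGeneric("predictActivity"))

#' @rdname twoMedoids
#' @export
setGeneric("medoidIndices", function(x) standardGeneric("medoidIndices"))

#' @rdname twoMedoids
#' @export
setGeneric("clusterAssignment", function(x) standardGeneric("clusterAssignment"))

#' @rdname replicate-losses
#' @export
setGeneric("lossMatrix", function(x) standardGeneric("lossMatrix"))
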