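#' @import methods
NULL

#' ActivityDataset: molecules with pIC50 activities
#'
#' Container for a curated structure-activity dataset: one row per unique
#' molecule, with an activity on the pIC50 scale (negative log10 molar IC50;
#' higher = more potent) and, optionally, a SMILES string. This is the
#' universe every train/test split is drawn from.
#'
#' @slot ids character vector of unique molecule identifiers.
#' @slot activity numeric vector of pIC50 values, finite, aligned with `ids`.
#' @slot smiles character vector of SMILES aligned with `ids`, or length 0
#'   when structures are not available.
#'
#' @aliases ActivityDataset-class
#' @exportClass ActivityDataset
setClass("ActivityDataset",
  representation(ids = "character", activity = "numeric", smiles = "character"),
  prototype(ids = character(), activity = numeric(), smiles = character()))

setValidity("ActivityDataset", function(object) {
  msg <- character()
  if (length(object@ids) != length(object@activity))
    msg <- c(msg, "'ids' and 'activity' must have equal length")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "duplicate molecule ids")
  if (any(!nzchar(object@ids)))
    msg <- c(msg, "empty molecule id")
  if (length(object@activity) && !all(is.finite(object@activity)))
    msg <- c(msg, "activities must be finite")
  if (length(object@smiles) && length(object@smiles) != length(object@ids))
    msg <- c(msg, "'smiles' must be empty or aligned with 'ids'")
  if (length(msg)) msg else TRUE
})

#' Construct an ActivityDataset
#'
#' @param ids character vector of unique molecule identifiers.
#' @param activity numeric vector of pIC50 activities.
#' @param smiles optional character vector of SMILES strings.
#' @return An [ActivityDataset-class] object.
#' @examples
#' ds <- ActivityDataset(c("m1", "m2"), c(6.5, 7.2))
#' activities(ds)
#' @export
ActivityDataset <- function(ids, activity, smiles = character()) {
  new("ActivityDataset", ids = as.character(ids),
      activity = as.numeric(activity), smiles = as.character(smiles))
}

#' FingerprintMatrix: binary molecular design matrix
#'
#' An N x P matrix of binary molecular fingerprints (default P = 128 bits),
#' the design matrix consumed by every regression model. Rows align with the
#' molecules of a paired [ActivityDataset-class]. All-zero rows are rejected:
#' they cannot arise from a valid molecule and would make the Tanimoto
#' coefficient 0/0.
#'
#' @slot bits integer matrix with entries in \{0, 1\}; rownames are molecule ids.
#'
#' @aliases FingerprintMatrix-class
#' @exportClass FingerprintMatrix
setClass("FingerprintMatrix", representation(bits = "matrix"))

setValidity("FingerprintMatrix", function(object) {
  b <- object@bits
  msg <- character()
  if (!is.numeric(b))
    return("fingerprint bits must be numeric 0/1")
  bad <- which(!(b == 0 | b == 1), arr.ind = TRUE)
  if (nrow(bad)) {
    msg <- c(msg, sprintf("non-binary entry at row %d, column %d (value %s)",
                          bad[1, 1], bad[1, 2], format(b[bad[1, 1], bad[1, 2]])))
  }
  if (is.null(rownames(b)) && nrow(b) > 0)
    msg <- c(msg, "rownames (molecule ids) are required")
  if (!is.null(rownames(b)) && anyDuplicated(rownames(b)))
    msg <- c(msg, "duplicate molecule ids in rownames")
  if (nrow(b) > 0 && !length(msg)) {
    zero <- which(rowSums(b) == 0)
    if (length(zero))
      msg <- c(msg, sprintf("all-zero fingerprint row(s): %s",
                            paste(utils::head(rownames(b)[zero], 5), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FingerprintMatrix
#'
#' @param bits numeric/integer matrix with entries in \{0, 1\}.
#' @param ids optional character vector of molecule ids; defaults to existing
#'   rownames of `bits`.
#' @return A [FingerprintMatrix-class] object.
#' @export
FingerprintMatrix <- function(bits, ids = rownames(bits)) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  if (is.null(ids) && nrow(bits) > 0)
    stop("molecule ids are required (pass 'ids' or set rownames)")
  rownames(bits) <- ids
  if (is.null(colnames(bits)))
    colnames(bits) <- paste0("fp_", seq_len(ncol(bits)) - 1L)
  new("FingerprintMatrix", bits = bits)
}

#' SplitSpec: definition of a resampling experiment
#'
#' Bundles the parameters of one validation design: the training quantile q
#' (q = 1 selects the standard out-of-bag bootstrap; q < 1 the
#' quantile-activity bootstrap training on the bottom-q activity fraction),
#' an optional dataset-level active quantile gamma, the number of bootstrap
#' iterations A, and the master seed.
#'
#' @slot q numeric in (0, 1].
#' @slot gamma numeric in (0, 1) with gamma > q when q < 1, or NA when the
#'   active set is defined as a fraction of the test set instead.
#' @slot nIterations integer, number of bootstrap iterations (A).
#' @slot seed integer master seed; per-iteration streams are derived from it.
#'
#' @aliases SplitSpec-class
#' @exportClass SplitSpec
setClass("SplitSpec",
  representation(q = "numeric", gamma = "numeric", nIterations = "integer",
                 seed = "integer"))

setValidity("SplitSpec", function(object) {
  msg <- character()
  if (length(object@q) != 1 || is.na(object@q) || object@q <= 0 || object@q > 1)
    msg <- c(msg, "'q' must be a single value in (0, 1]")
  if (!is.na(object@gamma)) {
    if (object@gamma <= 0 || object@gamma >= 1)
      msg <- c(msg, "'gamma' must lie in (0, 1)")
    else if (object@q < 1 && object@gamma <= object@q)
      msg <- c(msg, "'gamma' must exceed 'q' when q < 1")
  }
  if (object@nIterations < 1L)
    msg <- c(msg, "'nIterations' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SplitSpec
#'
#' @param q training-quantile fraction in (0, 1]; `q = 1` means the standard
#'   out-of-bag bootstrap on the whole dataset.
#' @param nIterations number of bootstrap iterations A (default 400).
#' @param seed integer master seed.
#' @param gamma optional dataset-level active quantile (e.g. 0.9 labels the
#'   top 10% of the whole dataset as active); `NA` when actives are defined
#'   as a fraction of each test set.
#' @return A [SplitSpec-class] object.
#' @examples
#' SplitSpec(q = 0.4, nIterations = 50, seed = 7)
#' @export
SplitSpec <- function(q, nIterations = 400L, seed = 1L, gamma = NA_real_) {
  new("SplitSpec", q = as.numeric(q), gamma = as.numeric(gamma),
      nIterations = as.integer(nIterations), seed = as.integer(seed))
}

#' ResampleDraw: one realized train/test split
#'
#' One iteration of a resampling scheme: a training index multiset (bootstrap
#' draws repeat indices) and a disjoint, non-empty test index set. Indices
#' refer to rows of the dataset the draw was built from, in the caller's
#' original row order.
#'
#' @slot train integer vector of training indices (repeats allowed).
#' @slot test integer vector of test indices (each once).
#' @slot iteration integer iteration number a.
#' @slot seed integer seed of this iteration's RNG stream.
#'
#' @aliases ResampleDraw-class
#' @exportClass ResampleDraw
setClass("ResampleDraw",
  representation(train = "integer", test = "integer", iteration = "integer",
                 seed = "integer"))

setValidity("ResampleDraw", function(object) {
  msg <- character()
  if (!length(object@test))
    msg <- c(msg, "empty test set")
  if (length(intersect(unique(object@train), object@test)))
    msg <- c(msg, "train and test indices overlap")
  if (length(object@train) && min(object@train) < 1L)
    msg <- c(msg, "indices must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ReplicateLossTable: per-iteration out-of-sample losses
#'
#' An A x T matrix of realized losses, one row per resampling iteration and
#' one column per model, for a single loss function and active-set
#' definition. Iterations are paired: every model was fitted to the same
#' draw and scored on the same test set within a row. This is the unit the
#' jackknife and the probability-of-optimality score consume.
#'
#' @slot losses numeric matrix (iterations x models), colnames = model names.
#' @slot lossName one of "lmin", "lsum", "mse".
#' @slot activeFraction fraction of the test set labelled active (NA for mse
#'   or when `gamma` is used instead).
#' @slot gamma dataset-level active quantile (NA unless in dataset-quantile
#'   mode).
#' @slot spec the [SplitSpec-class] that produced the draws.
#' @slot scheme resampling scheme used ("quantile", "bootstrap" or "kfold").
#' @slot datasetId identifier of the dataset scored.
#'
#' @aliases ReplicateLossTable-class
#' @exportClass ReplicateLossTable
setClass("ReplicateLossTable",
  representation(losses = "matrix", lossName = "character",
                 activeFraction = "numeric", gamma = "numeric",
                 spec = "SplitSpec", scheme = "character",
                 datasetId = "character"))

setValidity("ReplicateLossTable", function(object) {
  msg <- character()
  if (is.null(colnames(object@losses)))
    msg <- c(msg, "loss matrix must have model names as colnames")
  if (!object@lossName %in% c("lmin", "lsum", "mse"))
    msg <- c(msg, "lossName must be one of 'lmin', 'lsum', 'mse'")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: a reference regressor with frozen hyperparameters
#'
#' The four model families carry fixed, untuned hyperparameters: linear-kernel
#' support vector regression (library defaults), random forest (100 trees,
#' maximum depth 10), ridge regression (penalty alpha = 0.1) and a small dense
#' neural network (input standardization, then dense layers of width 128 and
#' 16 with ReLU activation, linear output).
#'
#' @slot family one of "ridge", "svr_linear", "random_forest", "deep_net".
#' @slot hyperparameters named list, fixed at construction.
#' @slot seed integer seed used by stochastic learners.
#'
#' @aliases ModelSpec-class
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(family = "character", hyperparameters = "list",
                 seed = "integer"))

setValidity("ModelSpec", function(object) {
  if (!object@family %in% c("ridge", "svr_linear", "random_forest", "deep_net"))
    return("unknown model family")
  TRUE
})

#' FittedModel: a trained regressor ready to predict
#'
#' @slot spec the [ModelSpec-class] that was fitted.
#' @slot fit opaque fitted object (family-specific).
#' @slot nFeatures number of fingerprint columns seen at training.
#' @slot details family-specific extras (e.g. training activity range,
#'   standardization constants for the neural network).
#'
#' @aliases FittedModel-class
#' @exportClass FittedModel
setClass("FittedModel",
  representation(spec = "ModelSpec", fit = "ANY", nFeatures = "integer",
                 details = "list"))

#' MedoidClustering: a two-medoids partition
#'
#' Result of PAM-style two-medoids clustering on a precomputed Tanimoto
#' distance matrix, with within-cluster and global mean pairwise distances
#' used to judge how much similarity structure the clustering captured.
#'
#' @slot medoids integer vector of length 2, indices of the two medoids.
#' @slot assignment integer vector in \{1, 2\}: nearest medoid per molecule,
#'   ties to cluster 1.
#' @slot withinClusterMeanDistance numeric length 2: mean pairwise distance
#'   within each cluster (NA for singleton clusters).
#' @slot globalMeanDistance mean pairwise distance over all molecules.
#' @slot cost total distance of every molecule to its nearest medoid.
#' @slot iterations number of SWAP passes performed.
#' @slot converged FALSE when the iteration cap stopped the descent.
#'
#' @aliases MedoidClustering-class
#' @exportClass MedoidClustering
setClass("MedoidClustering",
  representation(medoids = "integer", assignment = "integer",
                 withinClusterMeanDistance = "numeric",
                 globalMeanDistance = "numeric", cost = "numeric",
                 iterations = "integer", converged = "logical"))

setValidity("MedoidClustering", function(object) {
  msg <- character()
  if (length(object@medoids) != 2L)
    msg <- c(msg, "exactly two medoids required")
  if (!all(object@assignment %in% c(1L, 2L)))
    msg <- c(msg, "assignment must be 1 or 2")
  if (length(object@assignment)) {
    if (object@assignment[object@medoids[1L]] != 1L ||
        object@assignment[object@medoids[2L]] != 2L)
      msg <- c(msg, "medoids must belong to their own clusters")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: parameters of the synthetic benchmark generator
#'
#' Defines a simulated fingerprint/activity dataset with a known functional
#' relationship y = G(x) + noise. See [generateSynthetic()] for the three
#' scenarios.
#'
#' @slot nMolecules number of molecules N.
#' @slot nBits fingerprint length P (default 128).
#' @slot scenario one of "linear", "clustered_linear", "similar_actives".
#' @slot nInformativeBits number of bits with non-zero linear weight.
#' @slot effectSizes numeric vector of true linear weights (length
#'   `nInformativeBits`).
#' @slot noiseSd standard deviation of the additive experimental noise.
#' @slot nClusters number of structural clusters (clustered scenarios).
#' @slot withinClusterFlipProb per-bit flip probability within a cluster.
#' @slot bitProb marginal probability that a background bit is set.
#' @slot clusterEffectSd standard deviation of per-cluster potency shifts
#'   (clustered scenarios).
#' @slot activeClusterBonus additive pIC50 bonus of the designated
#'   high-activity cluster ("similar_actives" only).
#' @slot activityOffset constant added so activities sit on a realistic
#'   pIC50 scale.
#' @slot seed integer seed.
#'
#' @aliases SyntheticSpec-class
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(nMolecules = "integer", nBits = "integer",
                 scenario = "character", nInformativeBits = "integer",
                 effectSizes = "numeric", noiseSd = "numeric",
                 nClusters = "integer", withinClusterFlipProb = "numeric",
                 bitProb = "numeric", clusterEffectSd = "numeric",
                 activeClusterBonus = "numeric", activityOffset = "numeric",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (!object@scenario %in% c("linear", "clustered_linear", "similar_actives"))
    msg <- c(msg, "unknown scenario")
  if (object@nInformativeBits > object@nBits)
    msg <- c(msg, "more informative bits than fingerprint bits")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (object@withinClusterFlipProb <= 0 || object@withinClusterFlipProb >= 0.5)
    msg <- c(msg, "withinClusterFlipProb must lie in (0, 0.5)")
  if (object@bitProb <= 0 || object@bitProb >= 1)
    msg <- c(msg, "bitProb must lie in (0, 1)")
  if (length(object@effectSizes) != object@nInformativeBits)
    msg <- c(msg, "effectSizes must have length nInformativeBits")
  if (object@nMolecules < 4L)
    msg <- c(msg, "at least 4 molecules required")
  if (length(msg)) msg else TRUE
})

#' ExperimentResult: replicate loss tables plus provenance
#'
#' Returned by [runExperiment()]: one [ReplicateLossTable-class] per
#' requested (loss, active-set) combination, all computed from the same
#' paired sequence of resampling draws, plus the provenance needed to rerun
#' the experiment exactly.
#'
#' @slot tables named list of [ReplicateLossTable-class] objects.
#' @slot models character vector of model names (column order of each table).
#' @slot spec the [SplitSpec-class] used.
#' @slot scheme "quantile", "bootstrap" or "kfold".
#' @slot datasetId dataset identifier.
#' @slot provenance list of seeds and sizes recorded at run time.
#'
#' @aliases ExperimentResult-class
#' @exportClass ExperimentResult
setClass("ExperimentResult",
  representation(tables = "list", models = "character", spec = "SplitSpec",
                 scheme = "character", datasetId = "character",
                 provenance = "list"))
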