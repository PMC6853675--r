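#' @include AllClasses.R
NULL

#' Construct a SyntheticSpec
#'
#' Parameters of the synthetic benchmark generator. Defaults emulate the
#' regime structure-activity data live in: sparse 128-bit fingerprints
#' (marginal bit probability 0.2), a weak linear signal on 10 informative
#' bits with weights of alternating sign, experimental noise of 1 pIC50
#' unit, and (for the clustered scenarios) molecules grouped into structural
#' clusters that carry their own potency shifts, the way chemical series do.
#'
#' @param nMolecules number of molecules N.
#' @param scenario "linear", "clustered_linear" or "similar_actives".
#' @param nBits fingerprint length P (default 128).
#' @param nInformativeBits number of bits with non-zero linear weight
#'   (default 10; these are bits 1..nInformativeBits).
#' @param effectSizes true linear weights; default alternating +1/-1.
#' @param noiseSd standard deviation of the additive noise (default 1).
#' @param nClusters number of structural clusters (default 8).
#' @param withinClusterFlipProb per-bit flip probability within a cluster
#'   (default 0.05).
#' @param bitProb marginal probability of a background bit (default 0.2).
#' @param clusterEffectSd standard deviation of per-cluster potency shifts
#'   (default 1; clustered scenarios only).
#' @param activeClusterBonus potency elevation of the designated active
#'   cluster in "similar_actives" (default 2 pIC50 units).
#' @param activityOffset constant shift placing activities on a realistic
#'   pIC50 scale (default 6).
#' @param seed integer seed.
#' @return A [SyntheticSpec-class].
#' @export
SyntheticSpec <- function(nMolecules, scenario = c("linear", "clustered_linear",
                                                   "similar_actives"),
                          nBits = 128L, nInformativeBits = 10L,
                          effectSizes = NULL, noiseSd = 1,
                          nClusters = 8L, withinClusterFlipProb = 0.05,
                          bitProb = 0.2, clusterEffectSd = 1,
                          activeClusterBonus = 2, activityOffset = 6,
                          seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(effectSizes))
    effectSizes <- rep(c(1, -1), length.out = nInformativeBits)
  new("SyntheticSpec", nMolecules = as.integer(nMolecules),
      nBits = as.integer(nBits), scenario = scenario,
      nInformativeBits = as.integer(nInformativeBits),
      effectSizes = as.numeric(effectSizes), noiseSd = as.numeric(noiseSd),
      nClusters = as.integer(nClusters),
      withinClusterFlipProb = as.numeric(withinClusterFlipProb),
      bitProb = as.numeric(bitProb),
      clusterEffectSd = as.numeric(clusterEffectSd),
      activeClusterBonus = as.numeric(activeClusterBonus),
      activityOffset = as.numeric(activityOffset), seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: scenario '%s', N = %d, P = %d, noiseSd = %g, seed = %d\n",
              object@scenario, object@nMolecules, object@nBits,
              object@noiseSd, object@seed))
})

#' Generate a synthetic fingerprint/activity dataset
#'
#' Simulates binary fingerprints and activities with known truth
#' y = G(x) + noise, in three scenarios:
#' \describe{
#'   \item{linear}{i.i.d. Bernoulli bits; G(x) = offset + w.x.}
#'   \item{clustered_linear}{molecules belong to structural clusters, each
#'     defined by a prototype fingerprint whose bits members flip with a
#'     small probability; on top of the linear signal every cluster carries
#'     a potency shift drawn from N(0, clusterEffectSd), mimicking
#'     series-specific potency.}
#'   \item{similar_actives}{as clustered_linear, but one designated cluster
#'     is the "active series": its prototype has the positive-weight
#'     informative bits set (and the negative-weight ones unset), so it sits
#'     at the top of the linear signal, and its potency shift is the fixed
#'     `activeClusterBonus`. High-activity molecules are therefore mutually
#'     similar and structurally absent from the low-activity region.}
#' }
#'
#' @param spec a [SyntheticSpec-class].
#' @return List with elements `fingerprints` ([FingerprintMatrix-class]),
#'   `dataset` ([ActivityDataset-class]) and `truth` (list: `w` full-length
#'   weight vector, `informativeBits`, `clusterLabels`, `prototypes`,
#'   `clusterEffects`, `activeCluster`, `noiselessActivity`, `seed`).
#' @examples
#' sim <- generateSynthetic(SyntheticSpec(50, "linear", noiseSd = 0, seed = 1))
#' all.equal(activities(sim$dataset), sim$truth$noiselessActivity)
#' @export
generateSynthetic <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  n <- spec@nMolecules
  p <- spec@nBits
  w <- numeric(p)
  inf <- seq_len(spec@nInformativeBits)
  w[inf] <- spec@effectSizes
  res <- withLocalSeed(spec@seed, {
    if (spec@scenario == "linear") {
      bits <- matrix(stats::rbinom(n * p, 1L, spec@bitProb), n, p)
      labels <- rep(NA_integer_, n)
      prototypes <- NULL
      effects <- NULL
      active <- NA_integer_
      shift <- numeric(n)
    } else {
      k <- spec@nClusters
      prototypes <- matrix(stats::rbinom(k * p, 1L, spec@bitProb), k, p)
      effects <- stats::rnorm(k, 0, spec@clusterEffectSd)
      active <- NA_integer_
      if (spec@scenario == "similar_actives") {
        active <- 1L
        prototypes[active, inf] <- as.integer(spec@effectSizes > 0)
        effects[active] <- spec@activeClusterBonus
      }
      labels <- sample.int(k, n, replace = TRUE)
      flips <- matrix(stats::rbinom(n * p, 1L, spec@withinClusterFlipProb), n, p)
      bits <- abs(prototypes[labels, , drop = FALSE] - flips)  # XOR
      shift <- effects[labels]
    }
    noiseless <- spec@activityOffset + drop(bits %*% w) + shift
    y <- noiseless + stats::rnorm(n, 0, spec@noiseSd)
    list(bits = bits, labels = labels, prototypes = prototypes,
         effects = effects, active = active, noiseless = noiseless, y = y)
  })
  ids <- sprintf("syn_%06d", seq_len(n))
  rownames(res$bits) <- ids
  ## an all-zero fingerprint cannot represent a molecule; resample that bit
  zero <- which(rowSums(res$bits) == 0)
  for (i in zero) res$bits[i, p] <- 1L
  list(fingerprints = FingerprintMatrix(res$bits),
       dataset = ActivityDataset(ids, res$y),
       truth = list(w = w, informativeBits = inf,
                    clusterLabels = res$labels, prototypes = res$prototypes,
                    clusterEffects = res$effects, activeCluster = res$active,
                    noiselessActivity = res$noiseless, seed = spec@seed))
}

#' Export a dataset/fingerprint pair to the pipeline's CSV formats
#'
#' Writes the curated activity CSV (`molecule_id`, `pic50`, plus `smiles`
#' when present) and the fingerprint CSV (`molecule_id`, `fp_0` ..
#' `fp_<P-1>`) that [readCuratedActivities()] and [loadFingerprintMatrix()]
#' read back; the round trip is exact.
#'
#' @param dataset an [ActivityDataset-class].
#' @param fingerprints a [FingerprintMatrix-class] aligned with `dataset`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "synthetic").
#' @return Character vector with the two file paths (activities,
#'   fingerprints), invisibly.
#' @export
exportDataset <- function(dataset, fingerprints, dir, prefix = "synthetic") {
  stopifnot(is(dataset, "ActivityDataset"), is(fingerprints, "FingerprintMatrix"))
  bits <- alignFingerprints(fingerprints, dataset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  actPath <- file.path(dir, paste0(prefix, "_activities.csv"))
  fpPath <- file.path(dir, paste0(prefix, "_fingerprints.csv"))
  writeCuratedActivities(dataset, actPath)
  writeFingerprintMatrix(FingerprintMatrix(bits), fpPath)
  invisible(c(activities = actPath, fingerprints = fpPath))
}
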