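#' @include AllClasses.R AllGenerics.R
NULL

#' Tanimoto (Jaccard) coefficient of two binary fingerprints
#'
#' Number of substructure bits shared by both molecules over the bits set in
#' either: `sum(x1 & x2) / sum(x1 | x2)`. When both vectors are all-zero the
#' coefficient is defined as 1 (identical empty substructure sets), with a
#' message, since the ratio is otherwise 0/0.
#'
#' @param x1,x2 binary vectors of equal length.
#' @return Similarity in \[0, 1\]; `1 - tanimotoSimilarity()` is the Jaccard
#'   distance, a metric.
#' @examples
#' tanimotoSimilarity(c(1, 1, 0, 1), c(1, 0, 1, 1))  # 0.5
#' @export
tanimotoSimilarity <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("fingerprint lengths differ")
  if (!all(x1 %in% c(0, 1)) || !all(x2 %in% c(0, 1)))
    stop("fingerprints must be binary")
  union <- sum(x1 | x2)
  if (union == 0) {
    message("both fingerprints all-zero; Tanimoto defined as 1 by convention")
    return(1)
  }
  sum(x1 & x2) / union
}

#' Pairwise Tanimoto distance matrix
#'
#' Computes `d[i, j] = 1 - tanimoto(x_i, x_j)` for all molecule pairs via
#' matrix cross-products (intersection counts) and row sums (union counts).
#' Symmetric with a zero diagonal.
#'
#' @param fps a [FingerprintMatrix-class] with at least 2 rows (all-zero
#'   rows are already rejected at construction).
#' @return N x N numeric distance matrix with molecule ids as dimnames.
#' @export
pairwiseDistanceMatrix <- function(fps) {
  stopifnot(is(fps, "FingerprintMatrix"))
  b <- fpBits(fps)
  if (nrow(b) < 2L) stop("at least 2 molecules required")
  storage.mode(b) <- "double"
  inter <- tcrossprod(b)
  rs <- rowSums(b)
  union <- outer(rs, rs, "+") - inter
  d <- 1 - inter / union
  diag(d) <- 0
  dimnames(d) <- list(rownames(b), rownames(b))
  d
}

## Total cost of a medoid pair: every point contributes its distance to the
## nearer medoid.
medoidCost <- function(d, m1, m2) sum(pmin(d[, m1], d[, m2]))

meanPairwise <- function(d, idx) {
  if (length(idx) < 2L) return(NA_real_)
  sub <- d[idx, idx, drop = FALSE]
  sum(sub[upper.tri(sub)]) / choose(length(idx), 2)
}

## Alternate best-improvement SWAP passes from a starting medoid pair until
## no swap lowers the cost or the pass budget is exhausted.
swapDescent <- function(d, m1, m2, maxIter) {
  cost <- medoidCost(d, m1, m2)
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    keep1 <- colSums(pmin(d, d[, m1]))  # replace m2 by candidate h
    keep2 <- colSums(pmin(d, d[, m2]))  # replace m1 by candidate h
    keep1[c(m1, m2)] <- Inf
    keep2[c(m1, m2)] <- Inf
    best1 <- which.min(keep1)
    best2 <- which.min(keep2)
    if (min(keep1[best1], keep2[best2]) >= cost) {
      converged <- TRUE
      break
    }
    if (keep1[best1] <= keep2[best2]) {
      m2 <- best1; cost <- keep1[best1]
    } else {
      m1 <- best2; cost <- keep2[best2]
    }
  }
  list(m1 = m1, m2 = m2, cost = cost, iter = iter, converged = converged)
}

#' Two-medoids (PAM) clustering on a precomputed distance matrix
#'
#' Partitioning around medoids for k = 2: a greedy BUILD phase picks the
#' point of least total distance and then the partner that most reduces the
#' total cost; SWAP passes replace one medoid with the non-medoid that
#' lowers the cost most, until no swap improves it or `maxIter` passes are
#' exhausted (then the current state is returned with a warning). Because
#' the swap descent can stall in a local optimum, `nStart` additional
#' descents from seeded random medoid pairs are run and the best solution
#' kept; given the seed the whole procedure is deterministic. Cost ties are
#' resolved toward the lower index, and molecules equidistant from both
#' medoids join cluster 1.
#'
#' @param distances symmetric N x N distance matrix (N >= 4) with zero
#'   diagonal, e.g. from [pairwiseDistanceMatrix()].
#' @param maxIter maximum number of SWAP passes per start (default 100).
#' @param seed seed for the random restarts.
#' @param nStart number of random restarts on top of the greedy BUILD
#'   initialization (default 4).
#' @return A [MedoidClustering-class].
#' @export
twoMedoids <- function(distances, maxIter = 100L, seed = 1L, nStart = 4L) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n < 4L) stop("at least 4 points required")
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0))
    stop("'distances' must be symmetric with a zero diagonal")
  ## BUILD: cheapest single medoid, then the partner minimizing joint cost
  m1 <- which.min(colSums(d))
  costs <- colSums(pmin(d, d[, m1]))
  costs[m1] <- Inf
  starts <- list(c(m1, which.min(costs)))
  if (nStart > 0L) {
    extra <- withLocalSeed(seed, replicate(nStart, sample.int(n, 2L),
                                           simplify = FALSE))
    starts <- c(starts, extra)
  }
  best <- NULL
  for (st in starts) {
    res <- swapDescent(d, st[1L], st[2L], maxIter)
    if (is.null(best) || res$cost < best$cost - 1e-12) best <- res
  }
  m1 <- best$m1; m2 <- best$m2; cost <- best$cost
  iter <- best$iter; converged <- best$converged
  if (!converged)
    warning("two-medoids SWAP stopped at maxIter without converging")
  ## canonical order and assignment (ties to cluster 1)
  med <- sort(c(m1, m2))
  assign <- ifelse(d[, med[1]] <= d[, med[2]], 1L, 2L)
  new("MedoidClustering", medoids = as.integer(med),
      assignment = as.integer(assign),
      withinClusterMeanDistance = c(meanPairwise(d, which(assign == 1L)),
                                    meanPairwise(d, which(assign == 2L))),
      globalMeanDistance = meanPairwise(d, seq_len(n)),
      cost = cost, iterations = iter, converged = converged)
}

#' @rdname twoMedoids
#' @param x a [MedoidClustering-class].
setMethod("medoidIndices", "MedoidClustering", function(x) x@medoids)

#' @rdname twoMedoids
setMethod("clusterAssignment", "MedoidClustering", function(x) x@assignment)

setMethod("show", "MedoidClustering", function(object) {
  sizes <- tabulate(object@assignment, 2L)
  cat(sprintf(paste0("MedoidClustering: medoids (%d, %d), sizes (%d, %d), ",
                     "cost %.4f after %d pass(es)\n"),
              object@medoids[1], object@medoids[2], sizes[1], sizes[2],
              object@cost, object@iterations))
  cat(sprintf("  within-cluster mean distances: %.4f, %.4f (global %.4f)\n",
              object@withinClusterMeanDistance[1],
              object@withinClusterMeanDistance[2], object@globalMeanDistance))
})

#' Dissimilarity of a molecule subset relative to the whole set
#'
#' Compares the mean pairwise Tanimoto distance within a subset (for
#' example, a two-medoids cluster, or all molecules above an activity
#' quantile) with the global mean pairwise distance. The relative reduction
#' `1 - subset/global` measures how much more mutually similar the subset
#' is than the dataset at large.
#'
#' @param distances symmetric distance matrix.
#' @param subset integer (or logical) indices of the subset, at least 2.
#' @return List with `subsetMeanPairwise`, `globalMeanPairwise` and
#'   `relativeReduction`.
#' @export
dissimilaritySummary <- function(distances, subset) {
  d <- as.matrix(distances)
  if (is.logical(subset)) subset <- which(subset)
  if (length(subset) < 2L) stop("subset must contain at least 2 molecules")
  if (anyDuplicated(subset)) stop("duplicate subset indices")
  sub <- meanPairwise(d, subset)
  glob <- meanPairwise(d, seq_len(nrow(d)))
  list(subsetMeanPairwise = sub, globalMeanPairwise = glob,
       relativeReduction = 1 - sub / glob)
}
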