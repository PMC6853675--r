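#' @include AllClasses.R
NULL

#' Assign prediction ranks to test molecules
#'
#' Converts predicted activities to ranks using the screening convention:
#' rank 0 is the molecule with the highest predicted activity, rank
#' Ntest - 1 the lowest. Ties are broken uniformly at random under
#' `tieSeed`; a deterministic index-based tie-break would leak the input
#' ordering and bias constant-prediction models towards loss 0 or 1.
#'
#' @param predicted numeric vector of predicted activities (finite).
#' @param tieSeed integer seed for the tie-breaking permutation.
#' @return Integer vector `r` with `r[i]` the 0-based rank of molecule `i`;
#'   a permutation of `0:(length(predicted) - 1)`.
#' @examples
#' assignRanks(c(0.1, 0.9, 0.5), tieSeed = 1)  # 2 0 1
#' @export
assignRanks <- function(predicted, tieSeed = 1L) {
  if (!length(predicted)) stop("empty prediction vector")
  if (any(!is.finite(predicted))) stop("predictions must be finite (no NaN/NA/Inf)")
  tiebreak <- withLocalSeed(tieSeed, stats::runif(length(predicted)))
  ord <- order(-predicted, tiebreak)
  ranks <- integer(length(predicted))
  ranks[ord] <- seq_along(predicted) - 1L
  ranks
}

#' Indices of the active molecules in a test set
#'
#' The actives are the `nActive` test molecules of highest *true* activity.
#' Exactly `nActive` molecules are returned after a stable sort; when the
#' activity threshold splits tied values a warning flags the dataset, since
#' the active set is then one consistent choice among several.
#'
#' @param trueActivity numeric vector of observed test-set activities.
#' @param nActive number of actives (1 <= nActive < length(trueActivity)).
#' @return Integer vector of `nActive` indices into `trueActivity`.
#' @export
activeIndices <- function(trueActivity, nActive) {
  n <- length(trueActivity)
  nActive <- assertCount(nActive, "nActive")
  if (nActive >= n) stop("'nActive' must be smaller than the test-set size")
  ord <- order(-trueActivity, seq_len(n))
  act <- ord[seq_len(nActive)]
  threshold <- trueActivity[ord[nActive]]
  if (trueActivity[ord[nActive + 1L]] == threshold)
    warning("activity threshold splits tied values; active set chosen by stable order")
  act
}

#' Number of actives from a test-set fraction
#'
#' Labelling a fraction f of the test data as active means
#' `ceiling(f * nTest)` molecules, so even "1% active" always names at least
#' one molecule.
#'
#' @param nTest test-set size.
#' @param fraction fraction of the test set labelled active, in (0, 1).
#' @return Integer count of actives.
#' @export
nActiveFromFraction <- function(nTest, fraction) {
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must lie in (0, 1)")
  max(1L, as.integer(ceiling(fraction * nTest)))
}

checkLossArgs <- function(ranksOfActives, nTest, nActive) {
  nTest <- assertCount(nTest, "nTest", 2L)
  nActive <- assertCount(nActive, "nActive")
  if (nTest <= nActive)
    stop("'nTest' must exceed 'nActive'")
  if (length(ranksOfActives) != nActive)
    stop("expected ", nActive, " active ranks, got ", length(ranksOfActives))
  if (anyDuplicated(ranksOfActives) || any(ranksOfActives < 0) ||
      any(ranksOfActives > nTest - 1L))
    stop("active ranks must be distinct values in 0..nTest-1")
  list(nTest = nTest, nActive = nActive)
}

#' Minimum active-rank loss
#'
#' Normalized rank of the best-ranked active molecule:
#' `min(ranksOfActives) / (nTest - nActive)`. It is 0 when any active is
#' ranked top of the test set and 1 when all actives occupy the last
#' `nActive` ranks; the ranking of inactives below the best active is
#' irrelevant. This is the loss of a screening campaign that stops at the
#' first confirmed active, with each tested inactive costing one unit.
#'
#' @param ranksOfActives 0-based predicted ranks of the active molecules.
#' @param nTest test-set size Ntest.
#' @param nActive number of actives.
#' @return A value in \[0, 1\].
#' @examples
#' lossMin(c(3, 7), nTest = 10, nActive = 2)  # 3/8
#' @export
lossMin <- function(ranksOfActives, nTest, nActive) {
  a <- checkLossArgs(ranksOfActives, nTest, nActive)
  min(ranksOfActives) / (a$nTest - a$nActive)
}

#' Sum active-rank loss
#'
#' Normalized sum of all active ranks, penalizing sub-optimal placement of
#' every active:
#' `(sum(ranksOfActives) - nActive*(nActive-1)/2) / denom`.
#' The minimum of the raw sum is `nActive*(nActive-1)/2` (all actives in the
#' top `nActive` ranks) and its maximum is `nActive*(2*nTest - nActive - 1)/2`
#' (all actives last), so the normalizing denominator that maps the loss onto
#' \[0, 1\] — and that makes it coincide with [lossMin()] when `nActive = 1` —
#' is `nActive * (nTest - nActive)`. That is the default
#' (`variant = "corrected"`). `variant = "as_printed"` uses
#' `nActive * (nTest - nActive - 1)` instead, which overshoots 1 by the
#' factor `(nTest - nActive)/(nTest - nActive - 1)` in the worst case; it is
#' retained for comparison with sources quoting that denominator.
#'
#' @inheritParams lossMin
#' @param variant "corrected" (default, range exactly \[0, 1\]) or
#'   "as_printed".
#' @return Non-negative loss; in \[0, 1\] for the corrected variant.
#' @examples
#' lossSum(c(8, 9), nTest = 10, nActive = 2)  # 1
#' lossSum(2, nTest = 5, nActive = 1)         # 0.5, equal to lossMin
#' @export
lossSum <- function(ranksOfActives, nTest, nActive,
                    variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  a <- checkLossArgs(ranksOfActives, nTest, nActive)
  denom <- if (variant == "corrected") a$nActive * (a$nTest - a$nActive)
           else a$nActive * (a$nTest - a$nActive - 1L)
  if (denom <= 0) stop("degenerate denominator (nTest too small for this variant)")
  (sum(ranksOfActives) - a$nActive * (a$nActive - 1) / 2) / denom
}

#' Mean squared error
#'
#' @param predicted numeric vector of predictions.
#' @param observed numeric vector of observed activities, same length.
#' @return Mean of squared differences.
#' @export
mseLoss <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("'predicted' and 'observed' lengths differ")
  if (!length(predicted)) stop("empty input")
  mean((predicted - observed)^2)
}

#' Active-rank losses from raw predictions
#'
#' Convenience wrapper tying the pieces together: ranks the predictions,
#' finds the actives by true activity, and returns both active-rank losses
#' plus the mean squared error for one model on one test set.
#'
#' @param predicted predicted activities for the test set.
#' @param trueActivity observed activities for the test set.
#' @param nActive number of actives.
#' @param tieSeed seed for prediction tie-breaking.
#' @param variant `lossSum` denominator variant.
#' @return Named numeric vector with elements `lmin`, `lsum`, `mse`.
#' @export
activeRankLosses <- function(predicted, trueActivity, nActive, tieSeed = 1L,
                             variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  if (length(predicted) != length(trueActivity))
    stop("'predicted' and 'trueActivity' lengths differ")
  ranks <- assignRanks(predicted, tieSeed)
  act <- activeIndices(trueActivity, nActive)
  c(lmin = lossMin(ranks[act], length(predicted), nActive),
    lsum = lossSum(ranks[act], length(predicted), nActive, variant),
    mse = mseLoss(predicted, trueActivity))
}
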