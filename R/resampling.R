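#' @include AllClasses.R utils.R
NULL

#' Quantile-activity bootstrap draws
#'
#' Builds the extrapolation-validation splits: let Nq = floor(N * q) be the
#' number of molecules in the bottom-q activity fraction. Each of the A
#' iterations trains on Nq indices sampled *with replacement* from those
#' bottom-Nq molecules; the test set is the N - Nq molecules of higher
#' activity and is identical across iterations. Molecules tied exactly at
#' the quantile threshold are assigned by their position in the stable
#' activity sort (first Nq positions train), so set sizes are always exactly
#' Nq and N - Nq; a warning is emitted when a tie straddles the boundary.
#'
#' Returned indices refer to the dataset's *original* row order (sorting
#' happens internally), so they can be used directly to subset the caller's
#' fingerprint matrix.
#'
#' @param dataset an [ActivityDataset-class].
#' @param spec a [SplitSpec-class] with q < 1.
#' @return List of `nIterations(spec)` [ResampleDraw-class] objects.
#' @examples
#' ds <- ActivityDataset(paste0("m", 1:50), sort(rnorm(50, 6)))
#' draws <- quantileActivityBootstrap(ds, SplitSpec(0.4, nIterations = 3, seed = 1))
#' length(testIndices(draws[[1]]))  # 30
#' @export
quantileActivityBootstrap <- function(dataset, spec) {
  stopifnot(is(dataset, "ActivityDataset"), is(spec, "SplitSpec"))
  if (spec@q >= 1)
    stop("quantile-activity bootstrap requires q < 1; use standardBootstrap() for q = 1")
  n <- length(dataset)
  nq <- as.integer(floor(n * spec@q))
  if (nq < 2L || n - nq < 2L)
    stop(sprintf("degenerate split: Nq = %d, N - Nq = %d (need both >= 2)", nq, n - nq))
  srt <- sortByActivity(dataset)
  y <- activities(srt$dataset)
  if (y[nq] == y[nq + 1L])
    warning("activities tied across the quantile boundary; split resolved by sorted index")
  trainPool <- srt$order[seq_len(nq)]        # original-order indices, bottom q
  testIdx <- srt$order[(nq + 1L):n]          # fixed extrapolation test set
  seeds <- iterationSeeds(spec@seed, spec@nIterations)
  lapply(seq_len(spec@nIterations), function(a) {
    tr <- withLocalSeed(seeds[a], sample(trainPool, nq, replace = TRUE))
    new("ResampleDraw", train = as.integer(tr), test = as.integer(testIdx),
        iteration = as.integer(a), seed = as.integer(seeds[a]))
  })
}

#' Standard out-of-bag bootstrap draws
#'
#' Each iteration trains on N indices sampled with replacement from the
#' whole dataset and tests on the out-of-bag molecules (those never drawn;
#' on average a fraction (1 - 1/N)^N, about e^-1, of the data). Draws whose
#' out-of-bag set is empty are rejected and redrawn, with a message.
#'
#' @param dataset an [ActivityDataset-class] with at least 5 molecules.
#' @param nIterations number of bootstrap iterations.
#' @param seed integer master seed.
#' @return List of [ResampleDraw-class] objects.
#' @export
standardBootstrap <- function(dataset, nIterations = 400L, seed = 1L) {
  stopifnot(is(dataset, "ActivityDataset"))
  n <- length(dataset)
  if (n < 5L) stop("standard bootstrap requires at least 5 molecules")
  nIterations <- assertCount(nIterations, "nIterations")
  seeds <- iterationSeeds(seed, nIterations)
  lapply(seq_len(nIterations), function(a) {
    draw <- withLocalSeed(seeds[a], {
      repeat {
        tr <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), tr)
        if (length(oob)) break
        message(sprintf("iteration %d: empty out-of-bag set, redrawing", a))
      }
      list(tr = tr, oob = oob)
    })
    new("ResampleDraw", train = as.integer(draw$tr),
        test = as.integer(sort(draw$oob)),
        iteration = as.integer(a), seed = as.integer(seeds[a]))
  })
}

#' K-fold cross-validation partition
#'
#' Random partition into k folds of near-equal size (sizes differ by at most
#' one, larger folds first); draw i trains on the union of the other folds
#' (each index once) and tests on fold i.
#'
#' @param dataset an [ActivityDataset-class].
#' @param k number of folds (default 5, i.e. 80% train / 20% test).
#' @param seed integer seed for the random partition.
#' @return List of k [ResampleDraw-class] objects.
#' @export
kfoldPartition <- function(dataset, k = 5L, seed = 1L) {
  stopifnot(is(dataset, "ActivityDataset"))
  n <- length(dataset)
  k <- assertCount(k, "k", 2L)
  if (n < k) stop("fewer molecules than folds")
  perm <- withLocalSeed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  stopsAt <- cumsum(sizes)
  startsAt <- c(1L, utils::head(stopsAt, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    test <- perm[startsAt[i]:stopsAt[i]]
    new("ResampleDraw", train = as.integer(perm[-(startsAt[i]:stopsAt[i])]),
        test = as.integer(sort(test)), iteration = as.integer(i),
        seed = as.integer(seed))
  })
}

#' Serialize resampling draws to JSON lines
#'
#' One JSON object per line (iteration, seed, train with multiplicity, test),
#' enough to re-run an experiment on exactly the same splits.
#'
#' @param draws list of [ResampleDraw-class] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDrawsJSONL <- function(draws, path) {
  lines <- vapply(draws, function(d) {
    jsonlite::toJSON(list(iteration = d@iteration, seed = d@seed,
                          train = d@train, test = d@test),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeDrawsJSONL
#' @export
readDrawsJSONL <- function(path) {
  lapply(readLines(path), function(line) {
    x <- jsonlite::fromJSON(line)
    new("ResampleDraw", train = as.integer(x$train), test = as.integer(x$test),
        iteration = as.integer(x$iteration), seed = as.integer(x$seed))
  })
}
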