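#' @include AllClasses.R AllGenerics.R losses.R resampling.R models.R
NULL

#' Run a full validation experiment
#'
#' Fits every model to every resampling draw and scores the paired
#' out-of-sample predictions with the requested losses. The resampling
#' scheme follows the split specification: `q < 1` runs the
#' quantile-activity bootstrap (train on the bottom-q activity fraction,
#' test on the rest), `q = 1` the standard out-of-bag bootstrap;
#' `scheme = "kfold"` runs k-fold cross-validation instead (rows of the
#' loss tables are then folds and active-rank losses are computed within
#' each fold's test set). Within an iteration all models see the same draw,
#' so rows are paired across models; a model failure at an iteration is
#' recorded as `NA` and logged, and summaries drop such iterations
#' complete-case.
#'
#' The active set of each test set holds the molecules of highest observed
#' activity: either a fraction of the test set (`activeFractions`, default
#' 10%, 5% and 1%, counts rounded up so at least one molecule is active) or
#' a dataset-level quantile (`gamma` of the split spec, giving
#' `floor(N * (1 - gamma))` actives).
#'
#' @param dataset an [ActivityDataset-class].
#' @param fingerprints a [FingerprintMatrix-class] covering the dataset's
#'   molecule ids.
#' @param models list of [ModelSpec-class] objects (or character family
#'   names); names become the loss-table columns.
#' @param split a [SplitSpec-class].
#' @param losses subset of `c("lmin", "lsum", "mse")`.
#' @param activeFractions test-set fractions labelled active for the
#'   active-rank losses; ignored when the split spec carries a `gamma`.
#' @param scheme `"auto"` (bootstrap flavour chosen by `q`) or `"kfold"`.
#' @param k number of folds when `scheme = "kfold"`.
#' @param lossSumVariant denominator variant passed to [lossSum()].
#' @param datasetId identifier stored in the result tables.
#' @return An [ExperimentResult-class]; its `tables` are named
#'   `"mse"` and `"<loss>_f<fraction>"` (or `"<loss>_g<gamma>"`).
#' @examples
#' sim <- generateSynthetic(SyntheticSpec(60, "linear", seed = 1))
#' res <- runExperiment(sim$dataset, sim$fingerprints,
#'                      models = list(ridge = ModelSpec("ridge")),
#'                      split = SplitSpec(0.5, nIterations = 3, seed = 1),
#'                      activeFractions = 0.1)
#' summarizeExperiment(res)
#' @export
runExperiment <- function(dataset, fingerprints, models,
                          split = SplitSpec(0.4),
                          losses = c("lmin", "lsum", "mse"),
                          activeFractions = c(0.1, 0.05, 0.01),
                          scheme = c("auto", "kfold"), k = 5L,
                          lossSumVariant = c("corrected", "as_printed"),
                          datasetId = "dataset") {
  stopifnot(is(dataset, "ActivityDataset"), is(split, "SplitSpec"))
  scheme <- match.arg(scheme)
  lossSumVariant <- match.arg(lossSumVariant)
  losses <- match.arg(losses, several.ok = TRUE)
  models <- lapply(models, function(m) if (is.character(m)) ModelSpec(m) else m)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- vapply(models, function(m) m@family, character(1))
  X <- alignFingerprints(fingerprints, dataset)
  y <- activities(dataset)
  n <- length(y)

  if (scheme == "kfold") {
    draws <- kfoldPartition(dataset, k = k, seed = split@seed)
    schemeName <- "kfold"
  } else if (split@q < 1) {
    draws <- quantileActivityBootstrap(dataset, split)
    schemeName <- "quantile"
  } else {
    draws <- standardBootstrap(dataset, split@nIterations, split@seed)
    schemeName <- "bootstrap"
  }
  A <- length(draws)

  useGamma <- !is.na(split@gamma)
  rankLosses <- intersect(losses, c("lmin", "lsum"))
  combos <- list()
  if (length(rankLosses)) {
    if (useGamma) {
      for (ln in rankLosses)
        combos[[sprintf("%s_g%g", ln, split@gamma)]] <-
          list(loss = ln, fraction = NA_real_, gamma = split@gamma)
    } else {
      for (ln in rankLosses) for (f in activeFractions)
        combos[[sprintf("%s_f%g", ln, f)]] <-
          list(loss = ln, fraction = f, gamma = NA_real_)
    }
  }
  if ("mse" %in% losses)
    combos[["mse"]] <- list(loss = "mse", fraction = NA_real_, gamma = NA_real_)
  if (!length(combos)) stop("no losses requested")

  tables <- lapply(combos, function(cmb)
    matrix(NA_real_, A, length(models),
           dimnames = list(NULL, names(models))))
  nGammaDataset <- if (useGamma) {
    ng <- as.integer(floor(n * (1 - split@gamma)))
    if (ng < 1L) stop("gamma leaves no active molecules")
    ng
  } else NA_integer_

  for (a in seq_len(A)) {
    draw <- draws[[a]]
    tr <- trainIndices(draw)
    te <- testIndices(draw)
    nTest <- length(te)
    yTest <- y[te]
    for (t in seq_along(models)) {
      preds <- tryCatch(
        predictActivity(fitModel(models[[t]], X[tr, , drop = FALSE], y[tr]),
                        X[te, , drop = FALSE]),
        error = function(e) {
          message(sprintf("iteration %d, model '%s' failed: %s",
                          a, names(models)[t], conditionMessage(e)))
          NULL
        })
      if (is.null(preds)) next
      tieSeed <- draw@seed + t
      ranks <- NULL
      for (cn in names(combos)) {
        cmb <- combos[[cn]]
        if (cmb$loss == "mse") {
          tables[[cn]][a, t] <- mseLoss(preds, yTest)
          next
        }
        nAct <- if (useGamma) min(nGammaDataset, nTest - 1L)
                else nActiveFromFraction(nTest, cmb$fraction)
        if (is.null(ranks)) ranks <- assignRanks(preds, tieSeed)
        act <- activeIndices(yTest, nAct)
        tables[[cn]][a, t] <-
          if (cmb$loss == "lmin") lossMin(ranks[act], nTest, nAct)
          else lossSum(ranks[act], nTest, nAct, lossSumVariant)
      }
    }
  }

  tabObjs <- lapply(names(combos), function(cn) {
    cmb <- combos[[cn]]
    new("ReplicateLossTable", losses = tables[[cn]], lossName = cmb$loss,
        activeFraction = cmb$fraction, gamma = cmb$gamma, spec = split,
        scheme = schemeName, datasetId = datasetId)
  })
  names(tabObjs) <- names(combos)
  new("ExperimentResult", tables = tabObjs, models = names(models),
      spec = split, scheme = schemeName, datasetId = datasetId,
      provenance = list(n = n, nIterations = A,
                        iterationSeeds = vapply(draws, function(d) d@seed,
                                                integer(1)),
                        lossSumVariant = lossSumVariant))
}

#' Replicate loss table accessors
#'
#' `lossMatrix()` extracts the iterations x models loss matrix.
#'
#' @param x a [ReplicateLossTable-class].
#' @name replicate-losses
NULL

#' @rdname replicate-losses
setMethod("lossMatrix", "ReplicateLossTable", function(x) x@losses)

setMethod("show", "ReplicateLossTable", function(object) {
  cat(sprintf("ReplicateLossTable '%s'%s: %d iterations x %d models (%s, %s)\n",
              object@lossName,
              if (!is.na(object@activeFraction))
                sprintf(" (active fraction %g)", object@activeFraction)
              else if (!is.na(object@gamma)) sprintf(" (gamma %g)", object@gamma)
              else "",
              nrow(object@losses), ncol(object@losses), object@scheme,
              object@datasetId))
})

setMethod("show", "ExperimentResult", function(object) {
  cat(sprintf("ExperimentResult: dataset '%s', scheme '%s', %d models, %d tables\n",
              object@datasetId, object@scheme, length(object@models),
              length(object@tables)))
  print(summarizeExperiment(object))
})

#' Jackknife standard error of a mean loss
#'
#' Delete-one jackknife standard error of the mean of the replicate losses:
#' `sqrt((A - 1)/A * sum((m_(-a) - mean(m_(-a)))^2))` over the A leave-one-out
#' means. For the mean statistic this reduces algebraically to `sd(x)/sqrt(A)`.
#'
#' @param losses numeric vector of replicate losses (length >= 2).
#' @return Non-negative standard error.
#' @examples
#' jackknifeSE(c(1, 2, 3))  # 1/sqrt(3)
#' @export
jackknifeSE <- function(losses) {
  a <- length(losses)
  if (a < 2L) stop("at least 2 replicates required")
  if (any(!is.finite(losses))) stop("losses must be finite")
  loo <- (sum(losses) - losses) / (a - 1)
  sqrt((a - 1) / a * sum((loo - mean(loo))^2))
}

#' Percentile 95% confidence interval of replicate losses
#'
#' 2.5th to 97.5th percentile of the replicate losses (type-7 interpolation,
#' the default quantile rule). Warns below 20 replicates, where percentile
#' intervals are unstable.
#'
#' @param losses numeric vector of replicate losses.
#' @return Numeric length-2 vector (lower, upper).
#' @export
lossCI95 <- function(losses) {
  if (length(losses) < 20L)
    warning("fewer than 20 replicates; percentile interval is unstable")
  stats::quantile(losses, c(0.025, 0.975), names = FALSE, type = 7)
}

#' Probability that each model is optimal
#'
#' For each iteration the model(s) attaining the lowest loss share one unit
#' of weight equally (ties split); the probability of optimality of a model
#' is its mean weight over iterations. Iterations with any missing model are
#' dropped (complete-case) to keep the pairing valid. The result sums to 1.
#'
#' @param table a [ReplicateLossTable-class] or a numeric iterations x
#'   models matrix.
#' @return Named numeric vector over models, summing to 1.
#' @examples
#' m <- cbind(m1 = c(0.1, 0.2, 0.3, 0.2), m2 = c(0.2, 0.1, 0.3, 0.4))
#' probabilityOptimal(m)  # 0.625, 0.375
#' @export
probabilityOptimal <- function(table) {
  m <- if (is(table, "ReplicateLossTable")) lossMatrix(table) else as.matrix(table)
  complete <- stats::complete.cases(m)
  if (!any(complete)) stop("no complete iterations")
  if (!all(complete))
    message(sprintf("dropping %d incomplete iteration(s)", sum(!complete)))
  m <- m[complete, , drop = FALSE]
  w <- t(apply(m, 1L, function(l) {
    win <- l == min(l)
    win / sum(win)
  }))
  p <- colMeans(w)
  names(p) <- colnames(m)
  p
}

#' Total model score across datasets
#'
#' Treating datasets as independent, the total score of a model is the sum
#' over datasets of its probabilities of optimality; scores sum to the
#' number of datasets.
#'
#' @param perDatasetP list of probability vectors from
#'   [probabilityOptimal()], identical model names in each.
#' @return Named numeric vector over models.
#' @export
totalModelScore <- function(perDatasetP) {
  if (!length(perDatasetP)) stop("no datasets")
  nm <- names(perDatasetP[[1]])
  for (p in perDatasetP) {
    if (!identical(names(p), nm))
      stop("model sets differ across datasets")
  }
  Reduce(`+`, perDatasetP)
}

#' Summarize an experiment
#'
#' Per (loss table, model): mean loss over complete iterations, jackknife
#' standard error, percentile 95% interval and probability of optimality.
#'
#' @param result an [ExperimentResult-class].
#' @return data.frame with one row per table x model.
#' @export
summarizeExperiment <- function(result) {
  stopifnot(is(result, "ExperimentResult"))
  do.call(rbind, lapply(names(result@tables), function(cn) {
    tab <- result@tables[[cn]]
    m <- lossMatrix(tab)
    complete <- stats::complete.cases(m)
    mc <- m[complete, , drop = FALSE]
    p <- suppressMessages(probabilityOptimal(mc))
    ci <- apply(mc, 2L, function(x) suppressWarnings(lossCI95(x)))
    data.frame(dataset = tab@datasetId, scheme = tab@scheme,
               loss = tab@lossName, activeFraction = tab@activeFraction,
               gamma = tab@gamma, q = tab@spec@q, model = colnames(m),
               nIterations = nrow(mc), meanLoss = colMeans(mc),
               jackknifeSE = apply(mc, 2L, jackknifeSE),
               ciLower = ci[1L, ], ciUpper = ci[2L, ], pOptimal = p,
               row.names = NULL)
  }))
}

#' Write / read an experiment result as JSON
#'
#' Serializes the replicate tables, summaries and provenance (spec, seeds,
#' package version) so a result file can be re-generated exactly from its
#' own metadata.
#'
#' @param result an [ExperimentResult-class].
#' @param path JSON file path.
#' @return `path` (write) or a list (read) with elements `summary`
#'   (data.frame) and `tables` (named list of matrices) plus provenance.
#' @export
writeExperimentResult <- function(result, path) {
  stopifnot(is(result, "ExperimentResult"))
  spec <- result@spec
  out <- list(
    datasetId = result@datasetId, scheme = result@scheme,
    models = result@models,
    spec = list(q = spec@q, gamma = spec@gamma,
                nIterations = spec@nIterations, seed = spec@seed),
    provenance = c(result@provenance,
                   list(package = "ActivityBootstrap",
                        version = as.character(utils::packageVersion("ActivityBootstrap")))),
    summary = summarizeExperiment(result),
    tables = lapply(result@tables, function(t) lossMatrix(t)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeExperimentResult
#' @export
readExperimentResult <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  x$tables <- lapply(x$tables, function(m) {
    m <- as.matrix(m)
    colnames(m) <- x$models
    m
  })
  x
}

#' Aggregate model scores over result files
#'
#' Reads experiment result JSON files (see [writeExperimentResult()]),
#' recomputes each probability of optimality from its replicate table, and
#' sums scores across files per loss table name.
#'
#' @param paths character vector of result JSON files.
#' @return data.frame with columns `table`, `model`, `totalScore`,
#'   `nDatasets`.
#' @export
scoreResults <- function(paths) {
  if (!length(paths)) stop("no result files")
  results <- lapply(paths, readExperimentResult)
  tabNames <- unique(unlist(lapply(results, function(r) names(r$tables))))
  do.call(rbind, lapply(tabNames, function(tn) {
    ps <- lapply(results, function(r) {
      if (is.null(r$tables[[tn]])) return(NULL)
      suppressMessages(probabilityOptimal(r$tables[[tn]]))
    })
    ps <- Filter(Negate(is.null), ps)
    total <- totalModelScore(ps)
    data.frame(table = tn, model = names(total), totalScore = unname(total),
               nDatasets = length(ps), row.names = NULL)
  }))
}
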