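#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a ModelSpec
#'
#' Hyperparameters are frozen per family and deliberately untuned:
#' \describe{
#'   \item{ridge}{closed-form ridge regression, penalty `alpha = 0.1` on the
#'     coefficients (intercept unpenalized).}
#'   \item{svr_linear}{epsilon support vector regression with a linear
#'     kernel, all other settings at the library defaults (cost 1,
#'     epsilon 0.1).}
#'   \item{random_forest}{100 trees, maximum depth 10, other settings at the
#'     library defaults.}
#'   \item{deep_net}{input standardization, then dense layers of width 128
#'     and 16 with ReLU activation and a linear output; trained with a
#'     mean-squared-error objective by Adam (learning rate 1e-3) for 100
#'     epochs, batch size 32. The training regimen beyond the layer sizes is
#'     a documented convention, exposed in the hyperparameter list.}
#' }
#'
#' @param family one of `"ridge"`, `"svr_linear"`, `"random_forest"`,
#'   `"deep_net"` (aliases: `"svr"`, `"rf"`, `"dnn"`).
#' @param seed integer seed for stochastic learners.
#' @return A [ModelSpec-class].
#' @examples
#' ModelSpec("ridge")
#' @export
ModelSpec <- function(family, seed = 1L) {
  family <- switch(family,
    svr = "svr_linear", rf = "random_forest", dnn = "deep_net", family)
  hp <- switch(family,
    ridge = list(alpha = 0.1),
    svr_linear = list(kernel = "linear", cost = 1, epsilon = 0.1),
    random_forest = list(num_trees = 100L, max_depth = 10L),
    deep_net = list(hidden = c(128L, 16L), activation = "relu",
                    loss = "mse", optimizer = "adam", learning_rate = 1e-3,
                    epochs = 100L, batch_size = 32L),
    stop("unknown model family: ", family))
  new("ModelSpec", family = family, hyperparameters = hp,
      seed = as.integer(seed))
}

#' Model family names understood by the package
#'
#' @return Character vector of canonical family names.
#' @export
modelFamilies <- function() c("ridge", "svr_linear", "random_forest", "deep_net")

setMethod("show", "ModelSpec", function(object) {
  hp <- object@hyperparameters
  cat(sprintf("ModelSpec: %s (%s)\n", object@family,
              paste(names(hp), vapply(hp, function(v) paste(format(v), collapse = "x"),
                                      character(1)),
                    sep = "=", collapse = ", ")))
})

setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel: %s, %d features, trained on %d molecules\n",
              object@spec@family, object@nFeatures,
              object@details$nTrain %||% NA_integer_))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

asDesign <- function(x) {
  if (is(x, "FingerprintMatrix")) x <- fpBits(x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)))
    colnames(x) <- paste0("fp_", seq_len(ncol(x)) - 1L)
  x
}

#' @rdname fitModel
setMethod("fitModel", signature(spec = "ModelSpec", x = "ANY", y = "numeric"),
  function(spec, x, y) {
    x <- asDesign(x)
    if (nrow(x) != length(y)) stop("rows of 'x' must align with 'y'")
    if (nrow(x) < 2L) stop("at least 2 training points required")
    fit <- switch(spec@family,
      ridge = fitRidge(x, y, spec@hyperparameters$alpha),
      svr_linear = if (stats::var(y) == 0) {
        ## zero-variance outcome leaves the SVR with no support vectors
        list(constant = y[1])
      } else {
        e1071::svm(x = x, y = y, type = "eps-regression",
                   kernel = "linear", scale = FALSE,
                   cost = spec@hyperparameters$cost,
                   epsilon = spec@hyperparameters$epsilon)
      },
      random_forest = ranger::ranger(x = x, y = y,
                                     num.trees = spec@hyperparameters$num_trees,
                                     max.depth = spec@hyperparameters$max_depth,
                                     seed = spec@seed, num.threads = 1L),
      deep_net = mlpFit(x, y, hidden = spec@hyperparameters$hidden,
                        epochs = spec@hyperparameters$epochs,
                        batchSize = spec@hyperparameters$batch_size,
                        learningRate = spec@hyperparameters$learning_rate,
                        seed = spec@seed))
    new("FittedModel", spec = spec, fit = fit, nFeatures = ncol(x),
        details = list(nTrain = nrow(x), trainRange = range(y)))
  })

## Ridge regression in closed form: coefficients minimize
## ||y - b0 - X w||^2 + alpha ||w||^2 with the intercept unpenalized,
## i.e. w = (Xc'Xc + alpha I)^-1 Xc' yc on centered data.
fitRidge <- function(x, y, alpha) {
  xm <- colMeans(x)
  ym <- mean(y)
  xc <- sweep(x, 2L, xm)
  w <- solve(crossprod(xc) + diag(alpha, ncol(x)), crossprod(xc, y - ym))
  list(w = drop(w), intercept = ym - sum(xm * w), alpha = alpha)
}

#' @rdname predictActivity
setMethod("predictActivity", signature(object = "FittedModel", x = "ANY"),
  function(object, x) {
    x <- asDesign(x)
    if (ncol(x) != object@nFeatures)
      stop(sprintf("feature count mismatch: model has %d, data has %d",
                   object@nFeatures, ncol(x)))
    p <- switch(object@spec@family,
      ridge = drop(x %*% object@fit$w) + object@fit$intercept,
      svr_linear = if (!is.null(object@fit$constant)) rep(object@fit$constant, nrow(x))
                   else as.numeric(stats::predict(object@fit, x)),
      random_forest = stats::predict(object@fit, data = x,
                                     num.threads = 1L)$predictions,
      deep_net = mlpPredict(object@fit, x))
    if (any(!is.finite(p))) stop("non-finite predictions")
    as.numeric(p)
  })
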