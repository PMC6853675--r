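## Small dense feed-forward network for activity regression, trained by
## mini-batch Adam on a mean-squared-error objective. Plain matrix-algebra
## implementation: two hidden ReLU layers and a linear output are small
## enough that this is fast and keeps the model fully seedable and
## dependency-free.

## He-uniform initialization for a layer of dims (in, out).
mlpInit <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(i) {
    fanIn <- sizes[i]
    lim <- sqrt(6 / fanIn)
    list(W = matrix(stats::runif(fanIn * sizes[i + 1L], -lim, lim),
                    fanIn, sizes[i + 1L]),
         b = numeric(sizes[i + 1L]))
  })
}

mlpForward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- x
  for (i in seq_along(layers)) {
    z <- sweep(acts[[i]] %*% layers[[i]]$W, 2L, layers[[i]]$b, "+")
    acts[[i + 1L]] <- if (i < length(layers)) pmax(z, 0) else z  # ReLU hidden, linear out
  }
  acts
}

mlpFit <- function(x, y, hidden = c(128L, 16L), epochs = 100L, batchSize = 32L,
                   learningRate = 1e-3, seed = 1L,
                   beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  n <- nrow(x)
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale == 0] <- 1           # constant bits carry no information
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  sizes <- c(ncol(x), hidden, 1L)
  withLocalSeed(seed, {
    layers <- mlpInit(sizes)
    m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
    v <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
    step <- 0L
    for (epoch in seq_len(epochs)) {
      perm <- sample.int(n)
      for (start in seq(1L, n, by = batchSize)) {
        idx <- perm[start:min(start + batchSize - 1L, n)]
        xb <- xs[idx, , drop = FALSE]
        yb <- y[idx]
        acts <- mlpForward(layers, xb)
        nb <- length(idx)
        ## dL/dz at the output for L = mean((pred - y)^2)
        delta <- matrix(2 * (drop(acts[[length(acts)]]) - yb) / nb, ncol = 1L)
        step <- step + 1L
        for (i in rev(seq_along(layers))) {
          gW <- crossprod(acts[[i]], delta)
          gb <- colSums(delta)
          if (i > 1L) {
            delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
          }
          ## Adam update with bias correction
          m[[i]]$W <- beta1 * m[[i]]$W + (1 - beta1) * gW
          m[[i]]$b <- beta1 * m[[i]]$b + (1 - beta1) * gb
          v[[i]]$W <- beta2 * v[[i]]$W + (1 - beta2) * gW^2
          v[[i]]$b <- beta2 * v[[i]]$b + (1 - beta2) * gb^2
          corr <- learningRate * sqrt(1 - beta2^step) / (1 - beta1^step)
          layers[[i]]$W <- layers[[i]]$W - corr * m[[i]]$W / (sqrt(v[[i]]$W) + eps)
          layers[[i]]$b <- layers[[i]]$b - corr * m[[i]]$b / (sqrt(v[[i]]$b) + eps)
        }
      }
    }
    list(layers = layers, center = center, scale = scale)
  })
}

mlpPredict <- function(fit, x) {
  xs <- sweep(sweep(x, 2L, fit$center), 2L, fit$scale, "/")
  drop(mlpForward(fit$layers, xs)[[length(fit$layers) + 1L]])
}
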