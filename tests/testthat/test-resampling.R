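test_that("quantile-activity bootstrap splits on the activity quantile", {
  set.seed(3)
  ds <- ActivityDataset(paste0("m", 1:100), stats::rnorm(100, 6))
  spec <- SplitSpec(q = 0.4, nIterations = 5, seed = 11)
  draws <- quantileActivityBootstrap(ds, spec)
  expect_length(draws, 5L)
  y <- activities(ds)
  for (d in draws) {
    expect_length(trainIndices(d), 40L)          # Nq = floor(100 * 0.4)
    expect_length(testIndices(d), 60L)
    # every training activity at or below every test activity
    expect_lte(max(y[trainIndices(d)]), min(y[testIndices(d)]))
  }
  # the extrapolation test set is identical across iterations
  tests <- unique(lapply(draws, testIndices))
  expect_length(tests, 1L)
  # training draws differ across iterations (sampling with replacement)
  expect_gt(length(unique(lapply(draws, trainIndices))), 1L)
  # determinism from the master seed
  again <- quantileActivityBootstrap(ds, spec)
  expect_identical(lapply(draws, trainIndices), lapply(again, trainIndices))
})

test_that("quantile bootstrap handles unsorted input, ties and degenerate sizes", {
  # unsorted dataset: indices still refer to the caller's row order
  ds <- ActivityDataset(c("hi", "lo", "mid", "lo2"), c(9, 1, 5, 2))
  draws <- quantileActivityBootstrap(ds, SplitSpec(0.5, nIterations = 2, seed = 1))
  expect_setequal(testIndices(draws[[1]]), c(1L, 3L))       # the two most potent
  expect_true(all(trainIndices(draws[[1]]) %in% c(2L, 4L)))
  # boundary ties resolved by index, with a warning
  tied <- ActivityDataset(paste0("t", 1:6), c(1, 2, 3, 3, 4, 5))
  expect_warning(quantileActivityBootstrap(tied, SplitSpec(0.5, 1, seed = 1)),
                 "tied")
  expect_error(quantileActivityBootstrap(ActivityDataset(c("a", "b", "c"), 1:3),
                                         SplitSpec(0.5, 1, seed = 1)),
               "degenerate")
  expect_error(quantileActivityBootstrap(ds, SplitSpec(1, 1, seed = 1)), "q < 1")
})

test_that("expected multiplicity of each bottom-q molecule is one", {
  ds <- ActivityDataset(paste0("m", 1:50), sort(stats::rnorm(50)))
  draws <- quantileActivityBootstrap(ds, SplitSpec(0.4, nIterations = 400, seed = 5))
  counts <- table(factor(unlist(lapply(draws, trainIndices)), levels = 1:20))
  mult <- as.numeric(counts) / 400
  expect_equal(mean(mult), 1, tolerance = 1e-12)  # exact: draws have size Nq
  expect_true(all(abs(mult - 1) < 0.35))          # Monte-Carlo band, sd ~ 0.05
})

test_that("standard bootstrap tests on the out-of-bag complement", {
  ds <- ActivityDataset(paste0("m", 1:60), stats::rnorm(60, 6))
  draws <- standardBootstrap(ds, nIterations = 200, seed = 9)
  for (d in draws[1:10]) {
    expect_length(trainIndices(d), 60L)
    expect_setequal(testIndices(d), setdiff(1:60, trainIndices(d)))
  }
  # OOB fraction concentrates near (1 - 1/N)^N ~ exp(-1)
  oobFrac <- mean(vapply(draws, function(d) length(testIndices(d)) / 60, numeric(1)))
  expect_equal(oobFrac, (1 - 1 / 60)^60, tolerance = 0.02)
  expect_identical(lapply(standardBootstrap(ds, 5, seed = 9), trainIndices),
                   lapply(draws[1:5], trainIndices))
  expect_error(standardBootstrap(ActivityDataset("a", 1), 10, 1), "at least 5")
})

test_that("k-fold partition is balanced, disjoint and exhaustive", {
  ds <- ActivityDataset(paste0("m", 1:11), stats::rnorm(11))
  folds <- kfoldPartition(ds, k = 5, seed = 2)
  sizes <- sort(vapply(folds, function(d) length(testIndices(d)), integer(1)),
                decreasing = TRUE)
  expect_identical(sizes, c(3L, 2L, 2L, 2L, 2L))
  expect_setequal(unlist(lapply(folds, testIndices)), 1:11)
  expect_identical(anyDuplicated(unlist(lapply(folds, testIndices))), 0L)
  for (d in folds) {
    expect_setequal(c(trainIndices(d), testIndices(d)), 1:11)
    expect_identical(anyDuplicated(trainIndices(d)), 0L)
  }
  expect_error(kfoldPartition(ActivityDataset(c("a", "b"), 1:2), k = 5, seed = 1),
               "fewer molecules")
})

test_that("draws serialize to JSON lines and back", {
  ds <- ActivityDataset(paste0("m", 1:20), stats::rnorm(20))
  draws <- standardBootstrap(ds, nIterations = 3, seed = 4)
  path <- file.path(tempdir(), "draws.jsonl")
  writeDrawsJSONL(draws, path)
  back <- readDrawsJSONL(path)
  expect_identical(lapply(back, trainIndices), lapply(draws, trainIndices))
  expect_identical(lapply(back, testIndices), lapply(draws, testIndices))
})
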