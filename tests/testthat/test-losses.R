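test_that("rank assignment follows the screening convention", {
  expect_identical(assignRanks(c(0.1, 0.9, 0.5)), c(2L, 0L, 1L))
  expect_identical(assignRanks(3.7), 0L)
  expect_error(assignRanks(c(1, NaN)), "finite")
  expect_error(assignRanks(numeric()), "empty")
  # a permutation of 0..n-1 regardless of ties
  r <- assignRanks(rep(1, 7), tieSeed = 11)
  expect_setequal(r, 0:6)
})

test_that("tie-breaking is uniform over permutations across seeds", {
  # all-equal predictions: each molecule's rank should be uniform on 0..2
  n <- 3L
  counts <- matrix(0L, n, n)
  for (s in 1:600) {
    r <- assignRanks(rep(0.5, n), tieSeed = s)
    counts[cbind(seq_len(n), r + 1L)] <- counts[cbind(seq_len(n), r + 1L)] + 1L
  }
  for (i in seq_len(n))
    expect_gt(stats::chisq.test(counts[i, ])$p.value, 1e-4)
  # and the caller's RNG stream is untouched
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(assignRanks(rep(1, 5), tieSeed = 3))
  expect_identical(stats::runif(1), before)
})

test_that("loss examples match hand-computed values", {
  expect_equal(lossMin(c(0, 20, 50, 70, 99), nTest = 100, nActive = 5), 0)
  expect_equal(lossMin(c(8, 9), nTest = 10, nActive = 2), 1)
  expect_equal(lossMin(c(3, 7), nTest = 10, nActive = 2), 0.375)
  expect_equal(lossSum(c(0, 1), nTest = 10, nActive = 2), 0)
  expect_equal(lossSum(c(8, 9), nTest = 10, nActive = 2), 1)
  expect_equal(lossSum(2, nTest = 5, nActive = 1), 0.5)
  expect_equal(lossSum(2, nTest = 5, nActive = 1), lossMin(2, 5, 1))
  expect_error(lossMin(c(1, 2), nTest = 2, nActive = 2), "exceed")
  expect_error(lossMin(c(1, 1), nTest = 5, nActive = 2), "distinct")
})

test_that("mse matches direct evaluation", {
  expect_equal(mseLoss(c(1, 2), c(1, 2)), 0)
  expect_equal(mseLoss(c(0, 0), c(1, 3)), 5)
  x <- stats::rnorm(20)
  expect_equal(mseLoss(x + 0.3, x), 0.3^2)
  expect_error(mseLoss(1:3, 1:2), "differ")
})

test_that("both losses are invariant to how inactives are ranked", {
  # permute predictions of inactive molecules among themselves; the active
  # ranks (hence both losses) must not change
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    nAct <- sample.int(n - 1L, 1)
    y <- stats::rnorm(n)
    pred <- stats::rnorm(n)
    act <- activeIndices(y, nAct)
    base <- activeRankLosses(pred, y, nAct, tieSeed = 1)
    inact <- setdiff(seq_len(n), act)
    pred2 <- pred
    pred2[inact] <- pred[inact[sample.int(length(inact))]]
    perm <- activeRankLosses(pred2, y, nAct, tieSeed = 1)
    expect_equal(perm[["lmin"]], base[["lmin"]])
    expect_equal(perm[["lsum"]], base[["lsum"]])
  }
})

test_that("demoting an active never decreases the sum loss", {
  # swap an active with the adjacent lower-ranked inactive
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(5:12, 1)
    nAct <- sample.int(n - 2L, 1)
    ranks <- sample(0:(n - 1L), nAct) # active ranks
    worst <- max(setdiff(0:(n - 1L), ranks))
    demotable <- ranks[ranks < worst]
    if (!length(demotable)) next
    pick <- sample(demotable, 1)
    nxt <- min(setdiff(0:(n - 1L), ranks)[setdiff(0:(n - 1L), ranks) > pick])
    demoted <- replace(ranks, ranks == pick, nxt)
    expect_gte(lossSum(demoted, n, nAct), lossSum(ranks, n, nAct))
    if (pick == min(ranks))
      expect_gte(lossMin(demoted, n, nAct), lossMin(ranks, n, nAct))
  }
})

test_that("the as-printed sum-loss denominator overshoots 1", {
  # all actives last: the raw sum attains its maximum, and the smaller
  # printed denominator maps it above 1 by (n - nAct)/(n - nAct - 1)
  for (n in c(5L, 10L)) for (nAct in c(1L, 3L)) {
    worst <- seq(n - nAct, n - 1L)
    expect_equal(lossSum(worst, n, nAct, variant = "as_printed"),
                 (n - nAct) / (n - nAct - 1L))
    expect_equal(lossSum(worst, n, nAct, variant = "corrected"), 1)
  }
})

test_that("active sets are the top-activity test molecules", {
  expect_identical(activeIndices(c(5, 9, 7, 8), 2), c(2L, 4L))
  expect_warning(activeIndices(c(1, 2, 2, 2), 2), "tied")
  expect_error(activeIndices(c(1, 2), 2), "smaller")
  expect_identical(nActiveFromFraction(300, 0.01), 3L)
  expect_identical(nActiveFromFraction(50, 0.01), 1L) # rounded up, never 0
  expect_identical(nActiveFromFraction(10, 0.1), 1L)
})
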