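test_that("Tanimoto coefficient counts shared over present substructures", {
  expect_equal(tanimotoSimilarity(c(1, 1, 0, 1), c(1, 0, 1, 1)), 0.5)
  expect_equal(tanimotoSimilarity(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimotoSimilarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_message(z <- tanimotoSimilarity(c(0, 0), c(0, 0)), "convention")
  expect_equal(z, 1)
  expect_error(tanimotoSimilarity(c(1, 0), c(1, 0, 1)), "lengths differ")
  expect_error(tanimotoSimilarity(c(2, 0), c(1, 0)), "binary")
})

test_that("pairwise distance matrix matches brute force and vegan", {
  set.seed(31)
  bits <- matrix(stats::rbinom(30 * 24, 1, 0.3), 30, 24)
  bits[rowSums(bits) == 0, 1] <- 1
  rownames(bits) <- paste0("m", 1:30)
  fps <- FingerprintMatrix(bits)
  d <- pairwiseDistanceMatrix(fps)
  # brute-force double loop oracle
  for (pair in list(c(1, 2), c(5, 17), c(30, 3))) {
    expect_equal(d[pair[1], pair[2]],
                 1 - tanimotoSimilarity(bits[pair[1], ], bits[pair[2], ]))
  }
  brute <- outer(1:30, 1:30, Vectorize(function(i, j)
    if (i == j) 0 else 1 - sum(bits[i, ] & bits[j, ]) / sum(bits[i, ] | bits[j, ])))
  expect_equal(unname(d), brute, tolerance = 1e-12)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 30))
  # duplicate rows are at distance zero
  dup <- FingerprintMatrix(rbind(a = bits[1, ], b = bits[1, ], c = bits[2, ]))
  expect_equal(pairwiseDistanceMatrix(dup)["a", "b"], 0)
  # independent implementation: vegan's binary Jaccard distance
  expect_equal(unname(d),
               as.matrix(vegan::vegdist(bits, method = "jaccard", binary = TRUE)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("Jaccard distance satisfies the triangle inequality", {
  set.seed(32)
  for (rep in 1:40) {
    x <- matrix(stats::rbinom(3 * 16, 1, 0.4), 3, 16)
    if (any(rowSums(x) == 0)) next
    d12 <- 1 - tanimotoSimilarity(x[1, ], x[2, ])
    d13 <- 1 - tanimotoSimilarity(x[1, ], x[3, ])
    d23 <- 1 - tanimotoSimilarity(x[2, ], x[3, ])
    expect_lte(d12, d13 + d23 + 1e-12)
    expect_lte(d13, d12 + d23 + 1e-12)
    expect_lte(d23, d12 + d13 + 1e-12)
  }
})

test_that("two-medoids separates well-separated groups perfectly", {
  bits <- rbind(matrix(rep(c(1, 1, 1, 0, 0, 0), each = 5), 5),
                matrix(rep(c(0, 0, 0, 1, 1, 1), each = 5), 5))
  rownames(bits) <- paste0("m", 1:10)
  cl <- twoMedoids(pairwiseDistanceMatrix(FingerprintMatrix(bits)))
  expect_setequal(unique(clusterAssignment(cl)[1:5]),
                  setdiff(1:2, unique(clusterAssignment(cl)[6:10])))
  expect_equal(cl@withinClusterMeanDistance, c(0, 0))
  expect_equal(cl@cost, 0)
  expect_true(cl@converged)
})

test_that("two-medoids matches exhaustive search and the PAM reference", {
  exact <- 0L
  for (s in 1:60) {
    n <- 4 + (s %% 7)
    d <- randomDistanceMatrix(n, seed = 1000 + s)
    cl <- twoMedoids(d)
    best <- exhaustiveTwoMedoidCost(d)
    expect_gte(cl@cost, best - 1e-12)      # never better than the optimum
    if (abs(cl@cost - best) < 1e-12) exact <- exact + 1L
    # cost is consistent with the returned medoids
    expect_equal(cl@cost, sum(pmin(d[, cl@medoids[1]], d[, cl@medoids[2]])))
  }
  expect_gte(exact, 57L)  # greedy BUILD+SWAP finds the optimum nearly always
  # cross-check against the cluster package's PAM on one instance
  d <- randomDistanceMatrix(12, seed = 77)
  cl <- twoMedoids(d)
  ref <- cluster::pam(stats::as.dist(d), k = 2, diss = TRUE)
  refCost <- sum(pmin(d[, ref$id.med[1]], d[, ref$id.med[2]]))
  expect_equal(cl@cost, refCost, tolerance = 1e-12)
})

test_that("dissimilarity summaries compare subset to global mean pairwise distance", {
  set.seed(33)
  bits <- matrix(stats::rbinom(40 * 32, 1, 0.3), 40, 32)
  bits[rowSums(bits) == 0, 1] <- 1
  rownames(bits) <- paste0("m", 1:40)
  d <- pairwiseDistanceMatrix(FingerprintMatrix(bits))
  # whole set: no reduction
  s <- dissimilaritySummary(d, 1:40)
  expect_equal(s$relativeReduction, 0)
  # identical fingerprints in a diverse pool: full reduction
  dup <- rbind(bits, bits[rep(1, 3), ])
  rownames(dup) <- paste0("m", 1:43)
  d2 <- pairwiseDistanceMatrix(FingerprintMatrix(dup))
  s2 <- dissimilaritySummary(d2, c(1L, 41L, 42L, 43L))
  expect_equal(s2$relativeReduction, 1)
  # brute-force pair averaging oracle
  idx <- c(2L, 9L, 17L, 33L)
  pairs <- utils::combn(idx, 2)
  expect_equal(dissimilaritySummary(d, idx)$subsetMeanPairwise,
               mean(apply(pairs, 2, function(p) d[p[1], p[2]])))
  expect_error(dissimilaritySummary(d, 3L), "at least 2")
})

test_that("all-zero fingerprints are rejected at matrix construction", {
  bits <- rbind(a = c(1, 0, 1), b = c(0, 0, 0))
  expect_error(FingerprintMatrix(bits), "all-zero")
  expect_error(FingerprintMatrix(rbind(a = c(1, 2, 0))), "non-binary")
})
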