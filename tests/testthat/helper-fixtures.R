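# Shared fixtures and brute-force oracles, built in code at test time.

# All permutations of 1..n as an n! x n matrix (row = one permutation).
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
          sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
  }))
}

# A raw activity table exercising every curation filter.
rawRecordsFixture <- function() {
  data.frame(
    molecule_id = c("m1", "m2", "m3", "m4", "m5"),
    smiles = c("CCO", "CCN", "CCC", "CCF", "CCCl"),
    standard_value = c(100, 50, 10, 200, 1),
    standard_units = c("nM", "uM", "nM", "nM", "nM"),
    standard_relation = c("=", "=", ">", "=", "="),
    target_type = "SINGLE PROTEIN",
    organism = "Homo sapiens",
    stringsAsFactors = FALSE)
}

# Random symmetric distance matrix with zero diagonal.
randomDistanceMatrix <- function(n, seed) {
  set.seed(seed)
  d <- matrix(stats::runif(n * n), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# Exhaustive two-medoids search: minimum cost over all medoid pairs.
exhaustiveTwoMedoidCost <- function(d) {
  n <- nrow(d)
  best <- Inf
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    best <- min(best, sum(pmin(d[, i], d[, j])))
  best
}

hasChemmine <- function() {
  requireNamespace("ChemmineR", quietly = TRUE) &&
    requireNamespace("ChemmineOB", quietly = TRUE)
}
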