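# Small in-code fixtures shared across test files.

# deterministic similarity matrix: symmetric, unit diagonal, entries in [0,1]
fixed_similarity <- function(labels, seed) {
  n <- length(labels)
  set.seed(seed)
  m <- matrix(runif(n * n, 0.1, 0.9), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  m
}

assoc_from_matrix <- function(A) {
  idx <- which(A == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(sm_id = rownames(A)[idx[, 1]],
                    mirna_id = colnames(A)[idx[, 2]],
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", class(out))
  out
}

# the 3 SM x 2 miRNA toy network used by the engine unit tests
toy_network <- function(A = NULL) {
  sm <- c("s1", "s2", "s3")
  mir <- c("m1", "m2")
  if (is.null(A)) {
    A <- matrix(c(1, 1, 0,
                  0, 1, 1), nrow = 3, dimnames = list(sm, mir))
  } else {
    dimnames(A) <- list(sm, mir)
  }
  build_network(assoc_from_matrix(A),
                fixed_similarity(sm, seed = 11),
                fixed_similarity(mir, seed = 12),
                mode = "dataset1")
}

# random small network for oracle-equivalence sweeps
random_network <- function(ns, nm, seed, p = 0.5) {
  set.seed(seed)
  sm <- sprintf("s%02d", seq_len(ns))
  mir <- sprintf("syn-mir-%02d", seq_len(nm))
  A <- matrix(rbinom(ns * nm, 1, p), ns, nm, dimnames = list(sm, mir))
  build_network(assoc_from_matrix(A),
                fixed_similarity(sm, seed = seed + 1000),
                fixed_similarity(mir, seed = seed + 2000),
                mode = "dataset1")
}
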