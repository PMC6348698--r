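# Independent brute-force oracle for the scoring engine: everything here is
# written with explicit element loops, no reuse of the package's vectorized
# path machinery beyond the transition matrices stored on the network.

mat_mult_loop <- function(X, Y) {
  stopifnot(ncol(X) == nrow(Y))
  Z <- matrix(0, nrow(X), ncol(Y))
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(ncol(Y))) {
      acc <- 0
      for (k in seq_len(ncol(X))) acc <- acc + X[i, k] * Y[k, j]
      Z[i, j] <- acc
    }
  }
  Z
}

oracle_transition <- function(net, from, to) {
  if (from == "SM"    && to == "miRNA") return(unname(net$Tsm))
  if (from == "miRNA" && to == "SM")    return(unname(net$Tms))
  if (from == "SM"    && to == "SM")    return(unname(net$Tss))
  net$Tmm |> unname()
}

oracle_reachable <- function(net, types) {
  R <- oracle_transition(net, types[[1]], types[[2]])
  if (length(types) > 2) {
    for (k in 2:(length(types) - 1)) {
      R <- mat_mult_loop(R, oracle_transition(net, types[[k]], types[[k + 1]]))
    }
  }
  R
}

oracle_cosine <- function(u, v) {
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

# per-pair, per-split HeteSim score for one typed path
oracle_path_score <- function(net, types) {
  l <- length(types) - 1
  ns <- nrow(net$A); nm <- ncol(net$A)
  splits <- if (l == 2) 2 else c(3, 2)
  acc <- matrix(0, ns, nm)
  for (m in splits) {
    L <- oracle_reachable(net, types[1:m])
    R <- oracle_reachable(net, rev(types[m:length(types)]))
    for (a in seq_len(ns)) {
      for (b in seq_len(nm)) {
        acc[a, b] <- acc[a, b] + oracle_cosine(L[a, ], R[b, ])
      }
    }
  }
  acc / length(splits)
}

oracle_predict <- function(net, beta) {
  S <- matrix(0, nrow(net$A), ncol(net$A))
  for (types in canonical_paths()) {
    l <- length(types) - 1
    S <- S + beta^(l - 1) * oracle_path_score(net, types)
  }
  S
}

# exhaustive pairwise Mann-Whitney statistic
oracle_auc <- function(pos, neg) {
  acc <- 0
  for (p in pos) for (n in neg) acc <- acc + (p > n) + 0.5 * (p == n)
  acc / (length(pos) * length(neg))
}
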