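#' The six canonical SM-to-miRNA relevance paths
#'
#' Enumerates, in a fixed order, every meta-path from node type SM to node
#' type miRNA with two or three relations — the exhaustive set over two node
#' types: two paths of length 2 and four of length 3.  Length-1 (the direct
#' association edge) is excluded: the aggregation sums over path lengths 2
#' and 3 only.
#'
#' @return Named list of six character vectors over `c("SM", "miRNA")`.
#' @export
canonical_paths <- function() {
  list(
    `S-S-M`   = c("SM", "SM", "miRNA"),
    `S-M-M`   = c("SM", "miRNA", "miRNA"),
    `S-S-S-M` = c("SM", "SM", "SM", "miRNA"),
    `S-S-M-M` = c("SM", "SM", "miRNA", "miRNA"),
    `S-M-M-M` = c("SM", "miRNA", "miRNA", "miRNA"),
    `S-M-S-M` = c("SM", "miRNA", "SM", "miRNA")
  )
}

# Transition matrix realizing one relation, by (source type, target type).
transition_matrix <- function(net, from, to) {
  if (from == "SM"    && to == "miRNA") return(net$Tsm)
  if (from == "miRNA" && to == "SM")    return(net$Tms)
  if (from == "SM"    && to == "SM")    return(net$Tss)
  if (from == "miRNA" && to == "miRNA") return(net$Tmm)
  stop("unknown relation ", from, " -> ", to, call. = FALSE)
}

#' Reachable probability matrix of a path segment
#'
#' The ordered left-to-right product of the transition matrices along a
#' meta-path segment; row `a` is the probability distribution over end-type
#' entities reachable from source entity `a` along the segment.
#'
#' @param mats List of transition matrices, already in path order.
#' @return Their matrix product (a single matrix is returned unchanged).
#' @export
reachable_probability <- function(mats) {
  if (length(mats) == 0L) stop("empty path segment", call. = FALSE)
  Reduce(`%*%`, mats)
}

#' Transition sequence of a reversed path segment
#'
#' The reverse of a typed segment is realized with the opposite-direction
#' transition matrices, not transposes: the reverse of an SM-to-miRNA
#' association step is `Tms` (row-normalized t(A)), and the reverse of a
#' similarity step reuses `Tss`/`Tmm` (their sources are symmetric, but the
#' type-level mapping — not transposition — is the rule).
#'
#' @param net A `hetero_network`.
#' @param types Character vector of node types, the segment to reverse.
#' @return List of transition matrices realizing the reversed segment.
#' @export
reverse_path <- function(net, types) {
  r <- rev(types)
  lapply(seq_len(length(r) - 1L), function(k) {
    transition_matrix(net, r[[k]], r[[k + 1L]])
  })
}

# Cosine of every (row of L, row of R) pair; rows live in the middle-type
# coordinate space.  Zero rows score 0 (the cosine is undefined there and a
# reach-nothing entity carries no evidence).
cosine_rows <- function(L, R) {
  num <- L %*% t(R)
  ln <- sqrt(rowSums(L * L))
  rn <- sqrt(rowSums(R * R))
  denom <- outer(ln, rn)
  out <- matrix(0, nrow(num), ncol(num), dimnames = dimnames(num))
  ok <- denom > 0
  out[ok] <- num[ok] / denom[ok]
  # nonnegative vectors: clip tiny float excursions outside [0,1]
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# Left/right reachable matrices for one split of a typed path.
# split = index of the middle node at which the path is cut.
split_matrices <- function(net, types, split, memo = NULL) {
  key_of <- function(tt) paste(tt, collapse = ">")
  fetch <- function(tt, builder) {
    if (is.null(memo)) return(builder())
    key <- key_of(tt)
    if (is.null(memo[[key]])) memo[[key]] <- builder()
    memo[[key]]
  }
  left_types <- types[1:split]
  right_types <- types[split:length(types)]
  L <- fetch(left_types, function() {
    reachable_probability(lapply(seq_len(split - 1L), function(k) {
      transition_matrix(net, types[[k]], types[[k + 1L]])
    }))
  })
  R <- fetch(rev(right_types), function() {
    reachable_probability(reverse_path(net, right_types))
  })
  list(L = L, R = R)
}

#' HeteSim relevance matrix for one meta-path
#'
#' For an even-length path the path is cut at its midpoint into a left
#' prefix `PL` and right suffix `PR`; the score of pair `(a, b)` is the
#' cosine between row `a` of the left reachable matrix `R_PL` and row `b` of
#' the reversed-suffix reachable matrix `R_PRinv`, both vectors indexed over
#' middle-type entities.  An odd-length (3-relation) path admits two uneven
#' cuts; both are scored and the entrywise mean is returned.  Pairs where
#' either vector is all-zero score 0, per cut, before averaging.
#'
#' @param net A `hetero_network`.
#' @param path One element of [canonical_paths()].
#' @param memo Optional environment caching reachable matrices across paths
#'   within one prediction run.
#' @return ns x nm matrix of per-path HeteSim scores in \[0,1\].
#' @export
hetesim_path_score <- function(net, path, memo = NULL) {
  l <- length(path) - 1L
  if (l == 2L) {
    sm <- split_matrices(net, path, split = 2L, memo = memo)
    return(cosine_rows(sm$L, sm$R))
  }
  if (l == 3L) {
    a <- split_matrices(net, path, split = 3L, memo = memo)  # PL len 2, PR len 1
    b <- split_matrices(net, path, split = 2L, memo = memo)  # PL len 1, PR len 2
    return((cosine_rows(a$L, a$R) + cosine_rows(b$L, b$R)) / 2)
  }
  stop("unsupported path length ", l, call. = FALSE)
}

#' Length-decayed aggregation of the six per-path scores
#'
#' `S = beta * (sum of the two length-2 scores) + beta^2 * (sum of the four
#' length-3 scores)`: each path's score is weighted by `beta^(l-1)` so the
#' decay factor `beta` in (0,1] punishes the longer paths.
#'
#' @param path_scores Named list of the six per-path score matrices, keyed
#'   exactly as [canonical_paths()].
#' @param beta Decay factor in (0,1].
#' @return ns x nm aggregated score matrix.
#' @export
aggregate_scores <- function(path_scores, beta = 0.5) {
  if (!(beta > 0 && beta <= 1)) stop("beta must be in (0, 1]", call. = FALSE)
  paths <- canonical_paths()
  if (!identical(sort(names(path_scores)), sort(names(paths)))) {
    stop("path_scores must hold exactly the six canonical paths", call. = FALSE)
  }
  lens <- vapply(paths, length, integer(1)) - 1L
  S <- 0
  for (nm in names(paths)) {
    S <- S + beta^(lens[[nm]] - 1L) * path_scores[[nm]]
  }
  S
}

#' Score all SM-miRNA pairs of a network
#'
#' Runs the HeteSim engine over the six canonical meta-paths and aggregates
#' with the length decay: the complete prediction step.  Deterministic; no
#' randomness anywhere in the scoring.
#'
#' @param net A `hetero_network`.
#' @param beta Decay factor in (0,1]; default 0.5.
#' @param per_path If `TRUE`, attach the six per-path matrices as attribute
#'   `"per_path"`.
#' @return ns x nm matrix of aggregated association scores, SM row names and
#'   miRNA column names.
#' @export
predict_associations <- function(net, beta = 0.5, per_path = FALSE) {
  if (!(beta > 0 && beta <= 1)) stop("beta must be in (0, 1]", call. = FALSE)
  memo <- new.env(parent = emptyenv())
  # pre-seed the similarity-only products cached at network build time
  memo[["SM>SM"]] <- net$Tss
  memo[["miRNA>miRNA"]] <- net$Tmm
  memo[["SM>SM>SM"]] <- net$Tss2
  memo[["miRNA>miRNA>miRNA"]] <- net$Tmm2
  scores <- lapply(canonical_paths(), function(p) {
    hetesim_path_score(net, p, memo = memo)
  })
  S <- aggregate_scores(scores, beta = beta)
  dimnames(S) <- list(net$sm_ids, net$mirna_ids)
  if (per_path) attr(S, "per_path") <- scores
  S
}

#' @rdname predict_associations
#' @param object A `hetero_network`.
#' @param ... Passed on to [predict_associations()].
#' @export
predict.hetero_network <- function(object, ...) {
  predict_associations(object, ...)
}
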