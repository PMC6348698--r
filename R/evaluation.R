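#' ROC curve and AUC from positive and negative score lists
#'
#' AUC is computed by the rank (Mann-Whitney) formulation with ties counted
#' half; ROC points come from sweeping every distinct score as a threshold.
#'
#' @param positives,negatives Non-empty finite numeric score vectors.
#' @return A `cv_result` list with `auc`, a `roc_points` data frame
#'   (`fpr`, `tpr`, starting at (0,0) and ending at (1,1)), and counts.
#' @export
roc_auc <- function(positives, negatives) {
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("positives and negatives must both be non-empty", call. = FALSE)
  }
  if (!all(is.finite(c(positives, negatives)))) {
    stop("scores must be finite", call. = FALSE)
  }
  np <- length(positives)
  nn <- length(negatives)
  r <- rank(c(positives, negatives), ties.method = "average")
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)

  thr <- sort(unique(c(positives, negatives)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(positives >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(negatives >= t), numeric(1))
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  structure(list(auc = auc,
                 roc_points = roc,
                 n_positive = np, n_negative = nn),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f", x$auc))
  if (!is.null(x$repeats_mean)) {
    cat(sprintf("  (mean over %d repeats; SD %.4f)",
                length(x$per_repeat_auc), x$repeats_sd))
  }
  cat("\n")
  invisible(x)
}

# Fraction of candidate scores strictly below `score`, ties at half credit:
# the per-holdout normalized rank statistic.
normalized_rank <- function(score, candidates) {
  (sum(candidates < score) + 0.5 * sum(candidates == score)) / length(candidates)
}

# ROC curve over per-holdout normalized ranks: a test sample "beats" a
# candidate fraction u; sweeping the candidate-fraction threshold gives a
# curve whose area equals mean(u).
roc_from_ranks <- function(u) {
  f <- sort(unique(c(0, 1 - u, 1)))
  tpr <- vapply(f, function(x) mean((1 - u) <= x), numeric(1))
  data.frame(fpr = f, tpr = tpr)
}

#' Leave-one-out cross-validation of the HeteSim predictor
#'
#' Each known association is held out in turn: it is masked from the network
#' (similarities stay fixed), the predictor is re-run, and the held-out
#' pair's score is ranked against a candidate population scored under the
#' same masking.  Candidates are the pairs without any known association —
#' all of them (`scope = "global"`), those sharing the held-out pair's miRNA
#' (`"local_mirna"`, ranking SMs for a fixed miRNA), or those sharing its SM
#' (`"local_sm"`, ranking miRNAs for a fixed SM).  The AUC is the mean
#' per-holdout normalized rank with ties at half credit.
#'
#' @param net A `hetero_network` with at least 2 associations.
#' @param beta Decay factor passed to [predict_associations()].
#' @param scope `"global"`, `"local_mirna"` or `"local_sm"`.
#' @param progress If `TRUE`, print a counter every 50 holdouts.
#' @return A `cv_result` with `auc`, `roc_points`, `per_sample_ranks`,
#'   `n_test`, `n_skipped` and a `config_echo` list.
#' @export
loocv <- function(net, beta = 0.5,
                  scope = c("global", "local_mirna", "local_sm"),
                  progress = FALSE) {
  scope <- match.arg(scope)
  pos <- which(net$A == 1, arr.ind = TRUE)
  if (nrow(pos) < 2L) stop("need at least 2 known associations", call. = FALSE)
  unknown <- net$A == 0  # candidate cells, fixed by the full training data
  u <- numeric(0)
  skipped <- 0L
  for (t in seq_len(nrow(pos))) {
    i <- pos[t, 1L]; j <- pos[t, 2L]
    S <- predict_associations(mask_associations(net, cbind(i, j)), beta = beta)
    cand <- switch(scope,
      global      = S[unknown],
      local_mirna = S[unknown[, j], j],
      local_sm    = S[i, unknown[i, ]]
    )
    if (length(cand) == 0L) {
      skipped <- skipped + 1L
      next
    }
    u <- c(u, normalized_rank(S[i, j], cand))
    if (progress && t %% 50L == 0L) {
      message("loocv: ", t, "/", nrow(pos), " holdouts")
    }
  }
  if (skipped > 0L) {
    warning(skipped, " holdout(s) skipped: empty candidate set", call. = FALSE)
  }
  structure(list(auc = mean(u),
                 roc_points = roc_from_ranks(u),
                 per_sample_ranks = u,
                 n_test = length(u),
                 n_skipped = skipped,
                 config_echo = list(method = "loocv", scope = scope,
                                    beta = beta, mode = net$mode)),
            class = "cv_result")
}

#' Repeated k-fold cross-validation
#'
#' Per repeat, the known associations are shuffled with a repeat-derived
#' seed (`seed + repeat index`) and split into `folds` near-equal parts
#' (sizes differ by at most 1).  Each part is masked wholesale, the
#' predictor re-run, and every held-out pair ranked against the global
#' candidate population (pairs with no known association) scored under that
#' fold's masking.  The per-repeat AUC pools the normalized ranks over all
#' folds; the result reports their mean and SD.
#'
#' @param net A `hetero_network`.
#' @param beta Decay factor.
#' @param folds Number of folds (>= 2, <= number of associations).
#' @param repeats Number of random re-partitions.
#' @param seed Master integer seed.
#' @return A `cv_result` with `auc` (mean over repeats), `repeats_mean`,
#'   `repeats_sd`, `per_repeat_auc` and `config_echo`.
#' @export
kfold_cv <- function(net, beta = 0.5, folds = 5, repeats = 100, seed = 1) {
  pos <- which(net$A == 1, arr.ind = TRUE)
  n <- nrow(pos)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (folds > n) stop("more folds than associations", call. = FALSE)
  unknown <- net$A == 0
  sizes <- rep(n %/% folds, folds) + c(rep(1L, n %% folds),
                                       rep(0L, folds - n %% folds))
  fold_id_template <- rep(seq_len(folds), times = sizes)
  aucs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    fold_id <- fold_id_template[order(stats::runif(n))]
    u <- numeric(0)
    for (f in seq_len(folds)) {
      held <- pos[fold_id == f, , drop = FALSE]
      S <- predict_associations(mask_associations(net, held), beta = beta)
      cand <- S[unknown]
      u <- c(u, vapply(seq_len(nrow(held)), function(k) {
        normalized_rank(S[held[k, 1L], held[k, 2L]], cand)
      }, numeric(1)))
    }
    aucs[[r]] <- mean(u)
  }
  structure(list(auc = mean(aucs),
                 repeats_mean = mean(aucs),
                 repeats_sd = stats::sd(aucs),
                 per_repeat_auc = aucs,
                 n_test = n,
                 config_echo = list(method = "kfold", folds = folds,
                                    repeats = repeats, seed = seed,
                                    beta = beta, mode = net$mode)),
            class = "cv_result")
}

#' Rank candidate miRNAs for a compound treated as new
#'
#' Emulates prediction for a small molecule with no known miRNA partners:
#' every known association of the investigated SM is masked, the predictor
#' re-run on the rest, and the SM's miRNAs returned ranked by descending
#' score (ties broken by miRNA id).
#'
#' @param net A `hetero_network`.
#' @param sm_id Identifier of the investigated SM (must be in the index).
#' @param beta Decay factor.
#' @param top_k Number of top miRNAs to return; `Inf` for the full ranking.
#' @return Data frame with `rank`, `mirna_id`, `score`.
#' @export
case_study_new_sm <- function(net, sm_id, beta = 0.5, top_k = 50) {
  i <- match(sm_id, net$sm_ids)
  if (is.na(i)) stop("unknown SM id: ", sm_id, call. = FALSE)
  js <- which(net$A[i, ] == 1)
  if (length(js) > 0L) {
    net <- mask_associations(net, cbind(i, js))
  }
  S <- predict_associations(net, beta = beta)
  ord <- order(-S[i, ], net$mirna_ids)
  out <- data.frame(rank = seq_along(ord),
                    mirna_id = net$mirna_ids[ord],
                    score = S[i, ord],
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  if (is.finite(top_k)) out <- utils::head(out, top_k)
  out
}
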