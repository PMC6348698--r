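#' Run the full reference evaluation protocol on user-supplied data
#'
#' Convenience driver for the published-data workflow: reads an association
#' list and the two integrated similarity matrices, builds the network in
#' the requested mode, and runs global, miRNA-fixed and SM-fixed LOOCV over
#' a grid of decay factors.  The decay factor has no published value, so
#' reproduction attempts sweep a grid and report every AUC.
#'
#' @param assoc_path Path to the known-association list.
#' @param sm_sim_path,mirna_sim_path Paths to the integrated SM and miRNA
#'   similarity matrices.
#' @param mode `"dataset1"` or `"dataset2"`.
#' @param betas Numeric vector of decay factors to sweep (default
#'   `seq(0.1, 0.9, by = 0.1)`).
#' @param scopes LOOCV scopes to run.
#' @param progress Print holdout counters.
#' @return Data frame with columns `mode`, `scope`, `beta`, `auc`,
#'   `n_test`, `n_skipped`.
#' @export
reference_evaluation <- function(assoc_path, sm_sim_path, mirna_sim_path,
                                 mode = c("dataset1", "dataset2"),
                                 betas = seq(0.1, 0.9, by = 0.1),
                                 scopes = c("global", "local_mirna", "local_sm"),
                                 progress = FALSE) {
  mode <- match.arg(mode)
  assoc <- read_association_list(assoc_path)
  ss <- read_similarity_matrix(sm_sim_path)
  mm <- read_similarity_matrix(mirna_sim_path)
  net <- build_network(assoc, ss, mm, mode = mode)
  rows <- list()
  for (beta in betas) {
    for (scope in scopes) {
      cv <- loocv(net, beta = beta, scope = scope, progress = progress)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, scope = scope, beta = beta, auc = cv$auc,
        n_test = cv$n_test, n_skipped = cv$n_skipped,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
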