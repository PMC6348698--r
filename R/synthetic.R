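#' Configuration for the block-structured synthetic network generator
#'
#' The generator plants the statistical structure the HeteSim predictor
#' assumes — similar entities share associations — by assigning SMs and
#' miRNAs to matched blocks: association probability is `p_in` inside a
#' matched block and `p_out` across blocks, and similarity values are drawn
#' from a high range inside blocks and a low, separated range across them.
#' Setting `p_in = p_out` and `sim_in = sim_out` removes the signal entirely
#' (a negative control expected to score near AUC 0.5).
#'
#' @param n_sm,n_mirna Entity counts (default 40 SMs, 60 miRNAs — a desk
#'   scale at which full LOOCV runs in seconds).
#' @param n_blocks Number of matched blocks (default 4).
#' @param p_in,p_out Association probabilities within / across matched
#'   blocks (defaults 0.3 / 0.01, giving a sparse matrix with strong block
#'   signal).
#' @param sim_in,sim_out Length-2 `(low, high)` uniform ranges for within-
#'   and cross-block similarity (defaults (0.6, 0.9) / (0.05, 0.3); the
#'   ranges must not overlap: `sim_out[2] <= sim_in[1]` — except when the
#'   two ranges are identical, the no-signal control).
#' @param seed Integer root seed; sub-streams for the association matrix and
#'   each similarity matrix derive from it deterministically.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_sm = 40, n_mirna = 60, n_blocks = 4,
                             p_in = 0.3, p_out = 0.01,
                             sim_in = c(0.6, 0.9), sim_out = c(0.05, 0.3),
                             seed = 7) {
  cfg <- list(n_sm = as.integer(n_sm), n_mirna = as.integer(n_mirna),
              n_blocks = as.integer(n_blocks),
              p_in = p_in, p_out = p_out,
              sim_in = sim_in, sim_out = sim_out,
              seed = as.integer(seed))
  if (!(cfg$p_out <= cfg$p_in && cfg$p_in <= 1 && cfg$p_out >= 0)) {
    stop("need 0 <= p_out <= p_in <= 1", call. = FALSE)
  }
  ok_range <- function(r) length(r) == 2L && r[1] <= r[2] && r[1] >= 0 && r[2] <= 1
  if (!ok_range(cfg$sim_in) || !ok_range(cfg$sim_out)) {
    stop("similarity ranges must be (low, high) within [0,1]", call. = FALSE)
  }
  # identical ranges are the sanctioned no-signal control; otherwise the
  # blocks must be separated
  if (!isTRUE(all.equal(cfg$sim_in, cfg$sim_out)) &&
      cfg$sim_out[2] > cfg$sim_in[1]) {
    stop("similarity ranges must be separated: sim_out high <= sim_in low",
         call. = FALSE)
  }
  if (cfg$n_blocks > min(cfg$n_sm, cfg$n_mirna)) {
    stop("more blocks than entities", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# one symmetric unit-diagonal similarity matrix with planted blocks
generate_block_similarity <- function(n, blocks, sim_in, sim_out, labels) {
  same <- outer(blocks, blocks, `==`)
  m <- matrix(stats::runif(n * n, sim_out[1], sim_out[2]), n, n)
  m[same] <- stats::runif(sum(same), sim_in[1], sim_in[2])
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  m
}

#' Generate a synthetic SM-miRNA heterogeneous-network fixture
#'
#' Entities are assigned to blocks round-robin; association `(i, j)` is
#' Bernoulli(`p_in`) when the blocks match and Bernoulli(`p_out`) otherwise;
#' similarity entries are uniform draws from the within- or cross-block
#' range, symmetrized by averaging, diagonal set to 1.  Fully determined by
#' the config seed (sub-seeds `seed`, `seed + 1`, `seed + 2` drive the
#' association, SM-similarity and miRNA-similarity streams).
#'
#' @param config A [synthetic_config()].
#' @return List with `associations` (an `assoc_table`), `sm_sim`,
#'   `mirna_sim`, ground-truth `sm_blocks` and `mirna_blocks`, and the
#'   `config` echo.
#' @export
generate_synthetic_network <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  sm_ids <- sprintf("SM%03d", seq_len(config$n_sm))
  mir_ids <- sprintf("syn-mir-%03d", seq_len(config$n_mirna))
  sm_blocks <- ((seq_len(config$n_sm) - 1L) %% config$n_blocks) + 1L
  mir_blocks <- ((seq_len(config$n_mirna) - 1L) %% config$n_blocks) + 1L

  set.seed(config$seed)
  p <- ifelse(outer(sm_blocks, mir_blocks, `==`), config$p_in, config$p_out)
  A <- matrix(stats::rbinom(length(p), 1L, as.vector(p)),
              config$n_sm, config$n_mirna, dimnames = list(sm_ids, mir_ids))

  set.seed(config$seed + 1L)
  sm_sim <- generate_block_similarity(config$n_sm, sm_blocks,
                                      config$sim_in, config$sim_out, sm_ids)
  set.seed(config$seed + 2L)
  mirna_sim <- generate_block_similarity(config$n_mirna, mir_blocks,
                                         config$sim_in, config$sim_out, mir_ids)

  idx <- which(A == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  assoc <- data.frame(sm_id = sm_ids[idx[, 1L]],
                      mirna_id = mir_ids[idx[, 2L]],
                      stringsAsFactors = FALSE)
  class(assoc) <- c("assoc_table", class(assoc))

  list(associations = assoc,
       sm_sim = sm_sim,
       mirna_sim = mirna_sim,
       sm_blocks = stats::setNames(sm_blocks, sm_ids),
       mirna_blocks = stats::setNames(mir_blocks, mir_ids),
       config = config)
}

#' Write a synthetic fixture to disk in the package's file dialects
#'
#' Emits `associations.tsv`, `sm_similarity.tsv`, `mirna_similarity.tsv`
#' and `blocks.tsv` under `dir`; reading them back through the package's
#' readers reproduces the in-memory objects.
#'
#' @param fixture Output of [generate_synthetic_network()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    associations = file.path(dir, "associations.tsv"),
    sm_similarity = file.path(dir, "sm_similarity.tsv"),
    mirna_similarity = file.path(dir, "mirna_similarity.tsv"),
    blocks = file.path(dir, "blocks.tsv")
  )
  utils::write.table(as.data.frame(fixture$associations),
                     paths[["associations"]],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_similarity_matrix(fixture$sm_sim, paths[["sm_similarity"]])
  write_similarity_matrix(fixture$mirna_sim, paths[["mirna_similarity"]])
  blocks <- data.frame(
    id = c(names(fixture$sm_blocks), names(fixture$mirna_blocks)),
    type = c(rep("SM", length(fixture$sm_blocks)),
             rep("miRNA", length(fixture$mirna_blocks))),
    block = c(fixture$sm_blocks, fixture$mirna_blocks),
    stringsAsFactors = FALSE
  )
  utils::write.table(blocks, paths[["blocks"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
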