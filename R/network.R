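#' Row-normalize a nonnegative matrix into a transition matrix
#'
#' Divides each nonzero row by its sum; zero rows stay zero (an entity with
#' no outgoing edges of this type reaches nothing — a uniform row would
#' fabricate reachability the data does not support).
#'
#' @param m Nonnegative numeric matrix.
#' @return Matrix of the same shape whose rows sum to 1 or 0.
#' @export
row_normalize <- function(m) {
  if (any(m < 0)) stop("negative entry in matrix to normalize", call. = FALSE)
  rs <- rowSums(m)
  nz <- rs > 0
  m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  m
}

#' Build the SM-miRNA heterogeneous network
#'
#' Combines a known-association table with integrated SM-SM and miRNA-miRNA
#' similarity matrices into one object holding the binary adjacency matrix
#' `A` (rows = SMs, columns = miRNAs) and the four row-stochastic transition
#' matrices: `Tsm = row_normalize(A)`, `Tms = row_normalize(t(A))`,
#' `Tss = row_normalize(SS)`, `Tmm = row_normalize(MM)`.
#'
#' Two index modes mirror the two dataset conventions: `"dataset1"` keeps
#' every entity named in the similarity matrices (most SMs then have no
#' association and a zero `Tsm` row); `"dataset2"` restricts to entities with
#' at least one known association and subsets the similarity matrices
#' accordingly.
#'
#' @param assoc `assoc_table` of known pairs (see [read_association_list()]).
#' @param sm_sim Integrated SM similarity matrix (labels = SM ids).
#' @param mirna_sim Integrated miRNA similarity matrix (labels = miRNA ids).
#' @param mode `"dataset1"` (full label set) or `"dataset2"` (associated
#'   entities only).
#' @param self_loops Keep the unit diagonal of the similarity matrices when
#'   normalizing into `Tss`/`Tmm` (default `TRUE`); `FALSE` zeroes it first,
#'   for sensitivity analysis.
#' @return An object of class `hetero_network`: a list with `sm_ids`,
#'   `mirna_ids`, `A`, `Tsm`, `Tms`, `Tss`, `Tmm`, the similarity matrices
#'   `SS` and `MM`, and cached two-step similarity walks `Tss2`, `Tmm2`.
#' @export
build_network <- function(assoc, sm_sim, mirna_sim,
                          mode = c("dataset1", "dataset2"),
                          self_loops = TRUE) {
  mode <- match.arg(mode)
  sm_labels <- rownames(sm_sim)
  mir_labels <- rownames(mirna_sim)
  missing_sm <- setdiff(assoc$sm_id, sm_labels)
  if (length(missing_sm) > 0L) {
    stop("SM id(s) absent from SM similarity labels: ",
         paste(utils::head(missing_sm, 5L), collapse = ", "), call. = FALSE)
  }
  missing_mir <- setdiff(assoc$mirna_id, mir_labels)
  if (length(missing_mir) > 0L) {
    stop("miRNA id(s) absent from miRNA similarity labels: ",
         paste(utils::head(missing_mir, 5L), collapse = ", "), call. = FALSE)
  }
  if (mode == "dataset2") {
    sm_labels <- sm_labels[sm_labels %in% assoc$sm_id]
    mir_labels <- mir_labels[mir_labels %in% assoc$mirna_id]
    sm_sim <- sm_sim[sm_labels, sm_labels, drop = FALSE]
    mirna_sim <- mirna_sim[mir_labels, mir_labels, drop = FALSE]
  }
  ns <- length(sm_labels)
  nm <- length(mir_labels)
  A <- matrix(0, ns, nm, dimnames = list(sm_labels, mir_labels))
  A[cbind(match(assoc$sm_id, sm_labels), match(assoc$mirna_id, mir_labels))] <- 1

  SS <- sm_sim
  MM <- mirna_sim
  if (!self_loops) {
    diag(SS) <- 0
    diag(MM) <- 0
  }
  Tss <- row_normalize(SS)
  Tmm <- row_normalize(MM)
  net <- structure(list(
    sm_ids = sm_labels,
    mirna_ids = mir_labels,
    A = A,
    Tsm = row_normalize(A),
    Tms = row_normalize(t(A)),
    Tss = Tss,
    Tmm = Tmm,
    Tss2 = Tss %*% Tss,
    Tmm2 = Tmm %*% Tmm,
    SS = sm_sim,
    MM = mirna_sim,
    mode = mode,
    self_loops = self_loops
  ), class = "hetero_network")
  net
}

#' @export
print.hetero_network <- function(x, ...) {
  cat(sprintf("SM-miRNA heterogeneous network (%s): %d SMs x %d miRNAs, %d known associations\n",
              x$mode, length(x$sm_ids), length(x$mirna_ids), sum(x$A)))
  invisible(x)
}

#' Mask known associations out of a network
#'
#' Returns a copy of the network with the given `A` cells set to 0 and the
#' association transitions `Tsm`, `Tms` re-derived; the similarity-based
#' `Tss`/`Tmm` (and their cached squares) are static inputs and unchanged.
#' This is the holdout primitive behind every cross-validation scheme and
#' the new-compound case study.
#'
#' @param net A `hetero_network`.
#' @param held_out Two-column matrix or data frame of (SM row index, miRNA
#'   column index) pairs; every named cell must currently be 1.
#' @return The masked `hetero_network`.
#' @export
mask_associations <- function(net, held_out) {
  held_out <- as.matrix(held_out)
  if (length(held_out) == 0L) return(net)
  if (ncol(held_out) != 2L) stop("held_out must have two columns", call. = FALSE)
  vals <- net$A[held_out]
  if (any(vals != 1)) {
    bad <- which(vals != 1)[1L]
    stop("cannot mask non-association cell (", held_out[bad, 1L], ",",
         held_out[bad, 2L], ")", call. = FALSE)
  }
  net$A[held_out] <- 0
  net$Tsm <- row_normalize(net$A)
  net$Tms <- row_normalize(t(net$A))
  net
}
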