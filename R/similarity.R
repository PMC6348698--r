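#' Jaccard similarity of two finite sets
#'
#' `|A intersect B| / |A union B|`, the set-overlap score used to build the
#' side-effect and disease-phenotype components of the integrated
#' similarities.  Two empty sets score 0, not 1: an annotation-free entity
#' carries no evidence of similarity to anything.
#'
#' @param set_a,set_b Vectors treated as sets (duplicates ignored).
#' @return A number in \[0,1\].
#' @export
jaccard_similarity <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Weighted integration of component similarity matrices
#'
#' Entrywise weighted mean `sum_k w_k M_k / sum_k w_k` of component
#' similarity matrices sharing identical labels.  With the default equal
#' weights this is the plain average used to combine e.g. side-effect,
#' gene-functional, chemical-structure and disease-phenotype SM similarities
#' into one integrated matrix (and likewise the two miRNA components).
#'
#' @param components List of labeled similarity matrices with identical
#'   dimnames.
#' @param weights Nonnegative weights, one per component; at least one must
#'   be positive.  Default: equal weights.
#' @return The integrated similarity matrix (validated).
#' @export
integrate_similarities <- function(components, weights = rep(1, length(components))) {
  if (length(components) == 0L) stop("no component matrices", call. = FALSE)
  if (length(weights) != length(components)) {
    stop("need one weight per component matrix", call. = FALSE)
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be nonnegative with a positive sum", call. = FALSE)
  }
  ref <- dimnames(components[[1L]])
  for (k in seq_along(components)) {
    if (!identical(dimnames(components[[k]]), ref)) {
      stop("component ", k, " labels differ from component 1", call. = FALSE)
    }
  }
  acc <- 0
  for (k in seq_along(components)) acc <- acc + weights[[k]] * components[[k]]
  validate_similarity(acc / sum(weights), where = "integrated similarity")
}
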