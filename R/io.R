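#' Read a list of known SM-miRNA associations
#'
#' Parses a two-column delimited text file of known small-molecule--miRNA
#' association pairs (e.g. `"CID 3385"` / `"hsa-mir-21"`).  Blank lines and
#' lines starting with `#` are ignored; fields are whitespace-trimmed;
#' duplicate pairs collapse silently (a warning reports the count).  Order of
#' first appearance is preserved.
#'
#' An optional single header line is detected when the second field of the
#' first line is non-numeric and does not look like a miRNA name (no "mir"
#' substring).
#'
#' @param path Path to the association file.
#' @param delimiter Field delimiter.  `NULL` (default) auto-detects among
#'   tab, comma and semicolon on the first non-empty line.
#' @param normalize_ids If `TRUE`, identifiers are lower-cased after
#'   trimming.  Off by default: `"hsa-mir-203a"` and `"hsa-miR-203a"` are
#'   deliberately distinct unless the user opts in.
#' @return A data frame of class `assoc_table` with character columns
#'   `sm_id` and `mirna_id`, one row per unique pair.
#' @export
read_association_list <- function(path, delimiter = NULL, normalize_ids = FALSE) {
  if (!file.exists(path)) {
    stop("association file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    stop("association file contains no data lines: ", path, call. = FALSE)
  }
  if (is.null(delimiter)) delimiter <- detect_delimiter(lines[[1L]])

  fields <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(bad) > 0L) {
    stop("malformed association line (fewer than 2 fields) at line ",
         line_no[bad[1L]], " of ", path, call. = FALSE)
  }
  sm  <- trimws(vapply(fields, `[[`, character(1), 1L))
  mir <- trimws(vapply(fields, `[[`, character(1), 2L))

  # optional header: second field non-numeric and not a miRNA name
  # (miRNA names carry a "mir-"/"let-" token, e.g. hsa-mir-21, hsa-let-7b)
  mirna_like <- function(x) grepl("(^|-)(mir|let)-", x, ignore.case = TRUE)
  if (length(sm) > 1L &&
      is.na(suppressWarnings(as.numeric(mir[[1L]]))) &&
      !mirna_like(mir[[1L]])) {
    sm <- sm[-1L]; mir <- mir[-1L]
  }
  if (normalize_ids) {
    sm <- tolower(sm); mir <- tolower(mir)
  }
  if (any(!nzchar(sm)) || any(!nzchar(mir))) {
    stop("empty identifier after trimming in ", path, call. = FALSE)
  }
  key <- paste(sm, mir, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate association pair(s) collapsed", call. = FALSE)
  }
  out <- data.frame(sm_id = sm[!dup], mirna_id = mir[!dup],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) {
    stop("zero association pairs after parsing: ", path, call. = FALSE)
  }
  class(out) <- c("assoc_table", class(out))
  out
}

#' @export
print.assoc_table <- function(x, ...) {
  cat(sprintf("SM-miRNA association table: %d pairs, %d distinct SMs, %d distinct miRNAs\n",
              nrow(x), length(unique(x$sm_id)), length(unique(x$mirna_id))))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read a labeled similarity matrix
#'
#' Reads an `(n+1) x (n+1)` delimited text file whose first row and first
#' column carry identical entity labels (top-left cell ignored), validates it
#' as a similarity matrix (square, symmetric and unit-diagonal within 1e-6,
#' entries in \[0,1\] up to 1e-9), silently symmetrizes asymmetries below the
#' tolerance by averaging with the transpose, and clamps entries to \[0,1\].
#'
#' An unlabeled all-numeric body is also accepted when `labels` is supplied.
#'
#' @param path Path to the matrix file.
#' @param delimiter Field delimiter; `NULL` auto-detects (tab/comma/semicolon).
#' @param labels Optional character vector of entity labels for unlabeled files.
#' @return A numeric matrix with identical row and column names.
#' @export
read_similarity_matrix <- function(path, delimiter = NULL, labels = NULL) {
  if (!file.exists(path)) {
    stop("similarity file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty similarity file: ", path, call. = FALSE)
  if (is.null(delimiter)) delimiter <- detect_delimiter(lines[[1L]])
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  fields <- lapply(fields, trimws)

  first <- fields[[1L]]
  first_numeric <- !any(is.na(suppressWarnings(as.numeric(first))))

  if (first_numeric) {
    # unlabeled body
    body <- do.call(rbind, lapply(fields, function(f) as.numeric(f)))
    if (is.null(labels)) {
      stop("unlabeled similarity matrix requires explicit `labels`: ", path,
           call. = FALSE)
    }
    if (length(labels) != nrow(body)) {
      stop("labels length does not match matrix dimension", call. = FALSE)
    }
    row_labels <- col_labels <- as.character(labels)
  } else {
    col_labels <- first[-1L]
    rows <- fields[-1L]
    row_labels <- vapply(rows, `[[`, character(1), 1L)
    body <- do.call(rbind, lapply(rows, function(f) {
      suppressWarnings(as.numeric(f[-1L]))
    }))
    if (anyNA(body)) stop("non-numeric matrix entry in ", path, call. = FALSE)
  }
  if (nrow(body) != ncol(body)) {
    stop("similarity matrix is not square: ", nrow(body), " x ", ncol(body),
         call. = FALSE)
  }
  if (!identical(row_labels, col_labels)) {
    stop("row labels do not match column labels in ", path, call. = FALSE)
  }
  dimnames(body) <- list(row_labels, col_labels)
  validate_similarity(body, where = path)
}

#' Validate (and lightly repair) a similarity matrix
#'
#' Checks squareness, symmetry and unit diagonal within 1e-6, and entry range
#' within \[0,1\] up to 1e-9.  Sub-tolerance asymmetry is averaged away and
#' entries are clamped to \[0,1\]; anything larger is a fatal error listing
#' the first offending indices.
#'
#' @param m Numeric square matrix with matching dimnames.
#' @param where Label used in error messages.
#' @return The validated matrix.
#' @export
validate_similarity <- function(m, where = "similarity matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(where, ": not a square matrix", call. = FALSE)
  }
  if (!all(is.finite(m))) stop(where, ": non-finite entries", call. = FALSE)
  if (any(m < -1e-9) || any(m > 1 + 1e-9)) {
    idx <- which(m < -1e-9 | m > 1 + 1e-9, arr.ind = TRUE)[1L, ]
    stop(where, ": entry out of [0,1] at (", idx[1L], ",", idx[2L], "): ",
         m[idx[1L], idx[2L]], call. = FALSE)
  }
  asym <- abs(m - t(m))
  if (max(asym) > 1e-6) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(where, ": asymmetry ", max(asym), " exceeds 1e-6 at (",
         idx[1L], ",", idx[2L], ")", call. = FALSE)
  }
  dev <- abs(diag(m) - 1)
  if (max(dev) > 1e-6) {
    stop(where, ": diagonal deviates from 1 by ", max(dev), " at index ",
         which.max(dev), call. = FALSE)
  }
  m <- (m + t(m)) / 2
  m[m < 0] <- 0
  m[m > 1] <- 1
  diag(m) <- 1
  m
}

#' Write a similarity matrix in the labeled dialect
#'
#' @param m Labeled similarity matrix.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @export
write_similarity_matrix <- function(m, path, delimiter = "\t") {
  labels <- rownames(m)
  header <- paste(c("id", labels), collapse = delimiter)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(labels[i], format(m[i, ], digits = 17, trim = TRUE,
                              scientific = FALSE)),
          collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write ranked association predictions
#'
#' Flattens a score matrix into `(rank, sm_id, mirna_id, score)` rows sorted
#' by descending score, ties broken by `(sm_id, mirna_id)` lexicographic
#' order.
#'
#' @param scores Numeric ns x nm matrix with SM row names and miRNA column
#'   names.
#' @param path Output path.
#' @param top_k Number of rows to keep; `Inf` (default) keeps all.
#' @param delimiter Field delimiter (default tab).
#' @param exclude Optional logical/binary matrix of the same shape; cells
#'   with a nonzero entry (e.g. known associations) are omitted.
#' @return Invisibly, the written data frame.
#' @export
write_predictions <- function(scores, path, top_k = Inf, delimiter = "\t",
                              exclude = NULL) {
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  df <- data.frame(
    sm_id = rep(rownames(scores), times = ncol(scores)),
    mirna_id = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores),
    stringsAsFactors = FALSE
  )
  if (!is.null(exclude)) df <- df[as.vector(exclude) == 0, , drop = FALSE]
  ord <- order(-df$score, df$sm_id, df$mirna_id)
  df <- df[ord, , drop = FALSE]
  if (is.finite(top_k)) df <- utils::head(df, top_k)
  df <- cbind(rank = seq_len(nrow(df)), df)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

# Pick the delimiter among tab/comma/semicolon that splits the header into
# the most fields; tab wins ties (the common supplementary-file dialect).
detect_delimiter <- function(line) {
  cands <- c("\t", ",", ";")
  counts <- vapply(cands, function(d) length(strsplit(line, d, fixed = TRUE)[[1L]]),
                   integer(1))
  cands[[which.max(counts)]]
}
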