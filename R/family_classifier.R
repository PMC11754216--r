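# V gene family classification by pairwise percent nucleotide identity.

#' Pairwise percent-identity matrix
#'
#' All-pairs global alignment identity (percent of match columns among
#' columns where both rows are non-gap). Sequences must be supplied in
#' coding orientation; [call_segments()] already reverse-complements
#' inverted segments.
#'
#' @param x A `gene_segments` data.frame (V rows are used) or a named
#'   character vector of nucleotide sequences.
#' @param ... Scoring parameters passed to [global_align()].
#' @return A symmetric numeric matrix of class `identity_matrix` with a
#'   100 diagonal, dimnames = sequence ids.
#' @export
identity_matrix <- function(x, ...) {
  if (inherits(x, "gene_segments") || is.data.frame(x)) {
    keep <- if ("kind" %in% names(x)) x$kind == "V" else rep(TRUE, nrow(x))
    seqs <- stats::setNames(x$sequence[keep], x$name[keep])
  } else {
    seqs <- x
  }
  n <- length(seqs)
  if (n < 1) stop("at least one sequence is required")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sequences must have unique names")
  }
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        pid <- global_align(seqs[[i]], seqs[[j]], ...)$identity_pct
        m[i, j] <- m[j, i] <- pid
      }
    }
  }
  class(m) <- c("identity_matrix", class(m))
  m
}

#' Cluster sequences into families at an identity threshold
#'
#' Families are the single-linkage connected components of the graph with
#' an edge wherever pairwise identity is at least the threshold (the
#' weakest reading of "sharing >= X% identity"); complete linkage is
#' available as a stricter alternative. Family labels are contiguous from
#' 1 and ordered by each family's first member in `order_by` (segment
#' start coordinate when available, otherwise input order), so the result
#' is invariant to input permutation once `order_by` is fixed.
#'
#' @param matrix An `identity_matrix`.
#' @param threshold Percent identity threshold (default 80).
#' @param method `"single"` (default) or `"complete"` linkage.
#' @param order_by Optional numeric vector (named by matrix ids) used to
#'   order families and rank members, e.g. 5' start coordinates.
#' @return A `family_assignment`: named integer vector of family labels
#'   with attributes `threshold` and `method`.
#' @export
cluster_families <- function(matrix, threshold = 80,
                             method = c("single", "complete"),
                             order_by = NULL) {
  method <- match.arg(method)
  ids <- rownames(matrix)
  n <- nrow(matrix)
  if (n == 1) {
    labels <- stats::setNames(1L, ids)
  } else {
    d <- stats::as.dist(100 - unclass(matrix))
    hc <- stats::hclust(d, method = method)
    grp <- stats::cutree(hc, h = 100 - threshold)
    if (is.null(order_by)) {
      ord <- stats::setNames(seq_len(n), ids)
    } else {
      ord <- order_by[ids]
      if (any(is.na(ord))) stop("order_by must cover every matrix id")
    }
    first_pos <- tapply(ord, grp, min)
    relabel <- stats::setNames(rank(first_pos, ties.method = "first"),
                               names(first_pos))
    labels <- stats::setNames(as.integer(relabel[as.character(grp)]), ids)
  }
  structure(labels, threshold = threshold, method = method,
            class = "family_assignment")
}

#' @export
print.family_assignment <- function(x, ...) {
  cat(sprintf("family assignment: %d sequences in %d families (>= %s%% %s linkage)\n",
              length(x), max(unclass(x)), attr(x, "threshold"),
              attr(x, "method")))
  print(unclass(x))
  invisible(x)
}

#' Write an identity matrix as wide and long TSV tables
#'
#' The long format (`id_a`, `id_b`, `identity`) is convenient for heatmap
#' plotting.
#'
#' @param matrix An `identity_matrix`.
#' @param path Output path for the wide matrix; the long table goes to
#'   `<path>.long.tsv` unless `long_path` is given.
#' @param long_path Optional explicit path for the long table.
#' @export
write_identity_tsv <- function(matrix, path, long_path = NULL) {
  wide <- data.frame(id = rownames(matrix), unclass(matrix),
                     check.names = FALSE)
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(long_path)) long_path <- paste0(path, ".long.tsv")
  idx <- which(upper.tri(matrix, diag = TRUE), arr.ind = TRUE)
  long <- data.frame(id_a = rownames(matrix)[idx[, 1]],
                     id_b = colnames(matrix)[idx[, 2]],
                     identity = matrix[idx])
  write.table(long, long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
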