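# Distance-based phylogenetics: p-distances, neighbor joining, bootstrap.
#
# The neighbor-joining agglomeration (Saitou & Nei) is implemented here
# with a deterministic lexicographic tie-break; trees are returned as ape
# "phylo" objects and written as Newick.

#' Pairwise p-distance matrix from an alignment
#'
#' Per pair, the proportion of mismatching columns among columns where
#' both rows are non-gap (pairwise deletion of gaps).
#'
#' @param msa Named character vector of equal-length aligned sequences
#'   (gap character `-`).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(msa) {
  if (length(msa) < 2) stop("at least two taxa are required")
  if (length(unique(nchar(msa))) != 1) {
    stop("aligned sequences must all have the same length")
  }
  ids <- names(msa)
  if (is.null(ids) || anyDuplicated(ids)) stop("taxa must have unique names")
  chars <- do.call(rbind, strsplit(unname(msa), ""))
  n <- length(msa)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable columns between ", ids[i], " and ", ids[j])
      }
      d[i, j] <- d[j, i] <- sum(chars[i, ok] != chars[j, ok]) / sum(ok)
    }
  }
  d
}

.quote_label <- function(x) {
  needs <- grepl("[][ ():,;']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

.fmt_len <- function(x) sprintf("%.10g", max(x, 0))

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q criterion is joined, with branch lengths from the standard formulas
#' (negative lengths clamped to zero). Ties are broken by lexicographic
#' order of the joined clusters' smallest taxon labels, making the result
#' deterministic.
#'
#' @param d Symmetric distance matrix with taxon dimnames (at least 3).
#' @return An unrooted `phylo` tree (ape) with branch lengths.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  ids <- rownames(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  # build with placeholder tip labels so arbitrary ids survive re-parsing
  newick <- paste0("t", seq_len(n))
  minleaf <- ids                # cluster identity for tie-breaking
  active <- seq_len(n)
  D <- d

  while (length(active) > 2) {
    m <- length(active)
    if (m == 3) {
      # closed-form star resolution of the last three clusters
      a <- active[1]; b <- active[2]; c3 <- active[3]
      la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
      lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
      lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
      txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                     newick[a], .fmt_len(la), newick[b], .fmt_len(lb),
                     newick[c3], .fmt_len(lc))
      tree <- ape::read.tree(text = txt)
      tree$tip.label <- ids[as.integer(sub("^t", "", tree$tip.label))]
      return(tree)
    }
    Dm <- D[active, active]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- vapply(seq_len(nrow(cand)), function(k) {
      lab <- sort(c(minleaf[active[cand[k, 1]]],
                    minleaf[active[cand[k, 2]]]))
      paste(lab, collapse = "\r")
    }, "")
    pick <- cand[order(pair_key)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]

    dij <- D[i, j]
    li <- dij / 2 + (r[pick[1]] - r[pick[2]]) / (2 * (m - 2))
    lj <- dij - li
    new_txt <- sprintf("(%s:%s,%s:%s)", newick[i], .fmt_len(li),
                       newick[j], .fmt_len(lj))

    # distances from the new node to the remaining clusters
    rest <- setdiff(active, c(i, j))
    newD <- (D[i, rest] + D[j, rest] - dij) / 2
    idx <- length(newick) + 1L
    D <- rbind(cbind(D, 0), 0)
    D[idx, rest] <- D[rest, idx] <- newD
    newick <- c(newick, new_txt)
    minleaf <- c(minleaf, min(minleaf[c(i, j)]))
    active <- c(rest, idx)
  }
  # n == 3 handled inside the loop; n > 3 always reduces to 3
  stop("unreachable")
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Alignment columns are resampled with replacement `n_reps` times; the
#' support of each internal bipartition of the full-data tree is the
#' percentage of replicate trees containing it, stored in the tree's
#' `node.label`.
#'
#' @param msa Named character vector of aligned sequences.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed for reproducible resampling.
#' @param dist_fun Distance function applied to each resampled alignment
#'   (default [p_distance()]).
#' @return A `phylo` tree with `node.label` giving supports in `[0, 100]`.
#' @export
nj_bootstrap <- function(msa, n_reps = 1000, seed = NULL,
                         dist_fun = p_distance) {
  ref <- nj_tree(dist_fun(msa))
  chars <- do.call(rbind, strsplit(unname(msa), ""))
  n_col <- ncol(chars)
  run <- function() {
    trees <- vector("list", n_reps)
    for (b in seq_len(n_reps)) {
      repeat {
        cols <- sample.int(n_col, n_col, replace = TRUE)
        boot <- stats::setNames(apply(chars[, cols, drop = FALSE], 1,
                                      paste, collapse = ""), names(msa))
        tr <- tryCatch(nj_tree(dist_fun(boot)), error = function(e) NULL)
        if (!is.null(tr)) break  # redraw on all-gap column draws
      }
      trees[[b]] <- tr
    }
    trees
  }
  trees <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps, 1)
  ref$node.label <- as.character(support)
  ref$node.label[1] <- ""  # root of the unrooted representation
  attr(ref, "n_reps") <- n_reps
  ref
}

#' Serialize a tree as Newick
#'
#' Branch lengths are written at full precision; internal `node.label`
#' values (e.g. bootstrap supports) appear as internal labels. Labels
#' containing spaces or Newick metacharacters are single-quoted. The
#' output re-parses with `ape::read.tree`.
#'
#' @param tree A `phylo` object.
#' @param path Optional output path.
#' @return The Newick string, invisibly if `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  node_str <- function(node) {
    rows <- children[[as.character(node)]]
    if (is.null(rows)) {
      return(.quote_label(tree$tip.label[node]))
    }
    parts <- vapply(rows, function(r) {
      child <- tree$edge[r, 2]
      s <- node_str(child)
      if (!is.null(tree$edge.length)) {
        s <- paste0(s, ":", sprintf("%.10g", tree$edge.length[r]))
      }
      s
    }, "")
    label <- ""
    if (!is.null(tree$node.label)) {
      lab <- tree$node.label[node - ntip]
      if (!is.na(lab) && nzchar(lab)) label <- .quote_label(lab)
    }
    paste0("(", paste(parts, collapse = ","), ")", label)
  }
  txt <- paste0(node_str(root), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write a distance matrix as TSV
#'
#' @param d Matrix with dimnames.
#' @param path Output path.
#' @export
write_distance_tsv <- function(d, path) {
  out <- data.frame(id = rownames(d), unclass(d), check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
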