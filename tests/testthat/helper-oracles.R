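# Independent oracles used to validate the package's primitives.

rand_nt_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Affine-gap global alignment score by an independent R dynamic program
# (score only, no traceback). Gap of length L costs open + (L-1) * ext.
oracle_global_score <- function(a, b, match = 2, mismatch = -1,
                                open = -4, ext = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(-Inf, n + 1, m + 1)
  GA <- matrix(-Inf, n + 1, m + 1)  # gap consuming A
  GB <- matrix(-Inf, n + 1, m + 1)  # gap consuming B
  M[1, 1] <- 0
  for (i in 2:(n + 1)) GA[i, 1] <- open + (i - 2) * ext
  for (j in 2:(m + 1)) GB[1, j] <- open + (j - 2) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") match else mismatch
      M[i, j] <- s + max(M[i - 1, j - 1], GA[i - 1, j - 1],
                         GB[i - 1, j - 1])
      GA[i, j] <- max(M[i - 1, j] + open, GA[i - 1, j] + ext,
                      GB[i - 1, j] + open)
      GB[i, j] <- max(M[i, j - 1] + open, GB[i, j - 1] + ext,
                      GA[i, j - 1] + open)
    }
  }
  max(M[n + 1, m + 1], GA[n + 1, m + 1], GB[n + 1, m + 1])
}

# True exhaustive enumeration over all alignments (tiny inputs only);
# validates the oracle DP itself.
oracle_enumerate_score <- function(a, b, match = 2, mismatch = -1,
                                   open = -4, ext = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(A)) {
      g <- if (last == "A") ext else open
      best <- max(best, g + rec(i + 1, j, "A"))
    }
    if (j <= length(B)) {
      g <- if (last == "B") ext else open
      best <- max(best, g + rec(i, j + 1, "B"))
    }
    best
  }
  rec(1, 1, "M")
}

# Fit alignment oracle: best global score of the query against every
# substring of the reference (end gaps on the reference free).
oracle_fit_score <- function(query, reference, ...) {
  m <- nchar(reference)
  best <- -Inf
  for (s in 1:m) {
    for (e in s:m) {
      best <- max(best, oracle_global_score(query,
                                            substr(reference, s, e), ...))
    }
  }
  best
}

# Independent recomputation of simulator truth flags from the truth
# tables (frame arithmetic plus stop-codon scan).
recompute_truth_flags <- function(rep_truth, locus_truth) {
  germ <- stats::setNames(locus_truth$sequence, locus_truth$name)
  out <- rep_truth
  for (r in seq_len(nrow(rep_truth))) {
    tt <- rep_truth[r, ]
    Lv <- nchar(germ[[tt$v_name]])
    Lj <- nchar(germ[[tt$j_name]])
    pre_c <- paste0(substr(germ[[tt$v_name]], 1, Lv - tt$v_trim),
                    tt$junction,
                    substr(germ[[tt$j_name]], tt$j_trim + 1, Lj))
    out$in_frame[r] <- nchar(pre_c) %% 3 == 0
    out$has_stop[r] <- grepl("*", translate_nt(pre_c), fixed = TRUE)
    out$productive[r] <- tt$complete_5p && out$in_frame[r] &&
      !out$has_stop[r]
  }
  out
}

# All unrooted topologies for a small taxon set, with least-squares
# branch lengths: the unique topology fitting an additive matrix with
# ~zero residual is the true tree.
oracle_best_topology <- function(d) {
  taxa <- rownames(d)
  n <- length(taxa)
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  pair_idx <- which(upper.tri(d), arr.ind = TRUE)
  target <- d[upper.tri(d)]
  best <- NULL; best_res <- Inf
  for (ti in seq_along(trees)) {
    # [[ re-attaches the multiPhylo's compressed tip labels
    tr <- trees[[ti]]
    n_edge <- nrow(tr$edge)
    # indicator of each edge on each tip-pair path
    A <- matrix(0, nrow(pair_idx), n_edge)
    for (e in seq_len(n_edge)) {
      t2 <- tr
      t2$edge.length <- rep(0, n_edge)
      t2$edge.length[e] <- 1
      cp <- ape::cophenetic.phylo(t2)[taxa, taxa]
      A[, e] <- cp[upper.tri(cp)]
    }
    fit <- stats::lsfit(A, target, intercept = FALSE)
    res <- sum(fit$residuals^2)
    if (res < best_res) {
      best_res <- res
      tr$edge.length <- fit$coefficients
      best <- tr
    }
  }
  list(tree = best, residual = best_res)
}

# Random additive distance matrix from a random binary tree with
# positive branch lengths; returns matrix and the generating ape tree.
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.5, 3))
  tr$tip.label <- LETTERS[seq_len(n_taxa)]
  d <- ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label]
  list(d = d, tree = tr)
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# small default locus/repertoire used by several tests
tiny_locus <- function(seed = 3, ...) {
  generate_locus(locus_config(n_v = 4, n_d = 2, n_j = 3, n_c = 1,
                              n_families = 2, n_inverted_v = 1,
                              seed = seed, ...))
}
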