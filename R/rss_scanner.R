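# Recombination signal sequence (RSS) detection.
#
# An RSS is a conserved heptamer (consensus CACAGTG) separated from a
# conserved nonamer (consensus ACAAAAACC) by a 12- or 23-bp spacer. The
# scanner scores candidate heptamer/nonamer windows with a position
# frequency model as summed per-position log2 odds against a background
# composition, in bits, and reports hits on both strands in forward
# coordinates.

RSS_HEPTAMER_CONSENSUS <- "CACAGTG"
RSS_NONAMER_CONSENSUS <- "ACAAAAACC"
.BASES <- c("A", "C", "G", "T")

.validate_pfm <- function(pfm, width, what) {
  if (!is.matrix(pfm) || nrow(pfm) != 4 || ncol(pfm) != width) {
    stop(what, " must be a 4 x ", width, " matrix (rows A, C, G, T)")
  }
  if (any(pfm <= 0)) stop(what, " must be strictly positive")
  sweep(pfm, 2, colSums(pfm), "/")
}

#' Construct an RSS scoring model
#'
#' @param heptamer_pfm 4 x 7 base frequency matrix (rows A, C, G, T);
#'   columns are renormalized to sum to 1.
#' @param nonamer_pfm 4 x 9 base frequency matrix.
#' @param spacer_class 12 or 23.
#' @param spacer_tolerance Allowed deviation from the spacer class, in bp.
#' @param background Per-base background frequencies (A, C, G, T).
#' @return An object of class `rss_model`.
#' @export
rss_model <- function(heptamer_pfm, nonamer_pfm, spacer_class,
                      spacer_tolerance = 1, background = rep(0.25, 4)) {
  if (!spacer_class %in% c(12, 23)) stop("spacer_class must be 12 or 23")
  stopifnot(spacer_tolerance >= 0, length(background) == 4,
            all(background > 0))
  background <- background / sum(background)
  h <- .validate_pfm(heptamer_pfm, 7, "heptamer_pfm")
  n <- .validate_pfm(nonamer_pfm, 9, "nonamer_pfm")
  rownames(h) <- rownames(n) <- .BASES
  names(background) <- .BASES
  structure(list(heptamer_pfm = h, nonamer_pfm = n,
                 spacer_class = as.integer(spacer_class),
                 spacer_tolerance = as.integer(spacer_tolerance),
                 background = background),
            class = "rss_model")
}

.consensus_pfm <- function(consensus, major, strong_pos = integer(0),
                           strong = 0.94) {
  bases <- strsplit(consensus, "")[[1]]
  w <- length(bases)
  pfm <- matrix(0, 4, w, dimnames = list(.BASES, NULL))
  for (k in seq_len(w)) {
    p <- if (k %in% strong_pos) strong else major
    pfm[, k] <- (1 - p) / 3
    pfm[bases[k], k] <- p
  }
  pfm
}

#' Default RSS model
#'
#' Position frequencies concentrated on the canonical consensus
#' (CACAGTG heptamer, ACAAAAACC nonamer), with the first three heptamer
#' positions (CAC), which are functionally the most constrained, weighted
#' most heavily.
#'
#' @param spacer_class 12 or 23.
#' @param spacer_tolerance Allowed spacer length deviation (default 1).
#' @return An `rss_model`.
#' @export
default_rss_model <- function(spacer_class, spacer_tolerance = 1) {
  rss_model(
    heptamer_pfm = .consensus_pfm(RSS_HEPTAMER_CONSENSUS, 0.85,
                                  strong_pos = 1:3),
    nonamer_pfm = .consensus_pfm(RSS_NONAMER_CONSENSUS, 0.85),
    spacer_class = spacer_class,
    spacer_tolerance = spacer_tolerance
  )
}

#' Train an RSS model from example sites
#'
#' Position frequency tables are estimated from base counts with additive
#' pseudocount smoothing.
#'
#' @param examples A data.frame with character columns `heptamer` (length-7)
#'   and `nonamer` (length-9), or a list of such pairs.
#' @param spacer_class 12 or 23.
#' @param pseudocount Positive smoothing mass added to every base count.
#' @param background `"uniform"` or `"empirical"` (base composition of the
#'   training examples).
#' @param spacer_tolerance Allowed spacer length deviation (default 1).
#' @return An `rss_model`.
#' @export
train_rss_model <- function(examples, spacer_class, pseudocount = 1,
                            background = c("uniform", "empirical"),
                            spacer_tolerance = 1) {
  background <- match.arg(background)
  if (is.list(examples) && !is.data.frame(examples)) {
    examples <- data.frame(
      heptamer = vapply(examples, `[[`, "", 1),
      nonamer = vapply(examples, function(e) e[[length(e)]], "")
    )
  }
  if (nrow(examples) < 1) stop("at least one training example is required")
  if (any(nchar(examples$heptamer) != 7)) stop("heptamers must be length 7")
  if (any(nchar(examples$nonamer) != 9)) stop("nonamers must be length 9")
  stopifnot(pseudocount > 0)
  count_pfm <- function(seqs, w) {
    mat <- matrix(pseudocount, 4, w, dimnames = list(.BASES, NULL))
    chars <- do.call(rbind, strsplit(toupper(seqs), ""))
    for (k in seq_len(w)) {
      tab <- table(factor(chars[, k], levels = .BASES))
      mat[, k] <- mat[, k] + as.numeric(tab)
    }
    mat
  }
  bg <- rep(0.25, 4)
  if (background == "empirical") {
    all_chars <- unlist(strsplit(toupper(
      c(examples$heptamer, examples$nonamer)), ""))
    tab <- table(factor(all_chars[all_chars %in% .BASES], levels = .BASES))
    bg <- (as.numeric(tab) + 1) / sum(as.numeric(tab) + 1)
  }
  rss_model(count_pfm(examples$heptamer, 7), count_pfm(examples$nonamer, 9),
            spacer_class, spacer_tolerance = spacer_tolerance,
            background = bg)
}

.logodds <- function(pfm, background) log2(pfm / background)

#' Score a heptamer/nonamer pair under an RSS model
#'
#' Sum over positions of `log2(f_pos(base) / background(base))`, in bits.
#' An `N` contributes 0 at its position.
#'
#' @param model An `rss_model`.
#' @param heptamer Length-7 nucleotide string.
#' @param nonamer Length-9 nucleotide string.
#' @return Score in bits.
#' @export
score_rss_window <- function(model, heptamer, nonamer) {
  stopifnot(inherits(model, "rss_model"),
            nchar(heptamer) == 7, nchar(nonamer) == 9)
  score_part <- function(seq, pfm) {
    lo <- .logodds(pfm, model$background)
    chars <- strsplit(toupper(seq), "")[[1]]
    sum(vapply(seq_along(chars), function(k) {
      if (chars[k] == "N") 0 else lo[chars[k], k]
    }, 0))
  }
  score_part(heptamer, model$heptamer_pfm) +
    score_part(nonamer, model$nonamer_pfm)
}

#' Maximum attainable score of an RSS model
#'
#' @param model An `rss_model`.
#' @return Bits.
#' @export
rss_max_score <- function(model) {
  stopifnot(inherits(model, "rss_model"))
  sum(apply(.logodds(model$heptamer_pfm, model$background), 2, max)) +
    sum(apply(.logodds(model$nonamer_pfm, model$background), 2, max))
}

#' Total information content of an RSS model
#'
#' Sum over positions of `2 - H(position)` in bits, where `H` is the
#' Shannon entropy of the position's base frequencies.
#'
#' @param model An `rss_model`.
#' @return Bits.
#' @export
rss_information_content <- function(model) {
  ic <- function(pfm) sum(apply(pfm, 2, function(p) 2 + sum(p * log2(p))))
  ic(model$heptamer_pfm) + ic(model$nonamer_pfm)
}

#' @export
print.rss_model <- function(x, ...) {
  cat(sprintf(
    "RSS model: spacer class %d (+/- %d), max score %.2f bits, IC %.2f bits\n",
    x$spacer_class, x$spacer_tolerance, rss_max_score(x),
    rss_information_content(x)))
  invisible(x)
}

# per-start-position window scores for one strand of an encoded sequence;
# codes: 1..4 = A,C,G,T; NA = N (contributes 0)
.window_scores <- function(code, lo) {
  w <- ncol(lo)
  L <- length(code)
  n_start <- L - w + 1
  if (n_start < 1) return(numeric(0))
  total <- numeric(n_start)
  for (k in seq_len(w)) {
    contrib <- lo[, k][code[k:(k + n_start - 1)]]
    contrib[is.na(contrib)] <- 0
    total <- total + contrib
  }
  total
}

.encode_nt <- function(seq) {
  code <- match(strsplit(seq, "")[[1]], .BASES)
  code
}

.scan_one_strand <- function(seq, model, threshold) {
  code <- .encode_nt(seq)
  L <- length(code)
  s7 <- .window_scores(code, .logodds(model$heptamer_pfm, model$background))
  s9 <- .window_scores(code, .logodds(model$nonamer_pfm, model$background))
  spacers <- (model$spacer_class - model$spacer_tolerance):
    (model$spacer_class + model$spacer_tolerance)
  out <- list()
  for (sp in spacers) {
    offset <- 7 + sp  # nonamer start relative to heptamer start
    n_valid <- min(length(s7), length(s9) - offset)
    if (n_valid < 1) next
    i <- seq_len(n_valid)
    total <- s7[i] + s9[i + offset]
    keep <- which(total >= threshold)
    if (length(keep)) {
      out[[length(out) + 1]] <- data.frame(
        hept_start = keep, spacer_len = sp, score = total[keep])
    }
  }
  if (!length(out)) {
    return(data.frame(hept_start = integer(0), spacer_len = integer(0),
                      score = numeric(0)))
  }
  do.call(rbind, out)
}

#' Scan a sequence for RSS hits on both strands
#'
#' All heptamer/nonamer windows whose joint log-odds score reaches the
#' threshold and whose spacer length is within the model's tolerance are
#' reported. Minus-strand hits are reported in forward coordinates with a
#' strand flag; on the minus strand the heptamer lies to the right of the
#' nonamer in forward coordinates. Overlapping hits are all reported.
#'
#' @param seq Nucleotide string (length at least 7 + spacer + 9).
#' @param model An `rss_model`.
#' @param threshold Minimum joint score in bits; the default is 60% of the
#'   model's maximum score.
#' @return A data.frame of class `rss_hits`, sorted by coordinate, with
#'   columns `hept_start`, `hept_end`, `non_start`, `non_end`,
#'   `spacer_len`, `strand`, `score`, `heptamer`, `nonamer`, `canonical`.
#' @export
scan_rss <- function(seq, model, threshold = 0.6 * rss_max_score(model)) {
  stopifnot(length(seq) == 1, inherits(model, "rss_model"))
  .check_nt(seq)
  L <- nchar(seq)
  min_len <- 7 + model$spacer_class - model$spacer_tolerance + 9
  if (L < min_len) stop("sequence shorter than one RSS footprint")

  fwd <- .scan_one_strand(seq, model, threshold)
  rc <- .scan_one_strand(revcomp(seq), model, threshold)

  rows <- list()
  if (nrow(fwd)) {
    rows$fwd <- data.frame(
      hept_start = fwd$hept_start, hept_end = fwd$hept_start + 6,
      non_start = fwd$hept_start + 7 + fwd$spacer_len,
      non_end = fwd$hept_start + 15 + fwd$spacer_len,
      spacer_len = fwd$spacer_len, strand = "+", score = fwd$score)
  }
  if (nrow(rc)) {
    # position i on the reverse complement maps to forward L - i + 1
    rows$rev <- data.frame(
      hept_start = L - rc$hept_start - 5, hept_end = L - rc$hept_start + 1,
      non_start = L - rc$hept_start - rc$spacer_len - 14,
      non_end = L - rc$hept_start - rc$spacer_len - 6,
      spacer_len = rc$spacer_len, strand = "-", score = rc$score)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else data.frame(
    hept_start = integer(0), hept_end = integer(0), non_start = integer(0),
    non_end = integer(0), spacer_len = integer(0), strand = character(0),
    score = numeric(0))

  if (nrow(hits)) {
    hept_fwd <- substring(seq, hits$hept_start, hits$hept_end)
    non_fwd <- substring(seq, hits$non_start, hits$non_end)
    minus <- hits$strand == "-"
    hits$heptamer <- hept_fwd
    hits$nonamer <- non_fwd
    if (any(minus)) {
      hits$heptamer[minus] <- revcomp(hept_fwd[minus])
      hits$nonamer[minus] <- revcomp(non_fwd[minus])
    }
    hits$canonical <- hits$heptamer == RSS_HEPTAMER_CONSENSUS
    hits <- hits[order(pmin(hits$hept_start, hits$non_start),
                       hits$strand, hits$spacer_len), , drop = FALSE]
    rownames(hits) <- NULL
  } else {
    hits$heptamer <- character(0)
    hits$nonamer <- character(0)
    hits$canonical <- logical(0)
  }
  attr(hits, "spacer_class") <- model$spacer_class
  attr(hits, "threshold") <- threshold
  class(hits) <- c("rss_hits", "data.frame")
  hits
}

#' Write RSS hits as a BED-like TSV
#'
#' @param hits An `rss_hits` data.frame.
#' @param path Output path.
#' @param chrom Chromosome/sequence name for the first column.
#' @export
write_rss_bed <- function(hits, path, chrom = "locus") {
  bed <- data.frame(
    chrom = chrom,
    start = pmin(hits$hept_start, hits$non_start) - 1L,  # BED is 0-based
    end = pmax(hits$hept_end, hits$non_end),
    name = sprintf("RSS%d_%s", hits$spacer_len, hits$heptamer),
    score = round(hits$score, 3),
    strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
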