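# Sequence primitives shared by all analysis stages.
#
# Sequences are plain uppercase character strings; collections are named
# character vectors (names = record ids). Coordinates are 1-based inclusive
# throughout (the GFF3/IRanges convention).

.NT_CHARS <- c("A", "C", "G", "T", "N")

.check_nt <- function(seq, arg = "seq") {
  if (length(seq) == 0) stop(arg, " must contain at least one sequence")
  if (any(!nzchar(seq))) stop(arg, " contains an empty sequence")
  bad <- grepl(paste0("[^", paste(.NT_CHARS, collapse = ""), "]"), seq)
  if (any(bad)) {
    stop("non-nucleotide character in ", arg, " (allowed: A/C/G/T/N): ",
         substr(seq[bad][1], 1, 40))
  }
  invisible(seq)
}

#' Read sequences from a FASTA file
#'
#' Sequences are uppercased; for nucleotide input `U` is mapped to `T`.
#' Record ids (the first whitespace-delimited token of each header) must be
#' unique and sequences non-empty.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"nt"` (default) or `"aa"`.
#' @return A named character vector of sequences, with attribute `moltype`.
#' @export
read_fasta <- function(path, moltype = c("nt", "aa")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    out <- character(0)
    attr(out, "moltype") <- moltype
    return(out)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("malformed FASTA header (empty id) in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for FASTA record: ", ids[!nzchar(seqs)][1])
  }
  if (moltype == "nt") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    .check_nt(seqs, paste0("FASTA file ", path))
  }
  names(seqs) <- ids
  attr(seqs, "moltype") <- moltype
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  set <- Biostrings::BStringSet(unclass(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Reverse complement
#'
#' Vectorized over its input; `N` maps to `N`.
#'
#' @param seq Character vector of nucleotide sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  .check_nt(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code; stop codons render as `*`, any codon containing
#' `N` renders as `X`, and a trailing partial codon is dropped.
#'
#' @param seq A single nucleotide string.
#' @param frame Reading frame offset: 0, 1 or 2 nucleotides skipped.
#' @return The amino-acid string (possibly empty).
#' @export
translate_nt <- function(seq, frame = 0) {
  stopifnot(length(seq) == 1, frame %in% 0:2)
  .check_nt(seq)
  s <- substr(seq, frame + 1, nchar(seq))
  n_codon <- nchar(s) %/% 3
  if (n_codon == 0) return("")
  codons <- substring(s, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

.new_alignment <- function(res, a, b) {
  al_a <- res$aligned_a
  al_b <- res$aligned_b
  structure(list(
    aligned_a = al_a, aligned_b = al_b,
    score = res$score,
    identity_pct = alignment_identity(al_a, al_b),
    a_start = res$a_start, a_end = res$a_end,
    b_start = res$b_start, b_end = res$b_end
  ), class = "pairwise_alignment")
}

#' Percent identity of an alignment
#'
#' Identity over columns where both rows are non-gap; `N` never counts as a
#' match. Returns `NA` if no such column exists.
#'
#' @param aligned_a,aligned_b Equal-length gapped strings.
#' @return Percent identity in `[0, 100]`.
#' @export
alignment_identity <- function(aligned_a, aligned_b) {
  stopifnot(nchar(aligned_a) == nchar(aligned_b))
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both)) return(NA_real_)
  matches <- both & ca == cb & ca != "N"
  100 * sum(matches) / sum(both)
}

#' Global pairwise alignment (affine gaps)
#'
#' Optimal Needleman-Wunsch alignment with affine gap costs: a gap of
#' length L costs `gap_open + (L - 1) * gap_extend`.
#'
#' @param a,b Sequences to align (non-empty strings).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return A `pairwise_alignment`: gapped strings, `score`, `identity_pct`,
#'   and 1-based aligned coordinate spans on each input.
#' @export
global_align <- function(a, b, match = 2, mismatch = -1,
                         gap_open = -4, gap_extend = -1) {
  stopifnot(nzchar(a), nzchar(b))
  res <- .align_affine(a, b, match, mismatch, gap_open, gap_extend,
                       0L, FALSE)
  .new_alignment(res, a, b)
}

#' Fit (semi-global) alignment of a query against a reference
#'
#' Aligns the query against the best-scoring substring of the reference:
#' end gaps on the reference are free. With `query_free = TRUE` end gaps on
#' the query are also free (overlap alignment), which tolerates queries
#' truncated relative to the reference.
#'
#' @inheritParams global_align
#' @param query,reference Sequences; the reference ends are unpenalized.
#' @param query_free Also leave query end gaps unpenalized.
#' @return A `pairwise_alignment`; `b_start`/`b_end` give the matched
#'   reference interval, `a_start`/`a_end` the aligned query span.
#' @export
fit_align <- function(query, reference, match = 2, mismatch = -1,
                      gap_open = -4, gap_extend = -1, query_free = FALSE) {
  stopifnot(nzchar(query), nzchar(reference))
  res <- .align_affine(query, reference, match, mismatch, gap_open,
                       gap_extend, 1L, query_free)
  .new_alignment(res, query, reference)
}

#' Local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' Best-scoring block of both sequences; used to place a germline segment
#' anywhere within a longer transcript when either sequence may be
#' trimmed or truncated at its ends.
#'
#' @inheritParams global_align
#' @param query,reference Sequences to align.
#' @return A `pairwise_alignment` over the matched block; `a_start`/
#'   `a_end` and `b_start`/`b_end` give the block on each input.
#' @export
local_align <- function(query, reference, match = 2, mismatch = -1,
                        gap_open = -4, gap_extend = -1) {
  stopifnot(nzchar(query), nzchar(reference))
  res <- .align_affine(query, reference, match, mismatch, gap_open,
                       gap_extend, 2L, FALSE)
  .new_alignment(res, query, reference)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment: score %.1f, identity %.1f%%\n",
              x$score, x$identity_pct))
  cat(sprintf("  query [%d, %d]   reference [%d, %d]\n",
              x$a_start, x$a_end, x$b_start, x$b_end))
  w <- 60
  for (o in seq(1, nchar(x$aligned_a), by = w)) {
    cat(substr(x$aligned_a, o, o + w - 1), "\n")
    cat(substr(x$aligned_b, o, o + w - 1), "\n\n")
  }
  invisible(x)
}
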