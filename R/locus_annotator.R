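# Assembly of RSS hits into typed V/D/J/C gene segment calls.
#
# Segment architecture follows the 12/23 rule: V segments carry a 23-spacer
# RSS at their 3' end, J segments a 12-spacer RSS at their 5' end, and D
# segments are flanked by a 12-RSS on the V-proximal side and a 23-RSS on
# the C-proximal side. RSS orientation is informative: the recombination
# signal reads heptamer-then-nonamer pointing away from its coding segment,
# so the segment always sits on the side of the heptamer opposite the
# nonamer ("away side": left of the heptamer for plus-strand hits, right
# for minus-strand hits).

#' Segment-calling parameters
#'
#' Length windows (in nt) for candidate V, D and J segments. Defaults
#' reflect typical TCR gene segment sizes.
#'
#' @param min_v,max_v V exon length window; candidate V windows are
#'   codon-aligned (multiples of 3).
#' @param min_j,max_j J segment length window.
#' @param min_d,max_d D segment length window.
#' @return A named list.
#' @export
segment_params <- function(min_v = 270, max_v = 330, min_j = 30,
                           max_j = 70, min_d = 8, max_d = 25) {
  stopifnot(min_v <= max_v, min_j <= max_j, min_d <= max_d)
  list(min_v = min_v, max_v = max_v, min_j = min_j, max_j = max_j,
       min_d = min_d, max_d = max_d)
}

.rss_key <- function(hits, idx) {
  sprintf("%d:%d:%s", hits$hept_start[idx], hits$hept_end[idx],
          hits$strand[idx])
}

.has_stop_frame0 <- function(nt) grepl("*", translate_nt(nt), fixed = TRUE)

.j_motif_any_frame <- function(nt) {
  any(vapply(0:2, function(f) check_j_motif(translate_nt(nt, f)), NA))
}

# candidate V immediately 5' (in coding orientation) of a 23-RSS heptamer:
# the longest codon-aligned window in [min_v, max_v] whose frame-0
# translation is stop free
.v_candidate <- function(seq, L, hits23, i, params) {
  lens <- seq(params$min_v, params$max_v)
  lens <- rev(lens[lens %% 3 == 0])
  plus <- hits23$strand[i] == "+"
  for (len in lens) {
    if (plus) {
      end <- hits23$hept_start[i] - 1L
      start <- end - len + 1L
      if (start < 1L || end < 1L) next
      coding <- substr(seq, start, end)
    } else {
      start <- hits23$hept_end[i] + 1L
      end <- start + len - 1L
      if (end > L) next
      coding <- revcomp(substr(seq, start, end))
    }
    if (!.has_stop_frame0(coding)) {
      return(data.frame(kind = "V", start = start, end = end,
                        strand = if (plus) "+" else "-",
                        sequence = coding, score = hits23$score[i],
                        rss5_key = NA_character_,
                        rss3_key = .rss_key(hits23, i),
                        rss5_spacer = NA_integer_,
                        rss3_spacer = hits23$spacer_len[i]))
    }
  }
  NULL
}

# candidate J immediately 3' (coding orientation) of a 12-RSS heptamer:
# ends before the first splice-donor GT that yields a window in
# [min_j, max_j] containing the J anchor motif (F-G-x-G) in some frame
.j_candidate <- function(seq, L, hits12, i, params) {
  plus <- hits12$strand[i] == "-"  # away side right => segment on + strand
  if (plus) {
    j_start <- hits12$hept_end[i] + 1L
    ends <- seq(j_start + params$min_j - 1L, j_start + params$max_j - 1L)
    for (e in ends) {
      if (e + 2L > L) break
      if (substr(seq, e + 1L, e + 2L) != "GT") next
      coding <- substr(seq, j_start, e)
      if (.j_motif_any_frame(coding)) {
        return(data.frame(kind = "J", start = j_start, end = e,
                          strand = "+", sequence = coding,
                          score = hits12$score[i],
                          rss5_key = .rss_key(hits12, i),
                          rss3_key = NA_character_,
                          rss5_spacer = hits12$spacer_len[i],
                          rss3_spacer = NA_integer_))
      }
      break  # first qualifying donor only
    }
  } else {
    j_end <- hits12$hept_start[i] - 1L
    starts <- seq(j_end - params$min_j + 1L, j_end - params$max_j + 1L)
    for (s in starts) {
      if (s - 2L < 1L) break
      if (substr(seq, s - 2L, s - 1L) != "AC") next  # GT on minus strand
      coding <- revcomp(substr(seq, s, j_end))
      if (.j_motif_any_frame(coding)) {
        return(data.frame(kind = "J", start = s, end = j_end,
                          strand = "-", sequence = coding,
                          score = hits12$score[i],
                          rss5_key = .rss_key(hits12, i),
                          rss3_key = NA_character_,
                          rss5_spacer = hits12$spacer_len[i],
                          rss3_spacer = NA_integer_))
      }
      break
    }
  }
  NULL
}

# candidate D between a 12-RSS and a 23-RSS whose away sides face each other
.d_candidates <- function(seq, hits12, hits23, params) {
  out <- list()
  for (i in seq_len(nrow(hits12))) {
    for (k in seq_len(nrow(hits23))) {
      # plus-strand D: minus 12-hit on the left, plus 23-hit on the right
      if (hits12$strand[i] == "-" && hits23$strand[k] == "+") {
        d_start <- hits12$hept_end[i] + 1L
        d_end <- hits23$hept_start[k] - 1L
        strand <- "+"
      } else if (hits12$strand[i] == "+" && hits23$strand[k] == "-") {
        # minus-strand D: minus 23-hit on the left, plus 12-hit on the right
        d_start <- hits23$hept_end[k] + 1L
        d_end <- hits12$hept_start[i] - 1L
        strand <- "-"
      } else next
      len <- d_end - d_start + 1L
      if (is.na(len) || len < params$min_d || len > params$max_d) next
      coding <- substr(seq, d_start, d_end)
      if (strand == "-") coding <- revcomp(coding)
      out[[length(out) + 1]] <- data.frame(
        kind = "D", start = d_start, end = d_end, strand = strand,
        sequence = coding, score = hits12$score[i] + hits23$score[k],
        rss5_key = .rss_key(hits12, i), rss3_key = .rss_key(hits23, k),
        rss5_spacer = hits12$spacer_len[i],
        rss3_spacer = hits23$spacer_len[k])
    }
  }
  out
}

#' Call V, D, J and C gene segments from RSS hits
#'
#' Candidate segments are built around scanner hits (V: codon-aligned open
#' reading window 5' of a 23-RSS; J: window 3' of a 12-RSS ending before a
#' splice-donor GT and containing the F-G-x-G anchor; D: a short window
#' between a facing 12-RSS and 23-RSS), then resolved greedily by
#' descending combined RSS score with a leftmost tie-break. Each RSS
#' heptamer is consumed by at most one segment and accepted segments never
#' overlap; conflicting candidates are dropped with a logged note. C
#' regions are supplied externally (see [locate_c_regions()]).
#'
#' @param seq Locus nucleotide sequence.
#' @param hits12 `rss_hits` from a spacer-class-12 scan of `seq`.
#' @param hits23 `rss_hits` from a spacer-class-23 scan of `seq`.
#' @param c_regions Optional data.frame with columns `start`, `end` and
#'   optionally `strand` giving constant-region intervals.
#' @param params See [segment_params()].
#' @return A data.frame of class `gene_segments` with columns `name`
#'   (provisional, see [assign_names()]), `kind`, `start`, `end`, `strand`,
#'   `family`, `sequence` (coding orientation), RSS spacers and scores.
#' @export
call_segments <- function(seq, hits12, hits23, c_regions = NULL,
                          params = segment_params()) {
  stopifnot(length(seq) == 1)
  .check_nt(seq)
  L <- nchar(seq)

  cands <- list()
  for (i in seq_len(nrow(hits23))) {
    cands[[length(cands) + 1]] <- .v_candidate(seq, L, hits23, i, params)
  }
  for (i in seq_len(nrow(hits12))) {
    cands[[length(cands) + 1]] <- .j_candidate(seq, L, hits12, i, params)
  }
  cands <- c(cands, .d_candidates(seq, hits12, hits23, params))
  cands <- cands[!vapply(cands, is.null, NA)]

  accepted <- list()
  used_keys <- character(0)
  if (length(cands)) {
    df <- do.call(rbind, cands)
    # D candidates carry two RSS scores and outrank single-RSS candidates
    df <- df[order(-df$score, df$start), , drop = FALSE]
    occ_start <- integer(0); occ_end <- integer(0)
    if (!is.null(c_regions) && nrow(c_regions)) {
      occ_start <- c_regions$start; occ_end <- c_regions$end
    }
    for (r in seq_len(nrow(df))) {
      keys <- c(df$rss5_key[r], df$rss3_key[r])
      keys <- keys[!is.na(keys)]
      if (any(keys %in% used_keys)) next  # RSS already consumed (dedup)
      overlaps <- any(df$start[r] <= occ_end & df$end[r] >= occ_start)
      if (overlaps) {
        vdj_note("dropping ", df$kind[r], " candidate at [", df$start[r],
                 ", ", df$end[r], "]: overlaps an accepted segment")
        next
      }
      accepted[[length(accepted) + 1]] <- df[r, , drop = FALSE]
      used_keys <- c(used_keys, keys)
      occ_start <- c(occ_start, df$start[r])
      occ_end <- c(occ_end, df$end[r])
    }
  }

  seg <- if (length(accepted)) do.call(rbind, accepted) else data.frame(
    kind = character(0), start = integer(0), end = integer(0),
    strand = character(0), sequence = character(0), score = numeric(0),
    rss5_key = character(0), rss3_key = character(0),
    rss5_spacer = integer(0), rss3_spacer = integer(0))

  if (!is.null(c_regions) && nrow(c_regions)) {
    strand_c <- if ("strand" %in% names(c_regions)) c_regions$strand else "+"
    seqs_c <- substring(seq, c_regions$start, c_regions$end)
    minus <- strand_c == "-"
    if (any(minus)) seqs_c[minus] <- revcomp(seqs_c[minus])
    seg <- rbind(seg, data.frame(
      kind = "C", start = c_regions$start, end = c_regions$end,
      strand = strand_c, sequence = seqs_c, score = NA_real_,
      rss5_key = NA_character_, rss3_key = NA_character_,
      rss5_spacer = NA_integer_, rss3_spacer = NA_integer_))
  }

  seg <- seg[order(seg$start), , drop = FALSE]
  seg <- data.frame(name = sprintf("%s_%d", seg$kind, seg$start),
                    seg, family = rep(NA_integer_, nrow(seg)))
  rownames(seg) <- NULL
  class(seg) <- c("gene_segments", "data.frame")
  seg
}

#' Locate constant regions by fit alignment of known C sequences
#'
#' @param seq Locus nucleotide sequence.
#' @param c_db Named character vector of known constant-region nucleotide
#'   sequences (coding orientation).
#' @param min_identity Minimum percent identity to accept a placement.
#' @return A data.frame with columns `name`, `start`, `end`, `strand`.
#' @export
locate_c_regions <- function(seq, c_db, min_identity = 90) {
  out <- list()
  for (nm in names(c_db)) {
    best <- NULL
    for (strand in c("+", "-")) {
      target <- if (strand == "+") seq else revcomp(seq)
      al <- fit_align(c_db[[nm]], target)
      if (is.null(best) || al$score > best$al$score) {
        best <- list(al = al, strand = strand)
      }
    }
    al <- best$al
    if (is.na(al$identity_pct) || al$identity_pct < min_identity) next
    if (best$strand == "+") {
      start <- al$b_start; end <- al$b_end
    } else {
      L <- nchar(seq)
      start <- L - al$b_end + 1L; end <- L - al$b_start + 1L
    }
    out[[length(out) + 1]] <- data.frame(
      name = nm, start = start, end = end, strand = best$strand)
  }
  if (!length(out)) {
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  do.call(rbind, out)
}

#' Assign IMGT-style names to called segments
#'
#' Non-V segments are numbered 1..n in 5' to 3' locus order per kind
#' (a unique C is left unnumbered). V segments are named
#' `<prefix>V<family>.<member>` with members numbered 5' to 3' within each
#' family.
#'
#' @param segments A `gene_segments` data.frame (see [call_segments()]).
#' @param locus_prefix Locus prefix, e.g. `"TRB"`.
#' @param families A `family_assignment` (see [cluster_families()]) named
#'   by the segments' provisional V names; required when V segments are
#'   present.
#' @return The segments with final `name` and `family` columns.
#' @export
assign_names <- function(segments, locus_prefix = "TRB", families = NULL) {
  seg <- segments[order(segments$start), , drop = FALSE]
  for (kind in c("D", "J", "C")) {
    idx <- which(seg$kind == kind)
    if (!length(idx)) next
    if (kind == "C" && length(idx) == 1) {
      seg$name[idx] <- paste0(locus_prefix, "C")
    } else {
      seg$name[idx] <- paste0(locus_prefix, kind, seq_along(idx))
    }
  }
  v_idx <- which(seg$kind == "V")
  if (length(v_idx)) {
    if (is.null(families)) stop("V segments present but no families given")
    fam <- families[seg$name[v_idx]]
    if (any(is.na(fam))) {
      stop("missing family assignment for V segment: ",
           seg$name[v_idx][is.na(fam)][1])
    }
    seg$family[v_idx] <- as.integer(fam)
    for (f in unique(fam)) {
      members <- v_idx[fam == f]  # v_idx already in coordinate order
      seg$name[members] <- sprintf("%sV%d.%d", locus_prefix, f,
                                   seq_along(members))
    }
  }
  rownames(seg) <- NULL
  seg
}

#' Build an ordered locus map
#'
#' @param segments A named `gene_segments` data.frame.
#' @param flanking_genes Optional data.frame (`gene`, `start`, `end`,
#'   `side`) of annotated genes flanking the locus.
#' @param locus_name Display name.
#' @return A `locus_map`: ordered segments, locus span in bp, and per-kind
#'   counts.
#' @export
build_locus_map <- function(segments, flanking_genes = NULL,
                            locus_name = "locus") {
  seg <- segments[order(segments$start), , drop = FALSE]
  if (nrow(seg) == 0) stop("cannot map an empty segment set")
  if (nrow(seg) > 1) {
    ov <- which(seg$start[-1] <= seg$end[-nrow(seg)])
    if (length(ov)) {
      stop("overlapping segments: ",
           paste(sprintf("%s [%d,%d] / %s [%d,%d]", seg$name[ov],
                         seg$start[ov], seg$end[ov], seg$name[ov + 1],
                         seg$start[ov + 1], seg$end[ov + 1]),
                 collapse = "; "))
    }
  }
  structure(list(
    locus_name = locus_name,
    segments = seg,
    span_bp = max(seg$end) - min(seg$start) + 1L,
    flanking_genes = flanking_genes
  ), class = "locus_map")
}

#' Per-kind segment counts of a locus map
#'
#' @param map A `locus_map`.
#' @return Named integer vector with entries V, D, J, C.
#' @export
kind_counts <- function(map) {
  stopifnot(inherits(map, "locus_map"))
  tab <- table(factor(map$segments$kind, levels = c("V", "D", "J", "C")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Count inverted V segments
#'
#' Number of V segments whose strand differs from the majority strand of
#' the C segments (or of all segments, with a note, when no C is present).
#'
#' @param map A `locus_map` or `gene_segments` data.frame.
#' @return Integer count.
#' @export
count_inversions <- function(map) {
  seg <- if (inherits(map, "locus_map")) map$segments else map
  ref <- seg$strand[seg$kind == "C"]
  if (!length(ref)) {
    vdj_note("no C segment; using majority strand of all segments")
    ref <- seg$strand
  }
  majority <- if (sum(ref == "+") >= sum(ref == "-")) "+" else "-"
  sum(seg$kind == "V" & seg$strand != majority)
}

#' @export
print.locus_map <- function(x, ...) {
  counts <- kind_counts(x)
  cat(sprintf("locus map '%s': %d segments over %d bp\n", x$locus_name,
              nrow(x$segments), x$span_bp))
  cat(sprintf("  V: %d  D: %d  J: %d  C: %d  (inverted V: %d)\n",
              counts["V"], counts["D"], counts["J"], counts["C"],
              count_inversions(x)))
  invisible(x)
}

#' Export gene segments (and optionally RSS hits) as GFF3
#'
#' Feature types follow the Sequence Ontology: `V_gene_segment`,
#' `D_gene_segment`, `J_gene_segment`, `C_gene_segment` and
#' `recombination_signal_sequence`. Coordinates are 1-based inclusive.
#'
#' @param segments A `gene_segments` data.frame.
#' @param path Output path.
#' @param seqname Sequence (chromosome/scaffold) name.
#' @param hits Optional `rss_hits` to include.
#' @export
write_gff3 <- function(segments, path, seqname = "locus", hits = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(segments$start, segments$end),
    strand = segments$strand,
    type = paste0(segments$kind, "_gene_segment"),
    Name = segments$name)
  if (!is.null(hits) && nrow(hits)) {
    gr_h <- GenomicRanges::GRanges(
      seqnames = seqname,
      ranges = IRanges::IRanges(pmin(hits$hept_start, hits$non_start),
                                pmax(hits$hept_end, hits$non_end)),
      strand = hits$strand,
      type = "recombination_signal_sequence",
      Name = sprintf("RSS%d", hits$spacer_len))
    gr_h$score <- hits$score
    gr <- suppressWarnings(c(gr, gr_h))
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
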