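# Transcript-to-germline mapping and V(D)J rearrangement classification.
#
# A transcript is "complete at the 5' end" when its V alignment starts at
# the germline V's first nucleotide and covers at least 95% of it. A
# rearrangement is productive when it is complete, the V-to-C reading
# frame is preserved, and the junction region through the end of J
# encodes no stop codon.

round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  trunc(abs(x) * scale + 0.5) / scale * sign(x)
}

.best_fit <- function(query_db, transcript, min_identity) {
  best <- NULL
  tie <- FALSE
  for (nm in names(query_db)) {
    al <- local_align(query_db[[nm]], transcript)
    if (is.na(al$identity_pct) || al$identity_pct < min_identity) next
    if (is.null(best)) {
      best <- list(name = nm, al = al)
    } else if (al$score > best$al$score) {
      best <- list(name = nm, al = al); tie <- FALSE
    } else if (al$score == best$al$score) {
      tie <- TRUE  # keep the earlier (leftmost) germline entry
    }
  }
  if (!is.null(best)) best$tie <- tie
  best
}

.germline_db <- function(germline, kind) {
  if (is.data.frame(germline)) {
    keep <- germline$kind == kind
    return(stats::setNames(germline$sequence[keep], germline$name[keep]))
  }
  db <- germline[[kind]]
  if (is.null(db)) character(0) else db
}

#' Assign germline segments to a transcript
#'
#' The best fit alignment per segment kind with identity at or above
#' `min_identity` is assigned; V, J and C matches must appear in 5' to 3'
#' order on the transcript. The junction is the transcript substring
#' between the end of the V alignment and the start of the J alignment.
#' Transcripts without a C match are flagged unassigned.
#'
#' @param transcript A single nucleotide string, or a length-1 named
#'   character vector (the name becomes `transcript_id`).
#' @param germline Either a named `gene_segments` data.frame or a list
#'   with elements `V`, `D`, `J`, `C`, each a named character vector of
#'   germline nucleotide sequences in coding orientation.
#' @param min_identity Minimum percent identity for an assignment
#'   (default 90).
#' @param min_d_match Minimum exact-match length for D detection
#'   (see [detect_d()]).
#' @return A one-row data.frame (class `rearrangement_call`) with segment
#'   calls, junction, alignment anchors, and `complete_5p`; frame and
#'   productivity fields are completed by [classify_productivity()].
#' @export
assign_segments <- function(transcript, germline, min_identity = 90,
                            min_d_match = 8) {
  id <- if (!is.null(names(transcript))) names(transcript)[1] else "transcript"
  tr <- unname(transcript[1])
  .check_nt(tr, "transcript")

  v_db <- .germline_db(germline, "V")
  j_db <- .germline_db(germline, "J")
  c_db <- .germline_db(germline, "C")
  d_db <- .germline_db(germline, "D")
  if (!length(v_db) && !length(c_db)) stop("empty germline database")

  cc <- .best_fit(c_db, tr, min_identity)
  vv <- .best_fit(v_db, tr, min_identity)
  jj <- .best_fit(j_db, tr, min_identity)
  if (!is.null(vv) && isTRUE(vv$tie)) {
    vdj_note("transcript ", id, ": tied V scores, keeping leftmost germline entry")
  }

  # enforce 5' -> 3' ordering of V, J, C on the transcript; trailing
  # trimmed query ends may overrun a few nt into the next region, so the
  # test is on the spans' order, not strict non-overlap
  if (!is.null(vv) && !is.null(jj) &&
      (jj$al$b_start <= vv$al$b_start || jj$al$b_end <= vv$al$b_end)) {
    jj <- NULL
  }
  if (!is.null(jj) && !is.null(cc) && cc$al$b_start <= jj$al$b_start) jj <- NULL
  if (!is.null(vv) && !is.null(cc) && cc$al$b_start <= vv$al$b_start) vv <- NULL

  complete_5p <- FALSE
  if (!is.null(vv)) {
    v_len <- nchar(v_db[[vv$name]])
    complete_5p <- vv$al$a_start == 1 &&
      (vv$al$a_end - vv$al$a_start + 1) / v_len >= 0.95
  }

  junction <- NA_character_
  if (!is.null(vv) && !is.null(jj)) {
    junction <- if (jj$al$b_start >= vv$al$b_end + 1) {
      substr(tr, vv$al$b_end + 1, jj$al$b_start - 1)
    } else ""  # overlapping trail alignments leave no junction evidence
  }
  d_name <- NA_character_
  if (!is.na(junction) && nzchar(junction) && length(d_db)) {
    d_name <- detect_d(junction, d_db, min_match = min_d_match)
  }

  call <- data.frame(
    transcript_id = id,
    v_name = if (is.null(vv)) NA_character_ else vv$name,
    d_name = d_name,
    j_name = if (is.null(jj)) NA_character_ else jj$name,
    c_name = if (is.null(cc)) NA_character_ else cc$name,
    junction = junction,
    complete_5p = complete_5p,
    in_frame = NA, has_stop = NA, productive = FALSE,
    v_q_start = if (is.null(vv)) NA_integer_ else vv$al$a_start,
    v_q_end = if (is.null(vv)) NA_integer_ else vv$al$a_end,
    v_t_start = if (is.null(vv)) NA_integer_ else vv$al$b_start,
    v_t_end = if (is.null(vv)) NA_integer_ else vv$al$b_end,
    j_t_end = if (is.null(jj)) NA_integer_ else jj$al$b_end,
    c_q_start = if (is.null(cc)) NA_integer_ else cc$al$a_start,
    c_t_start = if (is.null(cc)) NA_integer_ else cc$al$b_start,
    unassigned = is.null(cc))
  class(call) <- c("rearrangement_call", "data.frame")
  call
}

#' Detect D segment evidence in a junction
#'
#' Longest exact substring shared between the junction and any germline D
#' segment, reported when at least `min_match` nt long. Ties are broken by
#' longer match, then by the 5'-most (first listed) D.
#'
#' @param junction_nt Junction nucleotide string.
#' @param d_segments Named character vector of germline D sequences.
#' @param min_match Minimum match length (default 8).
#' @return The matching D name, or `NA` if none qualifies.
#' @export
detect_d <- function(junction_nt, d_segments, min_match = 8) {
  if (is.na(junction_nt) || !nzchar(junction_nt) || !length(d_segments)) {
    return(NA_character_)
  }
  best_name <- NA_character_
  best_len <- min_match - 1L
  for (nm in names(d_segments)) {
    d <- d_segments[[nm]]
    max_k <- min(nchar(junction_nt), nchar(d))
    for (k in seq(max_k, 1)) {
      if (k <= best_len) break
      subs <- unique(substring(junction_nt, seq_len(nchar(junction_nt) - k + 1),
                               seq_len(nchar(junction_nt) - k + 1) + k - 1))
      if (any(vapply(subs, function(s) grepl(s, d, fixed = TRUE), NA))) {
        best_len <- k
        best_name <- nm
        break
      }
    }
  }
  best_name
}

#' Classify reading frame and productivity of a rearrangement
#'
#' The reading frame is anchored on the germline V's codon frame at the V
#' alignment start: with V and C "virtual starts" (transcript coordinate
#' of germline position 1, extrapolated), the rearrangement is in frame
#' when their distance is a multiple of 3. `has_stop` scans the V-frame
#' translation from the V alignment start through the end of the J
#' alignment. Productive requires complete, in frame and stop free.
#'
#' @param call A `rearrangement_call` from [assign_segments()].
#' @param transcript The transcript sequence used for the call.
#' @return The call with `in_frame`, `has_stop` and `productive` set.
#' @export
classify_productivity <- function(call, transcript) {
  tr <- unname(transcript[1])
  if (is.na(call$v_name) || is.na(call$c_name)) {
    call$productive <- FALSE
    return(call)
  }
  virtual_v <- call$v_t_start - (call$v_q_start - 1L)
  virtual_c <- call$c_t_start - (call$c_q_start - 1L)
  call$in_frame <- ((virtual_c - virtual_v) %% 3L) == 0L

  scan_end <- if (!is.na(call$j_t_end)) call$j_t_end else call$c_t_start - 1L
  # first codon boundary of the V frame at or after the V alignment start
  t0 <- call$v_t_start + ((3L - ((call$v_q_start - 1L) %% 3L)) %% 3L)
  call$has_stop <- if (scan_end >= t0 + 2L) {
    grepl("*", translate_nt(substr(tr, t0, scan_end)), fixed = TRUE)
  } else FALSE

  call$productive <- isTRUE(call$complete_5p && call$in_frame &&
                              !call$has_stop)
  call
}

#' Classify a set of transcripts against a germline database
#'
#' Convenience wrapper running [assign_segments()] and
#' [classify_productivity()] over a transcript collection.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param germline See [assign_segments()].
#' @param min_identity Minimum percent identity per assignment.
#' @return A data.frame of rearrangement calls, one row per transcript,
#'   with AIRR-style columns.
#' @export
classify_rearrangements <- function(transcripts, germline,
                                    min_identity = 90) {
  calls <- lapply(names(transcripts), function(id) {
    call <- assign_segments(stats::setNames(transcripts[id], id), germline,
                            min_identity = min_identity)
    classify_productivity(call, transcripts[[id]])
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Summarize repertoire completeness and productivity
#'
#' @param calls A data.frame of rearrangement calls.
#' @return A `repertoire_summary`: totals, counts and percentages
#'   (`pct_complete` of all transcripts; `pct_productive_of_complete` of
#'   complete ones), rounded half-up to one decimal.
#' @export
summarize_repertoire <- function(calls) {
  n_total <- nrow(calls)
  n_complete <- if (n_total) sum(calls$complete_5p, na.rm = TRUE) else 0L
  n_productive <- if (n_total) sum(calls$productive, na.rm = TRUE) else 0L
  structure(list(
    n_total = n_total,
    n_complete = n_complete,
    n_productive = n_productive,
    pct_complete = if (n_total > 0) {
      round_half_up(100 * n_complete / n_total)
    } else 0,
    pct_productive_of_complete = if (n_complete > 0) {
      round_half_up(100 * n_productive / n_complete)
    } else 0
  ), class = "repertoire_summary")
}

#' @export
print.repertoire_summary <- function(x, ...) {
  cat(sprintf("repertoire: %d transcripts\n", x$n_total))
  cat(sprintf("  complete at 5' end: %d (%.1f%%)\n", x$n_complete,
              x$pct_complete))
  cat(sprintf("  productive of complete: %d (%.1f%%)\n", x$n_productive,
              x$pct_productive_of_complete))
  invisible(x)
}

#' Write per-transcript rearrangement calls as TSV
#'
#' Columns follow AIRR naming: `sequence_id`, `v_call`, `d_call`,
#' `j_call`, `c_call`, `junction`, `productive`, `complete`.
#'
#' @param calls A data.frame of rearrangement calls.
#' @param path Output path.
#' @export
write_repertoire_tsv <- function(calls, path) {
  out <- data.frame(
    sequence_id = calls$transcript_id, v_call = calls$v_name,
    d_call = calls$d_name, j_call = calls$j_name, c_call = calls$c_name,
    junction = calls$junction, productive = calls$productive,
    complete = calls$complete_5p)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
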