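# Ground-truthed synthetic TCR loci and simulated V(D)J repertoires.
#
# The generator emits a locus with the canonical architecture: V segments
# (23-RSS), D segments (12-RSS on the V-proximal side, 23-RSS on the
# C-proximal side), J segments (12-RSS, splice-donor GT), one or more C
# regions with a planted transmembrane exon, and optionally inverted V
# segments 3' of C on the minus strand. Truth tables record every planted
# coordinate so annotator output can be checked exactly.

# stop codons in all three reading frames; placed immediately 5' of each
# V segment so the V's open reading window has an unambiguous start
.FRAME_GUARD <- "TAAATAAATAA"

.STOPS <- c("TAA", "TAG", "TGA")
.ALL_CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"), paste0),
                               c("A", "C", "G", "T"), paste0))
.NONSTOP_CODONS <- setdiff(.ALL_CODONS, .STOPS)
# codons free of the GT dinucleotide and not starting with T: strings of
# such codons can never contain GT, even across codon boundaries
.GTFREE_CODONS <- setdiff(
  .NONSTOP_CODONS[!grepl("GT", .NONSTOP_CODONS) &
                    !startsWith(.NONSTOP_CODONS, "T")],
  .STOPS)
.GTFREE_NO_G_END <- .GTFREE_CODONS[!endsWith(.GTFREE_CODONS, "G")]

.rand_nt <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.rand_orf <- function(n_codons) {
  paste(sample(.NONSTOP_CODONS, n_codons, replace = TRUE), collapse = "")
}

.rand_int <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  sample(seq(range[1], range[2]), 1)
}

# J segment: GT-free codon string with the F-G-x-G anchor planted near the
# 3' end (encoded TTT GGA CAA GGA, itself GT-free), so the first
# splice-donor GT at plausible J length is the planted donor
.make_j <- function(n_aa) {
  stopifnot(n_aa >= 10)
  k1 <- n_aa - 6
  pre <- if (k1 > 0) {
    c(if (k1 > 1) sample(.GTFREE_CODONS, k1 - 1, replace = TRUE),
      sample(.GTFREE_NO_G_END, 1))  # no G before the motif's leading T
  } else character(0)
  tail <- sample(.GTFREE_CODONS, 2, replace = TRUE)
  paste(c(pre, "TTTGGACAAGGA", tail), collapse = "")
}

.AA_CODONS <- split(names(Biostrings::GENETIC_CODE),
                    unname(Biostrings::GENETIC_CODE))

.encode_aa <- function(aa) {
  chars <- strsplit(aa, "")[[1]]
  paste(vapply(chars, function(a) sample(.AA_CODONS[[a]], 1), ""),
        collapse = "")
}

# constant region: extracellular stretch, a 19-residue hydrophobic
# transmembrane core carrying the requested charged residues, short tail
.make_c_nt <- function(chain_class = "K_only", n_ext = 55, n_tail = 15) {
  polar <- c("D", "E", "N", "Q", "S", "T", "G", "P", "H")
  hydro <- c("I", "L", "F", "M", "V", "A")
  core <- sample(hydro, 19, replace = TRUE)
  if (chain_class %in% c("RK")) core[5] <- "R"
  if (chain_class %in% c("RK", "K_only")) core[12] <- "K"
  aa <- c(sample(polar, n_ext, replace = TRUE), core,
          sample(polar, n_tail, replace = TRUE))
  .encode_aa(paste(aa, collapse = ""))
}

#' Synthetic locus configuration
#'
#' Defaults reproduce the architecture of a skink-like TRB locus: 15 V
#' segments in 8 families (one inverted, 3' of C), 3 D, 6 J and a single
#' C.
#'
#' @param n_v,n_d,n_j,n_c Segment counts.
#' @param n_families Number of V families (capped at `n_v`).
#' @param within_family_identity Target pairwise percent identity within a
#'   family (members are mutated from a family prototype to hit it within
#'   about 3 points).
#' @param between_family_identity Maximum pairwise identity tolerated
#'   between family prototypes.
#' @param n_inverted_v V segments emitted in inverted orientation 3' of C.
#' @param intersegment_gap Range (bp) of intergenic gaps.
#' @param v_len,d_len,j_len Segment length ranges in nt (V lengths are
#'   rounded to codon multiples).
#' @param noncanonical_heptamer Use the functional non-canonical heptamer
#'   CACAGCA instead of CACAGTG.
#' @param seed Integer seed; output is byte-reproducible given the config.
#' @return A `locus_config` list.
#' @export
locus_config <- function(n_v = 15, n_d = 3, n_j = 6, n_c = 1,
                         n_families = 8, within_family_identity = 88,
                         between_family_identity = 70, n_inverted_v = 1,
                         intersegment_gap = c(150, 400),
                         v_len = c(279, 321), d_len = c(12, 16),
                         j_len = c(36, 60),
                         noncanonical_heptamer = FALSE, seed = 1) {
  stopifnot(n_v >= 1, n_j >= 1, n_c >= 1, n_d >= 0,
            n_inverted_v <= n_v,
            within_family_identity > between_family_identity,
            within_family_identity <= 100, between_family_identity > 0)
  structure(list(
    n_v = n_v, n_d = n_d, n_j = n_j, n_c = n_c,
    n_families = min(n_families, n_v),
    within_family_identity = within_family_identity,
    between_family_identity = between_family_identity,
    n_inverted_v = n_inverted_v, intersegment_gap = intersegment_gap,
    v_len = v_len, d_len = d_len, j_len = j_len,
    noncanonical_heptamer = noncanonical_heptamer, seed = seed
  ), class = "locus_config")
}

.mutate_keep_orf <- function(seq, n_sub) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  # repair any stop codon introduced into frame 0
  n_codon <- length(chars) %/% 3
  for (k in seq_len(n_codon)) {
    idx <- (3 * k - 2):(3 * k)
    if (paste(chars[idx], collapse = "") %in% .STOPS) {
      chars[idx] <- strsplit(sample(.NONSTOP_CODONS, 1), "")[[1]]
    }
  }
  paste(chars, collapse = "")
}

.make_v_families <- function(cfg) {
  n_fam <- cfg$n_families
  sizes <- rep(cfg$n_v %/% n_fam, n_fam)
  extra <- cfg$n_v %% n_fam
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  protos <- character(n_fam)
  for (f in seq_len(n_fam)) {
    len <- 3 * (.rand_int(cfg$v_len) %/% 3)
    ok <- FALSE
    for (try in 1:30) {
      cand <- .rand_orf(len %/% 3)
      if (f == 1) { ok <- TRUE; protos[f] <- cand; break }
      ids <- vapply(protos[seq_len(f - 1)], function(p)
        global_align(cand, p)$identity_pct, 0)
      if (all(ids <= cfg$between_family_identity)) {
        ok <- TRUE; protos[f] <- cand; break
      }
    }
    if (!ok) stop("infeasible identity targets: could not generate a ",
                  "family prototype below ", cfg$between_family_identity,
                  "% identity to the others")
  }
  members <- list()
  for (f in seq_len(n_fam)) {
    L <- nchar(protos[f])
    n_sub <- max(1, round(L * (100 - cfg$within_family_identity) / 200))
    for (try in 1:10) {
      fam_members <- vapply(seq_len(sizes[f]), function(i)
        .mutate_keep_orf(protos[f], n_sub), "")
      if (sizes[f] < 2) break
      pid <- utils::combn(fam_members, 2, function(p)
        global_align(p[1], p[2])$identity_pct)
      if (all(abs(pid - cfg$within_family_identity) <= 3)) break
      if (try == 10) stop("infeasible identity targets: within-family ",
                          "identity did not converge")
    }
    members[[f]] <- fam_members
  }
  list(members = members, sizes = sizes)
}

#' Generate a synthetic TCR locus with ground truth
#'
#' See [locus_config()] for the tunable architecture. Each V segment is a
#' codon-aligned open reading window preceded by a short all-frame stop
#' guard (so its boundary is sequence-identifiable) and followed by a
#' 23-RSS; D segments carry facing 12- and 23-RSS; J segments follow a
#' 12-RSS and end at a splice-donor GT with the F-G-x-G anchor encoded
#' near their 3' end; the C region encodes a transmembrane exon with a
#' single Lys (K_only chain class). Intergenic gaps are i.i.d. uniform
#' nucleotides.
#'
#' @param cfg A `locus_config`.
#' @return A list of class `synthetic_locus`: `id`, `sequence`, `truth`
#'   (data.frame: name, kind, start, end, strand, family, sequence) and
#'   `config`.
#' @export
generate_locus <- function(cfg = locus_config()) {
  stopifnot(inherits(cfg, "locus_config"))
  withr::with_seed(cfg$seed, .generate_locus_impl(cfg))
}

.generate_locus_impl <- function(cfg) {
  hept <- if (cfg$noncanonical_heptamer) "CACAGCA" else
    RSS_HEPTAMER_CONSENSUS
  non <- RSS_NONAMER_CONSENSUS

  fams <- .make_v_families(cfg)
  v_pool <- data.frame(
    family = rep(seq_along(fams$sizes), fams$sizes),
    sequence = unlist(fams$members))
  v_pool <- v_pool[sample(nrow(v_pool)), , drop = FALSE]
  n_fwd <- cfg$n_v - cfg$n_inverted_v

  d_seqs <- character(cfg$n_d)
  if (cfg$n_d >= 1) {
    len1 <- max(12, .rand_int(cfg$d_len))
    d_seqs[1] <- paste0("GGGACAGGGGGC", .rand_nt(len1 - 12))
    for (k in seq_len(cfg$n_d)[-1]) d_seqs[k] <- .rand_nt(.rand_int(cfg$d_len))
  }
  j_seqs <- vapply(seq_len(cfg$n_j), function(k) {
    n_aa <- max(12, .rand_int(cfg$j_len) %/% 3)
    .make_j(n_aa)
  }, "")
  c_seqs <- vapply(seq_len(cfg$n_c), function(k) .make_c_nt("K_only"), "")

  parts <- character(0)
  pos <- 0L
  truth <- list()
  emit <- function(s) {
    parts[[length(parts) + 1]] <<- s
    pos <<- pos + nchar(s)
  }
  record <- function(kind, coding, strand, family = NA_integer_) {
    truth[[length(truth) + 1]] <<- data.frame(
      kind = kind, start = pos - nchar(coding) + 1L, end = pos,
      strand = strand, family = family, sequence = coding)
  }
  gap <- function() emit(.rand_nt(.rand_int(cfg$intersegment_gap)))

  gap()
  for (i in seq_len(n_fwd)) {
    emit(.FRAME_GUARD)
    emit(v_pool$sequence[i]); record("V", v_pool$sequence[i], "+",
                                     v_pool$family[i])
    emit(hept); emit(.rand_nt(23)); emit(non)
    gap()
  }
  for (d in d_seqs) {
    emit(revcomp(non)); emit(.rand_nt(12)); emit(revcomp(hept))
    emit(d); record("D", d, "+")
    emit(hept); emit(.rand_nt(23)); emit(non)
    gap()
  }
  for (j in j_seqs) {
    emit(revcomp(non)); emit(.rand_nt(12)); emit(revcomp(hept))
    emit(j); record("J", j, "+")
    emit("GT")
    gap()
  }
  for (cc in c_seqs) {
    emit(cc); record("C", cc, "+")
    gap()
  }
  if (cfg$n_inverted_v > 0) {
    for (i in seq(n_fwd + 1, cfg$n_v)) {
      emit(revcomp(non)); emit(.rand_nt(23)); emit(revcomp(hept))
      emit(revcomp(v_pool$sequence[i]))
      record("V", v_pool$sequence[i], "-", v_pool$family[i])
      emit(revcomp(.FRAME_GUARD))
      gap()
    }
  }

  seq <- paste(parts, collapse = "")
  truth <- do.call(rbind, truth)

  # canonical family labels: ordered by each family's 5'-most member
  v_rows <- which(truth$kind == "V")
  first_pos <- tapply(truth$start[v_rows], truth$family[v_rows], min)
  relabel <- stats::setNames(rank(first_pos, ties.method = "first"),
                             names(first_pos))
  truth$family[v_rows] <-
    as.integer(relabel[as.character(truth$family[v_rows])])

  # IMGT-style names matching assign_names() conventions
  truth$name <- NA_character_
  for (kind in c("D", "J", "C")) {
    idx <- which(truth$kind == kind)
    if (!length(idx)) next
    truth$name[idx] <- if (kind == "C" && length(idx) == 1) "TRBC" else
      paste0("TRB", kind, seq_along(idx))
  }
  for (f in unique(truth$family[v_rows])) {
    members <- v_rows[truth$family[v_rows] == f]
    truth$name[members] <- sprintf("TRBV%d.%d", f, seq_along(members))
  }
  truth <- truth[, c("name", "kind", "start", "end", "strand", "family",
                     "sequence")]

  structure(list(
    id = sprintf("synthetic_locus_seed%d", cfg$seed),
    sequence = seq, truth = truth, config = cfg
  ), class = "synthetic_locus")
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat(sprintf("synthetic locus '%s': %d bp, %d planted segments\n",
              x$id, nchar(x$sequence), nrow(x$truth)))
  print(table(x$truth$kind))
  invisible(x)
}

#' Repertoire simulation configuration
#'
#' The completeness and productive fractions are realized exactly (up to
#' rounding) by stratified allocation over transcripts, so configured
#' targets are recovered without binomial noise; defaults mirror a spleen
#' transcriptome composition of 52.6% 5'-complete transcripts of which
#' 80% are productive.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param trim_max_v,trim_max_d,trim_max_j Maximum exonuclease trimming
#'   (nt) at each coding end; trims are uniform on `0..max`.
#' @param n_addition_max Maximum non-templated N nucleotides per junction
#'   side (frame forcing may add up to 2 more).
#' @param target_frame_fraction Fraction of 5'-complete transcripts given
#'   a frame-preserving, stop-free junction (hence productive).
#' @param incomplete_5p_fraction Fraction of transcripts truncated within
#'   V at the 5' end.
#' @param allow_vj_direct Permit direct V-to-J joins when D segments
#'   exist (otherwise every transcript uses a D, per the 12/23 rule).
#' @param seed Integer seed.
#' @return A `recombination_config` list.
#' @export
recombination_config <- function(n_transcripts = 100, trim_max_v = 6,
                                 trim_max_d = 4, trim_max_j = 6,
                                 n_addition_max = 6,
                                 target_frame_fraction = 0.8,
                                 incomplete_5p_fraction = 0.474,
                                 allow_vj_direct = FALSE, seed = 1) {
  stopifnot(n_transcripts >= 1,
            target_frame_fraction >= 0, target_frame_fraction <= 1,
            incomplete_5p_fraction >= 0, incomplete_5p_fraction <= 1)
  structure(list(
    n_transcripts = n_transcripts, trim_max_v = trim_max_v,
    trim_max_d = trim_max_d, trim_max_j = trim_max_j,
    n_addition_max = n_addition_max,
    target_frame_fraction = target_frame_fraction,
    incomplete_5p_fraction = incomplete_5p_fraction,
    allow_vj_direct = allow_vj_direct, seed = seed
  ), class = "recombination_config")
}

#' Simulate V(D)J-recombined transcripts from a locus
#'
#' Per transcript: uniform V, D, J choice with the 12/23 rule enforced
#' (V joins D, D joins J; direct V-J joins only when configured), uniform
#' exonuclease trims, uniform N additions. Junction length is adjusted to
#' realize the configured in-frame fraction; frame-preserving junctions
#' are additionally resampled until stop free, so the configured fraction
#' is the productive fraction. Truth flags are computed by construction.
#'
#' @param locus A `synthetic_locus` (see [generate_locus()]), or any list
#'   with `truth` and `sequence`.
#' @param cfg A `recombination_config`.
#' @return A list of class `synthetic_repertoire`: `transcripts` (named
#'   character vector) and `truth` (per-transcript data.frame with v/d/j/c
#'   names, trims, additions, `complete_5p`, `in_frame`, `has_stop`,
#'   `productive`, `junction`).
#' @export
simulate_repertoire <- function(locus, cfg = recombination_config()) {
  stopifnot(inherits(cfg, "recombination_config"))
  truth <- locus$truth
  if (!any(truth$kind == "V") || !any(truth$kind == "J") ||
      !any(truth$kind == "C")) {
    stop("locus must contain at least one V, J and C segment")
  }
  withr::with_seed(cfg$seed, .simulate_repertoire_impl(truth, cfg))
}

.simulate_repertoire_impl <- function(truth, cfg) {
  pick_db <- function(kind) truth[truth$kind == kind, , drop = FALSE]
  vs <- pick_db("V"); ds <- pick_db("D"); js <- pick_db("J")
  cs <- pick_db("C")

  n <- cfg$n_transcripts
  n_complete <- round((1 - cfg$incomplete_5p_fraction) * n)
  n_productive <- round(cfg$target_frame_fraction * n_complete)
  status <- sample(c(rep("productive", n_productive),
                     rep("out_of_frame", n_complete - n_productive),
                     rep("incomplete", n - n_complete)))

  rows <- vector("list", n)
  transcripts <- character(n)
  for (t in seq_len(n)) {
    vi <- sample(nrow(vs), 1); ji <- sample(nrow(js), 1)
    ci <- sample(nrow(cs), 1)
    use_d <- nrow(ds) > 0 &&
      (!cfg$allow_vj_direct || sample(c(TRUE, FALSE), 1))
    di <- if (use_d) sample(nrow(ds), 1) else NA_integer_
    v_nt <- vs$sequence[vi]; j_nt <- js$sequence[ji]
    c_nt <- cs$sequence[ci]
    Lv <- nchar(v_nt); Lj <- nchar(j_nt)
    vt <- sample(0:cfg$trim_max_v, 1)
    force_frame <- status[t] == "productive"

    for (attempt in 1:200) {
      jt <- sample(0:cfg$trim_max_j, 1)
      d5 <- if (use_d) sample(0:cfg$trim_max_d, 1) else 0L
      d3 <- if (use_d) sample(0:cfg$trim_max_d, 1) else 0L
      d_nt <- if (use_d) {
        full <- ds$sequence[di]
        if (d5 + d3 >= nchar(full)) next
        substr(full, d5 + 1, nchar(full) - d3)
      } else ""
      n1 <- sample(0:cfg$n_addition_max, 1)
      n2 <- sample(0:cfg$n_addition_max, 1)
      len_pre_c <- (Lv - vt) + n1 + nchar(d_nt) + n2 + (Lj - jt)
      if (force_frame) {
        n2 <- n2 + (3 - len_pre_c %% 3) %% 3
      } else if (len_pre_c %% 3 == 0) {
        n2 <- n2 + sample(1:2, 1)
      }
      N1 <- .rand_nt(n1); N2 <- .rand_nt(n2)
      pre_c <- paste0(substr(v_nt, 1, Lv - vt), N1, d_nt, N2,
                      substr(j_nt, jt + 1, Lj))
      has_stop <- grepl("*", translate_nt(pre_c), fixed = TRUE)
      if (!force_frame || !has_stop) break
    }
    in_frame <- nchar(pre_c) %% 3 == 0
    whole <- paste0(pre_c, c_nt)

    complete <- status[t] != "incomplete"
    if (!complete) {
      cut <- .rand_int(c(round(0.15 * Lv), round(0.5 * Lv)))
      whole <- substr(whole, cut + 1, nchar(whole))
    }
    id <- sprintf("tx%04d", t)
    transcripts[t] <- whole
    names(transcripts)[t] <- id
    rows[[t]] <- data.frame(
      transcript_id = id, v_name = vs$name[vi],
      d_name = if (use_d) ds$name[di] else NA_character_,
      j_name = js$name[ji], c_name = cs$name[ci],
      v_trim = vt, d5_trim = d5, d3_trim = d3, j_trim = jt,
      n1 = nchar(N1), n2 = nchar(N2),
      junction = paste0(N1, d_nt, N2),
      complete_5p = complete, in_frame = in_frame, has_stop = has_stop,
      productive = complete && in_frame && !has_stop)
  }
  structure(list(transcripts = transcripts,
                 truth = do.call(rbind, rows), config = cfg),
            class = "synthetic_repertoire")
}

#' Generate a synthetic chain with a requested transmembrane charge class
#'
#' A 120-residue amino-acid sequence with a 19-residue hydrophobic core
#' in a polar background, carrying the requested conserved charged
#' residues (Arg and/or Lys) inside the core.
#'
#' @param chain_class `"RK"`, `"K_only"` or `"none"`.
#' @param seed Integer seed.
#' @return A single amino-acid string.
#' @export
generate_tm_chain <- function(chain_class = c("RK", "K_only", "none"),
                              seed = 1) {
  chain_class <- match.arg(chain_class)
  withr::with_seed(seed, {
    polar <- c("D", "E", "N", "Q", "S", "T", "G", "P", "H")
    hydro <- c("I", "L", "F", "M", "V", "A")
    core <- sample(hydro, 19, replace = TRUE)
    if (chain_class == "RK") core[5] <- "R"
    if (chain_class %in% c("RK", "K_only")) core[12] <- "K"
    aa <- c(sample(polar, 60, replace = TRUE), core,
            sample(polar, 41, replace = TRUE))
    paste(aa, collapse = "")
  })
}
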