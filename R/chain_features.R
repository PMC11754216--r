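# Constant-region transmembrane detection and charge-asymmetry pairing.
#
# TCR heterodimer chains carry conserved charged residues (Arg, Lys) in
# their transmembrane regions with an asymmetric pattern: one chain of a
# functional pair has both Arg and Lys, the partner a single Lys. The TM
# region is located with a Kyte-Doolittle hydropathy sliding window.

#' Kyte-Doolittle hydropathy scale
#' @format Named numeric vector over the 20 standard amino acids.
#' @export
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

.hydropathy <- function(aa_chars) {
  h <- KYTE_DOOLITTLE[aa_chars]
  h[is.na(h)] <- 0  # X and other non-standard residues are neutral
  unname(h)
}

#' Locate a transmembrane region by hydropathy window
#'
#' Finds the window of `window` residues maximizing mean Kyte-Doolittle
#' hydropathy (leftmost on ties), then extends it one residue at a time
#' on whichever side has the higher positive hydropathy, up to `max_len`
#' residues. No TM is reported when the best window mean is below
#' `min_hydropathy`.
#'
#' @param aa_seq Amino-acid string of length at least `window`.
#' @param window Window width in residues (default 19).
#' @param min_hydropathy Minimum mean hydropathy to call a TM
#'   (default 1.5).
#' @param max_len Maximum extended TM length (default 25).
#' @return Integer vector `c(start, end)` (1-based, inclusive), or `NULL`
#'   when no TM is found.
#' @export
find_tm <- function(aa_seq, window = 19, min_hydropathy = 1.5,
                    max_len = 25) {
  chars <- strsplit(aa_seq, "")[[1]]
  n <- length(chars)
  if (n < window) stop("sequence shorter than the hydropathy window")
  h <- .hydropathy(chars)
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  best <- which.max(means)  # leftmost maximum
  if (means[best] < min_hydropathy) return(NULL)
  start <- best
  end <- best + window - 1L
  while (end - start + 1L < max_len) {
    left <- if (start > 1) h[start - 1] else -Inf
    right <- if (end < n) h[end + 1] else -Inf
    if (left <= 0 && right <= 0) break
    if (left >= right) start <- start - 1L else end <- end + 1L
  }
  c(start = start, end = as.integer(end))
}

#' Classify a chain by charged residues in its transmembrane region
#'
#' @param aa_seq Amino-acid string.
#' @param ... Passed to [find_tm()].
#' @return A `tm_annotation`: the TM interval, the Arg/Lys positions
#'   inside it, and `chain_class` -- `"RK"` (both Arg and Lys), `"K_only"`
#'   (Lys only), or `"none"` (no charged residue or no TM found).
#' @export
classify_chain <- function(aa_seq, ...) {
  tm <- find_tm(aa_seq, ...)
  if (is.null(tm)) {
    return(structure(list(aa_seq = aa_seq, tm_start = NA_integer_,
                          tm_end = NA_integer_,
                          charged = data.frame(pos = integer(0),
                                               residue = character(0)),
                          chain_class = "none"),
                     class = "tm_annotation"))
  }
  chars <- strsplit(aa_seq, "")[[1]]
  pos <- seq(tm[["start"]], tm[["end"]])
  charged_idx <- pos[chars[pos] %in% c("R", "K")]
  charged <- data.frame(pos = charged_idx, residue = chars[charged_idx])
  residues <- unique(charged$residue)
  chain_class <- if (all(c("R", "K") %in% residues)) "RK"
    else if (identical(residues, "K")) "K_only"
    else "none"
  structure(list(aa_seq = aa_seq, tm_start = tm[["start"]],
                 tm_end = tm[["end"]], charged = charged,
                 chain_class = chain_class),
            class = "tm_annotation")
}

#' @export
print.tm_annotation <- function(x, ...) {
  if (is.na(x$tm_start)) {
    cat("tm annotation: no transmembrane region found\n")
  } else {
    cat(sprintf("tm annotation: TM [%d, %d], class %s", x$tm_start,
                x$tm_end, x$chain_class))
    if (nrow(x$charged)) {
      cat(" (", paste0(x$charged$residue, x$charged$pos, collapse = ", "),
          ")", sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' Predict heterodimer pairing compatibility
#'
#' Two chains are predicted compatible when their transmembrane charge
#' classes realize the conserved asymmetric pattern: one chain with both
#' Arg and Lys, the partner with a single Lys.
#'
#' @param a,b `tm_annotation` objects (see [classify_chain()]).
#' @return `"compatible"` or `"incompatible"`.
#' @export
predict_pairing <- function(a, b) {
  stopifnot(inherits(a, "tm_annotation"), inherits(b, "tm_annotation"))
  if (setequal(c(a$chain_class, b$chain_class), c("RK", "K_only"))) {
    "compatible"
  } else {
    "incompatible"
  }
}

#' Check for the conserved D-segment nucleotide motif
#'
#' Tests for an exact occurrence of the vertebrate-conserved TRBD core
#' sequence GGGACAGGGGGC.
#'
#' @param d_seq Nucleotide string.
#' @return Logical.
#' @export
check_d_motif <- function(d_seq) {
  grepl("GGGACAGGGGGC", d_seq, fixed = TRUE)
}

#' Check for the J-region F-G-x-G anchor motif
#'
#' @param j_aa Amino-acid string.
#' @return Logical.
#' @export
check_j_motif <- function(j_aa) {
  grepl("FG.G", j_aa)
}

#' Write a chain-feature report as TSV
#'
#' @param chains Named character vector of amino-acid chain sequences.
#' @param path Output path.
#' @param ... Passed to [classify_chain()].
#' @return The per-chain report data.frame, invisibly.
#' @export
write_chain_report <- function(chains, path, ...) {
  rows <- lapply(names(chains), function(nm) {
    ann <- classify_chain(chains[[nm]], ...)
    data.frame(chain = nm, tm_start = ann$tm_start, tm_end = ann$tm_end,
               charged = paste0(ann$charged$residue, ann$charged$pos,
                                collapse = ","),
               chain_class = ann$chain_class)
  })
  report <- do.call(rbind, rows)
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
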