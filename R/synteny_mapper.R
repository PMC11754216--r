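# Conserved-synteny comparison of annotated regions around a locus.

.canonical_names <- function(genes, aliases = NULL) {
  nm <- tolower(genes)
  if (!is.null(aliases)) {
    map <- stats::setNames(tolower(unname(aliases)), tolower(names(aliases)))
    hit <- nm %in% names(map)
    nm[hit] <- map[nm[hit]]
  }
  nm
}

.check_region <- function(region, arg) {
  req <- c("gene", "start", "end")
  if (!is.data.frame(region) || !all(req %in% names(region))) {
    stop(arg, " must be a data.frame with columns gene, start, end")
  }
  if (nrow(region) == 0) stop(arg, " must contain at least one gene")
  if (anyDuplicated(region$gene)) {
    stop("duplicate gene name in ", arg, ": ",
         region$gene[duplicated(region$gene)][1])
  }
  region
}

#' Distance between two flanking genes in a region
#'
#' Non-negative distance in bp from the inner boundary of the upstream
#' gene to the inner boundary of the downstream gene (gene order is
#' normalized by coordinate, so the result is invariant to which strand
#' the region was annotated on).
#'
#' @param region data.frame with columns `gene`, `start`, `end`.
#' @param five_prime,three_prime Names of the two flanking genes.
#' @return Distance in bp (0 for adjacent or overlapping genes).
#' @export
gap_between <- function(region, five_prime, three_prime) {
  .check_region(region, "region")
  nm <- .canonical_names(region$gene)
  for (g in c(five_prime, three_prime)) {
    if (!tolower(g) %in% nm) stop("gene not found in region: ", g)
  }
  a <- region[nm == tolower(five_prime), ][1, ]
  b <- region[nm == tolower(three_prime), ][1, ]
  left <- if (a$start <= b$start) a else b
  right <- if (a$start <= b$start) b else a
  max(0L, right$start - left$end - 1L)
}

#' Compare flanking-gene synteny between two annotated regions
#'
#' Genes are matched by name (case-insensitive, with an optional alias
#' table for cross-species name variants). For each shared gene the
#' report gives its interval in both regions and whether its relative
#' order among the shared genes is preserved. When designated 5'/3'
#' flanking genes are given, the distance between them is computed in
#' each region; a flanker missing from a region is reported as `NA`, not
#' an error.
#'
#' @param a,b data.frames with columns `gene`, `start`, `end` (optionally
#'   `strand`).
#' @param aliases Optional named character vector mapping alias names to
#'   canonical names (e.g. `c(MOXD2P = "DBHL", "EPHB5-like" = "EPHB6")`).
#' @param five_prime,three_prime Optional designated flanking gene names.
#' @return A `synteny_report`: `shared_genes` data.frame and
#'   `locus_gap_a` / `locus_gap_b` distances in bp.
#' @export
shared_flankers <- function(a, b, aliases = NULL, five_prime = NULL,
                            three_prime = NULL) {
  .check_region(a, "a"); .check_region(b, "b")
  ca <- .canonical_names(a$gene, aliases)
  cb <- .canonical_names(b$gene, aliases)
  common <- intersect(ca, cb)

  shared <- data.frame(name = character(0), start_a = integer(0),
                       end_a = integer(0), start_b = integer(0),
                       end_b = integer(0), same_order = logical(0))
  if (length(common)) {
    ia <- match(common, ca)
    ib <- match(common, cb)
    rank_a <- rank(a$start[ia])
    rank_b <- rank(b$start[ib])
    shared <- data.frame(
      name = a$gene[ia],
      start_a = a$start[ia], end_a = a$end[ia],
      start_b = b$start[ib], end_b = b$end[ib],
      same_order = rank_a == rank_b)
    shared <- shared[order(shared$start_a), , drop = FALSE]
    rownames(shared) <- NULL
  }

  gap_in <- function(region, cn) {
    if (is.null(five_prime) || is.null(three_prime)) return(NA_integer_)
    want <- .canonical_names(c(five_prime, three_prime), aliases)
    if (!all(want %in% cn)) {
      vdj_note("designated flanker absent from a region: ",
               paste(c(five_prime, three_prime)[!want %in% cn],
                     collapse = ", "))
      return(NA_integer_)
    }
    genes <- region$gene[match(want, cn)]
    gap_between(region, genes[1], genes[2])
  }

  structure(list(shared_genes = shared,
                 locus_gap_a = gap_in(a, ca),
                 locus_gap_b = gap_in(b, cb)),
            class = "synteny_report")
}

#' @export
print.synteny_report <- function(x, ...) {
  cat(sprintf("synteny report: %d shared genes\n", nrow(x$shared_genes)))
  if (nrow(x$shared_genes)) print(x$shared_genes)
  if (!is.na(x$locus_gap_a) || !is.na(x$locus_gap_b)) {
    cat(sprintf("  flanker gap: %s bp (a) vs %s bp (b)\n",
                format(x$locus_gap_a, big.mark = ","),
                format(x$locus_gap_b, big.mark = ",")))
  }
  invisible(x)
}

#' Read gene annotations from GFF3 or a simple TSV
#'
#' GFF3 files are read with rtracklayer (features of type `gene`, falling
#' back to all features); TSV files need columns `gene`, `start`, `end`
#' and optionally `strand`.
#'
#' @param path Input path (`.gff`/`.gff3` or tab-separated text).
#' @return data.frame with columns `gene`, `start`, `end`, `strand`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene"]
    }
    nm <- if ("Name" %in% names(S4Vectors::mcols(gr))) gr$Name else gr$ID
    return(data.frame(gene = as.character(nm),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr))))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  .check_region(tab, path)
  if (!"strand" %in% names(tab)) tab$strand <- "+"
  tab[, c("gene", "start", "end", "strand")]
}

#' Write a synteny report as TSV
#'
#' @param report A `synteny_report`.
#' @param path Output path.
#' @export
write_synteny_tsv <- function(report, path) {
  write.table(report$shared_genes, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
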