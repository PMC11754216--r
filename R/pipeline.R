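# End-to-end orchestration: scan -> annotate -> cluster -> repertoire ->
# chain features -> tree, from a single plain-text (YAML) config, with a
# reproducibility manifest.

#' Annotate a locus end to end
#'
#' Runs both RSS scans, calls segments, locates constant regions from a C
#' database, clusters V families and assigns IMGT-style names.
#'
#' @param seq Locus nucleotide sequence.
#' @param c_db Named character vector of known constant-region sequences
#'   (coding orientation), or `NULL` to skip C placement.
#' @param locus_prefix Name prefix for segments (default `"TRB"`).
#' @param threshold_frac Scan threshold as a fraction of the model
#'   maximum score (default 0.6).
#' @param spacer_tolerance Allowed spacer deviation in bp (default 1).
#' @param params Segment length windows, see [segment_params()].
#' @param family_threshold Percent identity threshold for V families.
#' @param locus_name Name for the resulting map.
#' @return A list: `map` (a [build_locus_map()] result), `segments`,
#'   `families`, `identity` (matrix or NULL), `hits12`, `hits23`.
#' @export
annotate_locus <- function(seq, c_db = NULL, locus_prefix = "TRB",
                           threshold_frac = 0.6, spacer_tolerance = 1,
                           params = segment_params(),
                           family_threshold = 80,
                           locus_name = "locus") {
  m12 <- default_rss_model(12, spacer_tolerance)
  m23 <- default_rss_model(23, spacer_tolerance)
  hits12 <- scan_rss(seq, m12, threshold_frac * rss_max_score(m12))
  hits23 <- scan_rss(seq, m23, threshold_frac * rss_max_score(m23))
  c_regions <- if (!is.null(c_db)) locate_c_regions(seq, c_db) else NULL
  segments <- call_segments(seq, hits12, hits23, c_regions, params)

  families <- NULL; idm <- NULL
  if (any(segments$kind == "V")) {
    idm <- identity_matrix(segments)
    v_starts <- stats::setNames(
      segments$start[segments$kind == "V"],
      segments$name[segments$kind == "V"])
    families <- cluster_families(idm, threshold = family_threshold,
                                 order_by = v_starts)
  }
  segments <- assign_names(segments, locus_prefix, families)
  map <- build_locus_map(segments, locus_name = locus_name)
  list(map = map, segments = segments, families = families,
       identity = idm, hits12 = hits12, hits23 = hits23)
}

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages (each optional, driven by the config): locus acquisition (FASTA
#' or synthetic simulation), RSS scan + segment annotation + family
#' clustering, repertoire classification, constant-region chain features,
#' neighbor-joining tree of the V segments, and synteny comparison.
#' Writes GFF3, TSV, FASTA and Newick outputs plus a `manifest.json`
#' recording package version, parameters, seed and input/output
#' checksums; outputs are deterministic given (inputs, config, seed).
#'
#' @param config A list or path to a YAML file. Recognized blocks:
#'   `locus` (either `fasta: <path>` or `simulate: <locus_config fields>`),
#'   `annotate` (`locus_prefix`, `threshold_frac`, `spacer_tolerance`,
#'   `family_threshold`), `repertoire` (either `fasta: <path>` or
#'   `simulate: <recombination_config fields>`, plus `min_identity`),
#'   `tree` (`bootstrap`, enabled when present), `chain_features`
#'   (logical), `synteny` (`a:`/`b:` annotation tables, `five_prime`,
#'   `three_prime`), `seed`, `out`.
#' @param out_dir Output directory (overrides `config$out`).
#' @param seed Integer seed (overrides `config$seed`).
#' @return The output directory path, invisibly; stage results as the
#'   attribute `"results"`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- .read_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out
  if (is.null(out_dir)) stop("an output directory is required")
  if (is.null(seed)) seed <- if (!is.null(cfg$seed)) cfg$seed else 1L
  seed <- as.integer(seed)

  # validate referenced inputs before writing anything
  inputs <- character(0)
  for (block in c("locus", "repertoire")) {
    p <- cfg[[block]]$fasta
    if (!is.null(p)) {
      if (!file.exists(p)) stop("input not found (", block, "): ", p)
      inputs[block] <- p
    }
  }
  for (side in c("a", "b")) {
    p <- cfg$synteny[[side]]
    if (!is.null(p)) {
      if (!file.exists(p)) stop("input not found (synteny ", side, "): ", p)
      inputs[paste0("synteny_", side)] <- p
    }
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  written <- character(0)
  out <- function(name) {
    written[[length(written) + 1]] <<- file.path(out_dir, name)
    file.path(out_dir, name)
  }

  # --- locus -----------------------------------------------------------
  locus_seq <- NULL; locus_truth <- NULL
  if (!is.null(cfg$locus$fasta)) {
    fa <- read_fasta(cfg$locus$fasta)
    locus_seq <- fa[[1]]
  } else if (!is.null(cfg$locus$simulate) || isTRUE(cfg$locus$simulate)) {
    sim_args <- if (is.list(cfg$locus$simulate)) cfg$locus$simulate else list()
    sim_args$seed <- seed
    loc <- generate_locus(do.call(locus_config, sim_args))
    locus_seq <- loc$sequence
    locus_truth <- loc$truth
    write_fasta(stats::setNames(locus_seq, loc$id), out("locus.fasta"))
    write.table(loc$truth, out("locus_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$locus <- loc
  }

  # --- annotation ------------------------------------------------------
  if (!is.null(locus_seq)) {
    ann_cfg <- cfg$annotate
    c_db <- NULL
    if (!is.null(locus_truth)) {
      cs <- locus_truth[locus_truth$kind == "C", ]
      c_db <- stats::setNames(cs$sequence, cs$name)
    } else if (!is.null(ann_cfg$c_fasta)) {
      c_db <- read_fasta(ann_cfg$c_fasta)
    }
    ann <- annotate_locus(
      locus_seq, c_db = c_db,
      locus_prefix = ann_cfg$locus_prefix %||% "TRB",
      threshold_frac = ann_cfg$threshold_frac %||% 0.6,
      spacer_tolerance = ann_cfg$spacer_tolerance %||% 1,
      family_threshold = ann_cfg$family_threshold %||% 80)
    results$annotation <- ann
    write_gff3(ann$segments, out("segments.gff3"),
               hits = rbind(ann$hits12, ann$hits23))
    if (!is.null(ann$identity)) {
      write_identity_tsv(ann$identity, out("identity_matrix.tsv"),
                         long_path = out("identity_matrix.long.tsv"))
    }
    write.table(ann$segments[, c("name", "kind", "start", "end", "strand",
                                 "family")],
                out("segments.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  # --- repertoire ------------------------------------------------------
  if (!is.null(cfg$repertoire)) {
    rep_cfg <- cfg$repertoire
    germline <- if (!is.null(locus_truth)) locus_truth else
      results$annotation$segments
    if (is.null(germline)) stop("repertoire stage needs a germline locus")
    if (!is.null(rep_cfg$fasta)) {
      tx <- read_fasta(rep_cfg$fasta)
    } else {
      sim_args <- if (is.list(rep_cfg$simulate)) rep_cfg$simulate else list()
      sim_args$seed <- seed + 1L
      rep <- simulate_repertoire(list(truth = germline),
                                 do.call(recombination_config, sim_args))
      tx <- rep$transcripts
      write_fasta(tx, out("transcripts.fasta"))
      write.table(rep$truth, out("repertoire_truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      results$repertoire_truth <- rep$truth
    }
    calls <- classify_rearrangements(
      tx, germline, min_identity = rep_cfg$min_identity %||% 90)
    results$calls <- calls
    results$summary <- summarize_repertoire(calls)
    write_repertoire_tsv(calls, out("repertoire.tsv"))
    s <- results$summary
    write.table(
      data.frame(n_total = s$n_total, n_complete = s$n_complete,
                 n_productive = s$n_productive,
                 pct_complete = s$pct_complete,
                 pct_productive_of_complete = s$pct_productive_of_complete),
      out("repertoire_summary.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  # --- chain features --------------------------------------------------
  if (isTRUE(cfg$chain_features) && !is.null(results$annotation)) {
    seg <- results$annotation$segments
    cs <- seg[seg$kind == "C", , drop = FALSE]
    if (nrow(cs)) {
      chains <- stats::setNames(
        vapply(cs$sequence, translate_nt, ""), cs$name)
      results$chains <- write_chain_report(chains,
                                           out("chain_features.tsv"))
    }
  }

  # --- tree ------------------------------------------------------------
  if (!is.null(cfg$tree) && !is.null(results$annotation)) {
    seg <- results$annotation$segments
    vs <- seg[seg$kind == "V", , drop = FALSE]
    if (nrow(vs) >= 3) {
      aa <- stats::setNames(vapply(vs$sequence, translate_nt, ""),
                            vs$name)
      msa <- align_progressive(aa)
      n_reps <- cfg$tree$bootstrap %||% 1000
      tree <- nj_bootstrap(msa, n_reps = n_reps, seed = seed + 2L)
      write_newick(tree, out("v_tree.nwk"))
      write_distance_tsv(p_distance(msa), out("v_distances.tsv"))
      results$tree <- tree
    }
  }

  # --- synteny ---------------------------------------------------------
  if (!is.null(cfg$synteny$a) && !is.null(cfg$synteny$b)) {
    rep_syn <- shared_flankers(
      read_gene_table(cfg$synteny$a), read_gene_table(cfg$synteny$b),
      aliases = unlist(cfg$synteny$aliases),
      five_prime = cfg$synteny$five_prime,
      three_prime = cfg$synteny$three_prime)
    write_synteny_tsv(rep_syn, out("synteny.tsv"))
    results$synteny <- rep_syn
  }

  manifest <- list(
    package = "vdjloci",
    version = as.character(utils::packageVersion("vdjloci")),
    seed = seed,
    config = cfg[setdiff(names(cfg), "out")],
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(unlist(written))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(invisible(out_dir), results = results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Progressive stacking alignment of unaligned sequences
#'
#' Builds a simple multiple alignment by fit-aligning each sequence in
#' turn against the current consensus-free profile (the first sequence
#' acts as the anchor), inserting gaps as needed. Adequate for the
#' closely related segment sets this package compares; not a
#' general-purpose MSA.
#'
#' @param seqs Named character vector (all the same molecule type).
#' @return Named character vector of equal-length aligned rows.
#' @export
align_progressive <- function(seqs) {
  stopifnot(length(seqs) >= 2)
  rows <- list()
  anchor <- seqs[[1]]
  rows[[names(seqs)[1]]] <- anchor
  for (k in seq_along(seqs)[-1]) {
    al <- global_align(seqs[[k]], gsub("-", "N", rows[[1]]))
    # columns inserted into the anchor must be propagated to all rows
    a_chars <- strsplit(al$aligned_b, "")[[1]]
    new_cols <- which(a_chars == "-")
    for (nm in names(rows)) {
      chars <- strsplit(rows[[nm]], "")[[1]]
      for (ins in new_cols) chars <- append(chars, "-", after = ins - 1)
      rows[[nm]] <- paste(chars, collapse = "")
    }
    rows[[names(seqs)[k]]] <- al$aligned_a
  }
  # pad any ragged ends
  w <- max(nchar(unlist(rows)))
  out <- vapply(rows, function(r)
    paste0(r, strrep("-", w - nchar(r))), "")
  stats::setNames(out, names(rows))
}
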