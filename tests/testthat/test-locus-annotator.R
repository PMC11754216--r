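annotate_with_truth <- function(loc, ...) {
  cs <- loc$truth[loc$truth$kind == "C", ]
  annotate_locus(loc$sequence,
                 c_db = stats::setNames(cs$sequence, cs$name), ...)
}

expect_exact_recovery <- function(loc, ann) {
  truth <- loc$truth[order(loc$truth$start), ]
  seg <- ann$segments[order(ann$segments$start), ]
  expect_equal(nrow(seg), nrow(truth))
  expect_equal(seg$kind, truth$kind)
  expect_equal(seg$start, truth$start)
  expect_equal(seg$end, truth$end)
  expect_equal(seg$strand, truth$strand)
  expect_equal(seg$sequence, truth$sequence)
}

test_that("a planted locus is recovered segment for segment", {
  loc <- generate_locus(locus_config(n_v = 3, n_d = 2, n_j = 2, n_c = 1,
                                     n_families = 2, n_inverted_v = 0,
                                     seed = 7))
  ann <- annotate_with_truth(loc)
  expect_exact_recovery(loc, ann)
  expect_equal(ann$segments$name, loc$truth$name[order(loc$truth$start)])
})

test_that("an inverted V 3' of C is called on the minus strand", {
  loc <- generate_locus(locus_config(n_v = 3, n_d = 1, n_j = 2, n_c = 1,
                                     n_families = 2, n_inverted_v = 1,
                                     seed = 13))
  ann <- annotate_with_truth(loc)
  expect_exact_recovery(loc, ann)
  seg <- ann$segments
  c_end <- seg$end[seg$kind == "C"]
  inv <- seg[seg$kind == "V" & seg$strand == "-", ]
  expect_equal(nrow(inv), 1)
  expect_gt(inv$start, c_end)
  expect_equal(count_inversions(ann$map), 1)
})

test_that("empty hit input yields an empty segment set", {
  m12 <- default_rss_model(12); m23 <- default_rss_model(23)
  set.seed(30)
  seq <- rand_nt_str(500)
  h12 <- scan_rss(seq, m12, threshold = rss_max_score(m12))
  h23 <- scan_rss(seq, m23, threshold = rss_max_score(m23))
  seg <- call_segments(seq, h12[0, ], h23[0, ])
  expect_equal(nrow(seg), 0)
})

test_that("every call respects the 12/23 spacer architecture", {
  for (s in c(2, 9, 17)) {
    loc <- generate_locus(locus_config(n_v = 4, n_d = 2, n_j = 3, n_c = 1,
                                       n_families = 2, n_inverted_v = 1,
                                       seed = s))
    seg <- annotate_with_truth(loc)$segments
    v <- seg[seg$kind == "V", ]
    expect_true(all(v$rss3_spacer %in% 22:24) && all(is.na(v$rss5_spacer)))
    d <- seg[seg$kind == "D", ]
    expect_true(all(d$rss5_spacer %in% 11:13) &&
                  all(d$rss3_spacer %in% 22:24))
    j <- seg[seg$kind == "J", ]
    expect_true(all(j$rss5_spacer %in% 11:13) && all(is.na(j$rss3_spacer)))
    expect_true(all(is.na(seg$rss5_spacer[seg$kind == "C"])))
  }
})

test_that("reverse-complementing the locus mirrors every call", {
  loc <- tiny_locus(seed = 5)
  ann <- annotate_with_truth(loc)
  L <- nchar(loc$sequence)
  cs <- loc$truth[loc$truth$kind == "C", ]
  ann_rc <- annotate_locus(revcomp(loc$sequence),
                           c_db = stats::setNames(cs$sequence, cs$name))
  a <- ann$segments[order(ann$segments$start), ]
  b <- ann_rc$segments
  b_m <- data.frame(kind = b$kind, start = L - b$end + 1,
                    end = L - b$start + 1,
                    strand = ifelse(b$strand == "+", "-", "+"),
                    sequence = b$sequence)
  b_m <- b_m[order(b_m$start), ]
  expect_equal(b_m$kind, a$kind)
  expect_equal(b_m$start, a$start)
  expect_equal(b_m$end, a$end)
  expect_equal(b_m$strand, a$strand)
  expect_equal(b_m$sequence, a$sequence)
})

test_that("naming follows locus order and family membership", {
  seg <- data.frame(
    name = c("J_10", "J_200", "J_300", "C_400"),
    kind = c("J", "J", "J", "C"),
    start = c(10L, 200L, 300L, 400L), end = c(50L, 240L, 340L, 600L),
    strand = "+", sequence = "ACGT", family = NA_integer_)
  named <- assign_names(seg, "TRB")
  expect_equal(named$name, c("TRBJ1", "TRBJ2", "TRBJ3", "TRBC"))

  vseg <- data.frame(
    name = c("V_10", "V_500", "V_900"),
    kind = "V", start = c(10L, 500L, 900L),
    end = c(300L, 790L, 1190L), strand = "+", sequence = "ACGT",
    family = NA_integer_)
  fams <- structure(stats::setNames(c(2L, 2L, 1L),
                                    c("V_10", "V_500", "V_900")),
                    threshold = 80, method = "single",
                    class = "family_assignment")
  named_v <- assign_names(vseg, "TRB", fams)
  expect_equal(named_v$name, c("TRBV2.1", "TRBV2.2", "TRBV1.1"))

  expect_error(assign_names(vseg, "TRB"), "famil")
})

test_that("locus maps validate overlap, span, and counts", {
  loc <- tiny_locus(seed = 4)
  ann <- annotate_with_truth(loc)
  truth <- loc$truth
  expect_equal(ann$map$span_bp, max(truth$end) - min(truth$start) + 1L)
  counts <- kind_counts(ann$map)
  expect_equal(unname(counts), c(4L, 2L, 3L, 1L))

  one <- ann$segments[1, ]
  expect_equal(build_locus_map(one)$span_bp, one$end - one$start + 1L)

  overlapping <- ann$segments[1:2, ]
  overlapping$start[2] <- overlapping$start[1] + 5L
  overlapping$end[2] <- overlapping$end[1] + 5L
  expect_error(build_locus_map(overlapping), "overlap")
})

test_that("inversion counting is strand-relabeling invariant", {
  loc <- generate_locus(locus_config(n_v = 5, n_d = 1, n_j = 2, n_c = 1,
                                     n_families = 2, n_inverted_v = 2,
                                     seed = 19))
  ann <- annotate_with_truth(loc)
  expect_equal(count_inversions(ann$map), 2)

  seg <- ann$map$segments
  seg$strand <- ifelse(seg$strand == "+", "-", "+")
  expect_equal(count_inversions(seg), 2)

  same <- seg; same$strand <- "+"
  expect_equal(count_inversions(same), 0)
})

test_that("C regions are located by fit alignment on either strand", {
  loc <- tiny_locus(seed = 6)
  cs <- loc$truth[loc$truth$kind == "C", ]
  found <- locate_c_regions(loc$sequence,
                            stats::setNames(cs$sequence, "Cquery"))
  expect_equal(found$start, cs$start)
  expect_equal(found$end, cs$end)
  expect_equal(found$strand, "+")

  found_rc <- locate_c_regions(revcomp(loc$sequence),
                               stats::setNames(cs$sequence, "Cquery"))
  L <- nchar(loc$sequence)
  expect_equal(found_rc$start, L - cs$end + 1L)
  expect_equal(found_rc$strand, "-")
})

test_that("GFF3 export round-trips coordinates", {
  loc <- tiny_locus(seed = 8)
  ann <- annotate_with_truth(loc)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann$segments, f, seqname = "chr1", hits = ann$hits23)
  gr <- rtracklayer::import(f)
  seg_types <- paste0(c("V", "D", "J", "C"), "_gene_segment")
  gr_seg <- gr[gr$type %in% seg_types]
  expect_equal(length(gr_seg), nrow(ann$segments))
  ord <- order(GenomicRanges::start(gr_seg))
  expect_equal(GenomicRanges::start(gr_seg)[ord],
               sort(ann$segments$start))
})
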