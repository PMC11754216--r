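test_that("the example configuration yields the planted architecture", {
  loc <- generate_locus(locus_config(n_v = 3, n_d = 2, n_j = 2, n_c = 1,
                                     n_families = 2, n_inverted_v = 1,
                                     seed = 7))
  expect_equal(nrow(loc$truth), 8)
  expect_equal(sum(loc$truth$strand == "-"), 1)
  expect_equal(unname(table(loc$truth$kind)[c("V", "D", "J", "C")]),
               c(3L, 2L, 2L, 1L), ignore_attr = TRUE)
  # inverted V sits 3' of C
  c_end <- loc$truth$end[loc$truth$kind == "C"]
  inv <- loc$truth[loc$truth$strand == "-", ]
  expect_gt(inv$start, c_end)
  # planted truth sequences match the locus coordinates
  for (r in seq_len(nrow(loc$truth))) {
    sub <- substr(loc$sequence, loc$truth$start[r], loc$truth$end[r])
    if (loc$truth$strand[r] == "-") sub <- revcomp(sub)
    expect_equal(sub, loc$truth$sequence[r])
  }
})

test_that("family structure survives the identity threshold by design", {
  loc <- generate_locus(locus_config(n_v = 6, n_d = 0, n_j = 1, n_c = 1,
                                     n_families = 2, n_inverted_v = 0,
                                     seed = 11))
  v <- loc$truth[loc$truth$kind == "V", ]
  m <- identity_matrix(stats::setNames(v$sequence, v$name))
  fam <- cluster_families(m, threshold = 80,
                          order_by = stats::setNames(v$start, v$name))
  expect_equal(as.integer(fam), v$family)
})

test_that("generation is byte-reproducible given the seed", {
  l1 <- generate_locus(locus_config(seed = 5))
  l2 <- generate_locus(locus_config(seed = 5))
  expect_identical(l1$sequence, l2$sequence)
  expect_identical(l1$truth, l2$truth)
  l3 <- generate_locus(locus_config(seed = 6))
  expect_false(identical(l1$sequence, l3$sequence))
})

test_that("the frame guard blocks every upstream reading frame", {
  g <- "TAAATAAATAA"
  for (f in 0:2) {
    expect_match(translate_nt(paste0(strrep("A", f), g)), "\\*")
  }
})

test_that("forced limits produce all-productive truth", {
  loc <- tiny_locus(seed = 21)
  rep <- simulate_repertoire(loc, recombination_config(
    n_transcripts = 40, target_frame_fraction = 1,
    incomplete_5p_fraction = 0, seed = 2))
  expect_true(all(rep$truth$productive))
  expect_true(all(rep$truth$complete_5p))
  expect_true(all(rep$truth$in_frame))
  expect_false(any(rep$truth$has_stop))
})

test_that("configured fractions are realized exactly by allocation", {
  loc <- tiny_locus(seed = 22)
  cfg <- recombination_config(n_transcripts = 200,
                              target_frame_fraction = 0.8,
                              incomplete_5p_fraction = 0.474, seed = 4)
  rep <- simulate_repertoire(loc, cfg)
  n_complete <- sum(rep$truth$complete_5p)
  expect_equal(n_complete, round(200 * (1 - 0.474)))
  expect_equal(sum(rep$truth$productive), round(0.8 * n_complete))
})

test_that("simulation is reproducible and truth matches an independent
          recomputation of frame and stop flags", {
  loc <- tiny_locus(seed = 23)
  cfg <- recombination_config(n_transcripts = 50, seed = 9)
  r1 <- simulate_repertoire(loc, cfg)
  r2 <- simulate_repertoire(loc, cfg)
  expect_identical(r1$transcripts, r2$transcripts)
  indep <- recompute_truth_flags(r1$truth, loc$truth)
  expect_equal(r1$truth$in_frame, indep$in_frame)
  expect_equal(r1$truth$has_stop, indep$has_stop)
  expect_equal(r1$truth$productive, indep$productive)
})

test_that("the 12/23 rule shapes every simulated junction", {
  loc <- tiny_locus(seed = 24)
  rep <- simulate_repertoire(loc, recombination_config(n_transcripts = 30,
                                                       seed = 5))
  # D segments are always used when present (no direct V-J joins)
  expect_false(any(is.na(rep$truth$d_name)))
})

test_that("the non-canonical heptamer option still supports annotation", {
  loc <- generate_locus(locus_config(n_v = 2, n_d = 1, n_j = 1, n_c = 1,
                                     n_families = 1, n_inverted_v = 0,
                                     noncanonical_heptamer = TRUE,
                                     seed = 3))
  cs <- loc$truth[loc$truth$kind == "C", ]
  ann <- annotate_locus(loc$sequence,
                        c_db = stats::setNames(cs$sequence, cs$name))
  seg <- ann$segments[order(ann$segments$start), ]
  truth <- loc$truth[order(loc$truth$start), ]
  expect_equal(seg$kind, truth$kind)
  expect_equal(seg$start, truth$start)
  expect_equal(seg$end, truth$end)
})

test_that("TM chains vary outside the planted core across seeds", {
  c1 <- generate_tm_chain("RK", seed = 1)
  c2 <- generate_tm_chain("RK", seed = 2)
  expect_false(identical(c1, c2))
  expect_identical(c1, generate_tm_chain("RK", seed = 1))
})

test_that("infeasible identity targets fail loudly", {
  # no pair of random prototypes can be this dissimilar under gapped
  # alignment, so prototype generation must give up
  cfg <- locus_config(n_v = 4, n_families = 2,
                      within_family_identity = 50,
                      between_family_identity = 5, seed = 1)
  expect_error(generate_locus(cfg), "infeasible")
})
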