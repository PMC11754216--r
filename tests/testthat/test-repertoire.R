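germline_of <- function(loc) loc$truth

test_that("segments are assigned from simulated transcripts", {
  loc <- tiny_locus(seed = 3)
  rep <- simulate_repertoire(loc, recombination_config(
    n_transcripts = 20, incomplete_5p_fraction = 0, seed = 5))
  calls <- classify_rearrangements(rep$transcripts, germline_of(loc))
  expect_equal(calls$v_name, rep$truth$v_name)
  expect_equal(calls$j_name, rep$truth$j_name)
  expect_equal(calls$c_name, rep$truth$c_name)
})

test_that("a bare constant-region transcript is incomplete with no V", {
  loc <- tiny_locus(seed = 3)
  c_seq <- loc$truth$sequence[loc$truth$kind == "C"][1]
  call <- assign_segments(c(only_c = c_seq), germline_of(loc))
  expect_true(is.na(call$v_name))
  expect_false(call$complete_5p)
  call <- classify_productivity(call, c_seq)
  expect_false(call$productive)
})

test_that("transcripts without a C match are flagged unassigned", {
  loc <- tiny_locus(seed = 3)
  call <- assign_segments(c(junk = rand_nt_str(400)), germline_of(loc))
  expect_true(call$unassigned)
  expect_false(call$productive)
})

test_that("D detection requires a long exact match and is monotone", {
  d_db <- c(TRBD1 = "GGGACAGGGGGC", TRBD2 = "GGGACTGGGGGG")
  expect_equal(detect_d("AATTGGGACAGGGGGCTT", d_db), "TRBD1")
  expect_true(is.na(detect_d("ACGT", d_db)))
  junction <- "AAGGGACAGGGTTT"  # 11 nt shared with TRBD1 at most
  hits <- vapply(4:12, function(mm) {
    !is.na(detect_d(junction, d_db, min_match = mm))
  }, NA)
  expect_true(all(diff(as.integer(hits)) <= 0))
  expect_true(hits[1])
  expect_false(hits[length(hits)])
})

test_that("frame arithmetic and stop scanning drive productivity", {
  # hand-built micro-germline: V of 12 nt, J of 9 nt, C of 30 nt
  v <- "ATGGCTGCAGCT"
  j <- "TTTGGACAA"
  c_seq <- "GAAGAAGAAGAAGAAGAAGAAGAAGAAGAA"
  germ <- data.frame(
    name = c("V1", "J1", "C1"), kind = c("V", "J", "C"),
    start = NA, end = NA, strand = "+",
    family = NA, sequence = c(v, j, c_seq))

  in_frame_tx <- paste0(v, "GGG", j, c_seq)  # junction of 3 nt
  call <- classify_productivity(
    assign_segments(c(tx = in_frame_tx), germ, min_identity = 90),
    in_frame_tx)
  expect_true(call$in_frame)
  expect_false(call$has_stop)
  expect_true(call$productive)

  shifted_tx <- paste0(v, "GGGA", j, c_seq)  # 1 nt insertion
  call2 <- classify_productivity(
    assign_segments(c(tx = shifted_tx), germ, min_identity = 90),
    shifted_tx)
  expect_false(call2$in_frame)
  expect_false(call2$productive)

  stop_tx <- paste0(v, "TAA", j, c_seq)  # in-frame junction encoding a stop
  call3 <- classify_productivity(
    assign_segments(c(tx = stop_tx), germ, min_identity = 90),
    stop_tx)
  expect_true(call3$in_frame)
  expect_true(call3$has_stop)
  expect_false(call3$productive)
})

test_that("summary percentages match the printed-composition arithmetic", {
  calls <- data.frame(
    complete_5p = rep(c(TRUE, FALSE), c(20, 18)),
    productive = rep(c(TRUE, FALSE), c(16, 22)))
  s <- summarize_repertoire(calls)
  expect_equal(s$n_total, 38)
  expect_equal(s$n_complete, 20)
  expect_equal(s$n_productive, 16)
  expect_equal(s$pct_complete, 52.6)
  expect_equal(s$pct_productive_of_complete, 80.0)

  empty <- summarize_repertoire(calls[0, ])
  expect_equal(empty$n_total, 0)
  expect_equal(empty$pct_complete, 0)
  expect_equal(empty$pct_productive_of_complete, 0)
})

test_that("summary counts equal a brute-force recount of the flags", {
  loc <- tiny_locus(seed = 9)
  rep <- simulate_repertoire(loc, recombination_config(n_transcripts = 60,
                                                       seed = 2))
  calls <- classify_rearrangements(rep$transcripts, germline_of(loc))
  s <- summarize_repertoire(calls)
  expect_equal(s$n_complete, sum(calls$complete_5p))
  expect_equal(s$n_productive, sum(calls$productive))
  expect_equal(s$pct_complete,
               round_half_up(100 * sum(calls$complete_5p) / nrow(calls)))
})

test_that("analyzer flags equal simulator truth with zero discordance", {
  for (s in 1:3) {
    loc <- generate_locus(locus_config(n_v = 5, n_d = 2, n_j = 3, n_c = 1,
                                       n_families = 2, n_inverted_v = 0,
                                       seed = s))
    rep <- simulate_repertoire(loc, recombination_config(
      n_transcripts = 80, seed = 50 + s))
    calls <- classify_rearrangements(rep$transcripts, germline_of(loc))
    expect_equal(calls$complete_5p, rep$truth$complete_5p)
    expect_equal(calls$productive, rep$truth$productive)
    cmp <- calls$complete_5p
    expect_equal(calls$in_frame[cmp], rep$truth$in_frame[cmp])
    expect_equal(calls$has_stop[cmp], rep$truth$has_stop[cmp])
  }
})

test_that("productive always implies complete, in frame, and stop free", {
  loc <- tiny_locus(seed = 12)
  rep <- simulate_repertoire(loc, recombination_config(n_transcripts = 60,
                                                       seed = 77))
  calls <- classify_rearrangements(rep$transcripts, germline_of(loc))
  prod <- calls[calls$productive, ]
  expect_true(all(prod$complete_5p))
  expect_true(all(prod$in_frame))
  expect_false(any(prod$has_stop))
})
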