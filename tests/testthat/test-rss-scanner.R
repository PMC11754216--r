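test_that("model construction validates and normalizes", {
  expect_error(default_rss_model(15), "12 or 23")
  m <- default_rss_model(23)
  expect_equal(m$spacer_class, 23L)
  expect_true(all(abs(colSums(m$heptamer_pfm) - 1) < 1e-12))
  expect_true(all(abs(colSums(m$nonamer_pfm) - 1) < 1e-12))
})

test_that("consensus scores strictly above every single-mismatch heptamer", {
  m <- default_rss_model(23)
  consensus <- score_rss_window(m, "CACAGTG", "ACAAAAACC")
  expect_equal(consensus, rss_max_score(m))
  chars <- strsplit("CACAGTG", "")[[1]]
  for (pos in 1:7) {
    for (base in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      mut <- chars; mut[pos] <- base
      expect_lt(score_rss_window(m, paste(mut, collapse = ""),
                                 "ACAAAAACC"), consensus)
    }
  }
})

test_that("the functional non-canonical heptamer still scores well", {
  m <- default_rss_model(23)
  s_canon <- score_rss_window(m, "CACAGTG", "ACAAAAACC")
  s_var <- score_rss_window(m, "CACAGCA", "ACAAAAACC")
  expect_lt(s_var, s_canon)
  # above the default scan threshold, and far above a random window
  expect_gt(s_var, 0.6 * rss_max_score(m))
  set.seed(2)
  random_scores <- replicate(50, score_rss_window(m, rand_nt_str(7),
                                                  rand_nt_str(9)))
  expect_gt(s_var, max(random_scores))
})

test_that("training reproduces counts with pseudocount smoothing", {
  ex <- data.frame(heptamer = "CACAGTG", nonamer = "ACAAAAACC")
  m <- train_rss_model(ex, 23, pseudocount = 1)
  # single example: consensus base frequency (1+1)/(1+4) at each position
  expect_equal(unname(m$heptamer_pfm["C", 1]), 2 / 5)
  expect_equal(unname(m$heptamer_pfm["A", 1]), 1 / 5)

  # many consensus copies with vanishing pseudocount approach the
  # consensus-concentrated model's ranking
  many <- data.frame(heptamer = rep("CACAGTG", 50),
                     nonamer = rep("ACAAAAACC", 50))
  m2 <- train_rss_model(many, 23, pseudocount = 1e-6)
  expect_gt(m2$heptamer_pfm["C", 1], 0.9999)

  expect_error(train_rss_model(
    data.frame(heptamer = "CACA", nonamer = "ACAAAAACC"), 23), "length 7")
})

test_that("information content is non-increasing in the pseudocount", {
  ex <- data.frame(
    heptamer = c("CACAGTG", "CACAGCA", "CACTGTG"),
    nonamer = c("ACAAAAACC", "ACAAAAACC", "GCAAAAACC"))
  ics <- vapply(c(0.01, 0.1, 1, 10, 100), function(pc)
    rss_information_content(train_rss_model(ex, 23, pseudocount = pc)), 0)
  expect_true(all(diff(ics) <= 1e-9))
})

test_that("window scores equal hand-summed per-position log odds", {
  # hand-checkable model: uniform nonamer contributes 0 by construction
  hept <- matrix(0.25, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  hept[, 1] <- c(0.7, 0.1, 0.1, 0.1)
  hept[, 2] <- c(0.1, 0.7, 0.1, 0.1)
  non <- matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- rss_model(hept, non, 12)
  expect_equal(score_rss_window(m, "ACAAAAA", "AAAAAAAAA"),
               log2(0.7 / 0.25) + log2(0.7 / 0.25))
  expect_equal(score_rss_window(m, "CAAAAAA", "AAAAAAAAA"),
               log2(0.1 / 0.25) + log2(0.1 / 0.25))
  expect_equal(score_rss_window(m, paste(rep("N", 7), collapse = ""),
                                paste(rep("N", 9), collapse = "")), 0)
})

test_that("a planted RSS is recovered at exact coordinates on both strands", {
  set.seed(8)
  m <- default_rss_model(23)
  left <- rand_nt_str(100); spacer <- rand_nt_str(23); right <- rand_nt_str(80)
  seq <- paste0(left, "CACAGTG", spacer, "ACAAAAACC", right)
  hits <- scan_rss(seq, m)
  hits <- hits[hits$canonical, ]
  expect_equal(nrow(hits), 1)
  expect_equal(hits$hept_start, 101)
  expect_equal(hits$hept_end, 107)
  expect_equal(hits$non_start, 131)
  expect_equal(hits$spacer_len, 23)
  expect_equal(hits$strand, "+")

  rc_hits <- scan_rss(revcomp(seq), m)
  rc_hits <- rc_hits[rc_hits$canonical, ]
  expect_equal(nrow(rc_hits), 1)
  expect_equal(rc_hits$strand, "-")
  L <- nchar(seq)
  expect_equal(rc_hits$hept_start, L - 107 + 1)
  expect_equal(rc_hits$hept_end, L - 101 + 1)
})

test_that("scanning is strand symmetric and threshold monotone", {
  set.seed(21)
  m <- default_rss_model(12)
  seq <- paste0(rand_nt_str(60), "CACAGTG", rand_nt_str(12), "ACAAAAACC",
                rand_nt_str(40), revcomp("ACAAAAACC"), rand_nt_str(13),
                revcomp("CACAGTG"), rand_nt_str(50))
  fwd <- scan_rss(seq, m)
  rev <- scan_rss(revcomp(seq), m)
  L <- nchar(seq)
  # mirrored coordinates with flipped strand reproduce the forward hits
  mirrored <- data.frame(
    hept_start = L - rev$hept_end + 1, hept_end = L - rev$hept_start + 1,
    strand = ifelse(rev$strand == "+", "-", "+"),
    spacer_len = rev$spacer_len, score = rev$score)
  key <- function(d) {
    sort(sprintf("%d:%d:%s:%d:%.6f", d$hept_start, d$hept_end, d$strand,
                 d$spacer_len, d$score))
  }
  expect_equal(key(mirrored), key(fwd))

  # raising the threshold never adds hits
  thr <- seq(0.3, 1, by = 0.1) * rss_max_score(m)
  counts <- vapply(thr, function(t) nrow(scan_rss(seq, m, t)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("random sequence yields no hits at the maximum threshold", {
  m <- default_rss_model(23)
  for (s in 1:5) {
    set.seed(s)
    seq <- rand_nt_str(10000)
    hits <- scan_rss(seq, m, threshold = rss_max_score(m))
    expect_equal(nrow(hits[hits$canonical &
                             hits$nonamer == "ACAAAAACC", ]), 0)
  }
})

test_that("short sequences are rejected", {
  expect_error(scan_rss("ACGT", default_rss_model(12)), "shorter")
})
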