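# Canonical G4 finder, BED loading, positional binning and the
# hypergeometric bin co-occurrence test.

test_that("finder reports the canonical four-tract pattern", {
  hit <- find_g4(c(s1 = "GGGAGGGTGGGAAGGG"))
  expect_identical(hit$start, 0L)
  expect_identical(hit$end, 16L)
  expect_equal(hit$score, 12)  # four tracts of three guanines
  expect_identical(nrow(find_g4(c(s1 = "ATATATATAT"))), 0L)
  expect_error(find_g4(c(s1 = "GGXGG")), "only A, C, G, T, N")
})

test_that("reported hits re-check against the pattern independently", {
  sq <- gen_l1_sequences(list(subfamilies = data.frame(subfamily = "S", n = 6,
                                                       length = 3000),
                              n_g4 = 4, n_motif = 0, g4_region = c(0, 1)),
                         seed = 21)
  hits <- find_g4(sq$sequences)
  expect_gt(nrow(hits), 0)
  for (i in seq_len(nrow(hits))) {
    sub <- substr(sq$sequences[[hits$seqid[i]]], hits$start[i] + 1,
                  hits$end[i])
    expect_true(is_canonical_g4(sub))
  }
  # hits on one sequence never overlap
  for (id in unique(hits$seqid)) {
    h <- hits[hits$seqid == id, ]
    h <- h[order(h$start), ]
    if (nrow(h) > 1) expect_true(all(h$start[-1] >= h$end[-nrow(h)]))
  }
})

test_that("minus-strand scan is the reflected scan of the complement", {
  s <- c(x = "GGGAGGGTGGGAAGGG")
  rc <- c(x = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s[[1]]))))
  plus_on_rc <- find_g4(rc)
  minus_on_s <- find_g4(s, strand = "-")
  L <- nchar(s[[1]])
  expect_identical(sort(minus_on_s$start),
                   sort(L - plus_on_rc$end))
  # the original plus-strand hit is invisible to the minus-strand scan of a
  # sequence without a complementary pattern
  expect_identical(nrow(find_g4(c(x = "CCCACCCTCCCAACCC"))), 0L)
  expect_gt(nrow(find_g4(c(x = "CCCACCCTCCCAACCC"), strand = "-")), 0L)
})

test_that("BED loading filters on score inclusively and validates lines", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("s1\t10\t40\tG4\t44\t+",
               "s1\t50\t80\tG4\t45\t+",
               "s1\t90\t120\tG4\t46\t+"), bed)
  ints <- load_intervals(bed, min_score = 45)
  expect_identical(nrow(ints), 2L)
  expect_true(all(ints$score >= 45))
  writeLines(character(0), bed)
  expect_identical(nrow(load_intervals(bed)), 0L)
  writeLines("s1\t-5\t10\tG4\t50\t+", bed)
  expect_error(load_intervals(bed), "line 1")
  writeLines(c("s1\t1\t10\tG4\t50\t+", "s1\tbroken"), bed)
  expect_error(load_intervals(bed), "line 2")
})

test_that("bin assignment follows the half-open start convention", {
  lens <- c(s1 = 200L)
  p <- bin_profile(intervals("s1", 60, 75), lens, window = 50)
  expect_identical(p$assignments$bin, 1)
  expect_equal(p$assignments$rel_pos, 0.25)
  pb <- bin_profile(intervals("s1", 50, 55), lens, window = 50)
  expect_identical(pb$assignments$bin, 1)
  empty <- bin_profile(intervals(character(), integer(), integer()), lens)
  expect_true(empty$degenerate)
  expect_error(bin_profile(intervals("zz", 0, 10), lens), "unknown sequence")
})

test_that("profile counts sum to the features and density reaches one", {
  set.seed(9)
  lens <- c(a = 430L, b = 500L)
  st <- c(sample(0:420, 30, replace = TRUE), sample(0:490, 25, replace = TRUE))
  ints <- intervals(rep(c("a", "b"), c(30, 25)), st, st + 5)
  p <- bin_profile(ints, lens, window = 50)
  expect_equal(sum(p$profile$count), 55)
  expect_equal(max(p$profile$cumdensity), 1)
  expect_true(all(diff(p$profile$cumdensity) >= 0))
})

test_that("full co-localization gives the closed-form point-mass p", {
  # one 5000 bp sequence = 100 bins of 50; a and b each occupy the same 10
  lens <- c(s = 5000L)
  st <- seq(0, 4500, by = 500)[1:10]
  a <- intervals("s", st, st + 10)
  b <- intervals("s", st + 20, st + 30)
  res <- overlap_test(a, b, lens, window = 50)
  expect_identical(res$n_bins, 100L)
  expect_identical(res$both_bins, 10L)
  expect_equal(res$p, 1 / choose(100, 10))
})

test_that("bin co-occurrence p equals exhaustive enumeration on <= 15 bins", {
  set.seed(31)
  for (rep in 1:10) {
    nb <- sample(6:15, 1)
    lens <- c(s = nb * 50L)
    K <- sample(1:(nb - 1), 1); n <- sample(1:(nb - 1), 1)
    a_bins <- seq_len(K) - 1L  # oracle fixes a-bins to the first K
    b_bins <- sample(nb, n) - 1L
    a <- intervals("s", a_bins * 50L, a_bins * 50L + 10L)
    b <- intervals("s", b_bins * 50L + 20L, b_bins * 50L + 30L)
    res <- overlap_test(a, b, lens, window = 50)
    expect_equal(res$p, enum_hyper_tail(nb, K, n, res$both_bins),
                 tolerance = 1e-12)
  }
})

test_that("zero overlap of sparse features is unsurprising", {
  lens <- c(s = 50000L)  # 1000 bins
  a <- intervals("s", c(0, 5000), c(10, 5010))
  b <- intervals("s", c(20000, 30000), c(20010, 30010))
  res <- overlap_test(a, b, lens, window = 50)
  expect_identical(res$both_bins, 0L)
  expect_gte(res$p, 0.99)
  degen <- overlap_test(intervals(character(), integer(), integer()), b,
                        lens, window = 50)
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
})

test_that("strand control exceeds the test p under plus-strand planting", {
  sq <- gen_l1_sequences(list(subfamilies = data.frame(subfamily = "S", n = 8,
                                                       length = 6000),
                              n_g4 = 3, n_motif = 3, motif_colocal = 1),
                         seed = 41)
  lens <- setNames(nchar(sq$sequences), names(sq$sequences))
  g4 <- find_g4(sq$sequences)
  p_test <- overlap_test(g4, sq$motifs, lens)$p
  ctrl <- strand_control(sq$sequences, sq$motifs, lens)
  expect_gt(ctrl$p, p_test)
  expect_lt(p_test, 0.05)
})

test_that("co-occurrence p decreases in the planted co-localization rate", {
  med_p <- vapply(c(0, 0.5, 1), function(r) {
    ps <- vapply(1:20, function(s) {
      sq <- gen_l1_sequences(list(subfamilies = data.frame(subfamily = "S",
                                                           n = 4,
                                                           length = 4000),
                                  n_g4 = 3, n_motif = 3, motif_colocal = r,
                                  g4_region = c(0.3, 1)),
                             seed = 100 * r + s)
      lens <- setNames(nchar(sq$sequences), names(sq$sequences))
      overlap_test(find_g4(sq$sequences), sq$motifs, lens)$p
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(all(diff(med_p) < 0))
})
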