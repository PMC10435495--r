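# Generators: determinism, exact planted quantities, degenerate inputs.

test_that("gene universe is sized, unique and deterministic", {
  u <- gen_universe(10, seed = 1)
  expect_length(u, 10)
  expect_false(anyDuplicated(u) > 0)
  expect_identical(u, gen_universe(10, seed = 1))
  expect_length(gen_universe(20000, seed = 7), 20000)
  expect_error(gen_universe(0), "positive")
})

test_that("DE tables achieve requested set sizes and intersections exactly", {
  u <- gen_universe(20000)
  de <- gen_de_tables(u, list(conditions = c("a", "b"),
                              n_up = c(3968, 4758), n_down = c(3933, 2958),
                              shared_up = 2710, shared_down = 2038),
                      seed = 4)
  up <- lapply(de$tables, function(t) t$gene[t$fdr <= 0.05 & t$log2fc > 0])
  dn <- lapply(de$tables, function(t) t$gene[t$fdr <= 0.05 & t$log2fc < 0])
  expect_identical(lengths(up), c(a = 3968L, b = 4758L))
  expect_identical(lengths(dn), c(a = 3933L, b = 2958L))
  expect_length(intersect(up$a, up$b), 2710)
  expect_length(intersect(dn$a, dn$b), 2038)
  # the planted concordance reproduces the recorded Jaccard coefficients
  expect_equal(round(jaccard(up$a, up$b), 1), 0.5)
  expect_equal(round(jaccard(dn$a, dn$b), 1), 0.4)
})

test_that("DE construction handles identical-set and infeasible requests", {
  u <- gen_universe(100)
  de <- gen_de_tables(u, list(conditions = c("a", "b"),
                              n_up = 20, n_down = 10,
                              shared_up = 20, shared_down = 10), seed = 1)
  expect_setequal(de$truth$up_sets$a, de$truth$up_sets$b)
  expect_setequal(de$truth$down_sets$a, de$truth$down_sets$b)
  expect_error(gen_de_tables(u, list(conditions = c("a", "b"),
                                     n_up = c(10, 30), shared_up = 15)),
               "core exceeds")
  expect_error(gen_de_tables(u, list(conditions = c("a", "b"),
                                     n_up = c(60, 60), shared_up = 0)),
               "universe too small")
})

test_that("DE tables are deterministic for a fixed seed", {
  u <- gen_universe(500)
  spec <- list(conditions = c("a", "b"), n_up = c(50, 60), n_down = c(40, 30),
               shared_up = 20, shared_down = 10)
  expect_identical(gen_de_tables(u, spec, seed = 9),
                   gen_de_tables(u, spec, seed = 9))
})

test_that("planted G4 cassettes are recovered exactly under zero noise", {
  sq <- gen_l1_sequences(list(subfamilies = data.frame(subfamily = "L1MdTf",
                                                       n = 5, length = 6000),
                              n_g4 = 3, n_motif = 0), seed = 2)
  found <- find_g4(sq$sequences)
  expect_identical(found[, c("seqid", "start", "end")],
                   sq$g4[, c("seqid", "start", "end")])
  # all planted cassettes sit in the 3' half by default
  lens <- nchar(sq$sequences)
  expect_true(all(found$start >= lens[found$seqid] / 2))
})

test_that("featureless background yields no G4 hits", {
  sq <- gen_l1_sequences(list(subfamilies = data.frame(subfamily = "S",
                                                       n = 2, length = 500),
                              n_g4 = 0, n_motif = 0, g_freq = 0), seed = 3)
  expect_false(any(grepl("G", sq$sequences)))
  expect_identical(nrow(find_g4(sq$sequences)), 0L)
})

test_that("explicit motif intervals are planted verbatim and bounds-checked", {
  sq <- gen_l1_sequences(list(subfamilies = data.frame(subfamily = "S",
                                                       n = 1, length = 400),
                              n_g4 = 0,
                              motif_intervals = list(c(100, 120))), seed = 1)
  expect_identical(sq$motifs$start, 100L)
  expect_identical(sq$motifs$end, 120L)
  expect_error(gen_l1_sequences(list(subfamilies = data.frame(subfamily = "S",
                                                              n = 1,
                                                              length = 300),
                                     n_g4 = 0,
                                     motif_intervals = list(c(250, 320)))),
               "exceeds sequence length")
})

test_that("Ct tables encode the planted knockdown in closed form", {
  noiseless <- function(kd) {
    g <- gen_ct_table(list(targets = "L1", kd = kd, noise_sd = 0), seed = 1)
    ddct(g$ct)
  }
  expect_equal(noiseless(0.60)$kd_percent, 60)
  expect_equal(noiseless(0)$kd_percent, 0)
  expect_equal(noiseless(0.5)$ddct, 1)  # 2^-1 = 0.5
  expect_error(gen_ct_table(list(kd = 1)), "knockdown fraction")
  expect_error(gen_ct_table(list(kd = 0.5, replicates = 0)), "replicates")
})

test_that("planted off-target sites match the scanner's view exactly", {
  spec <- list(n_tx = 6, tx_len = 1500,
               planted = data.frame(guide = "shX", transcript = c(1, 2),
                                    mismatches = c(0, 1),
                                    orientation = c("sense", "antisense")),
               expressed = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  txo <- gen_transcriptome(spec, seed = 5)
  h0 <- scan_offtargets(txo$guides, txo$transcripts, max_mm = 0)
  expect_identical(nrow(h0), 1L)
  expect_identical(h0$transcript, "TX0001")
  expect_identical(h0$offset, txo$truth$sites$offset[1])
  h1 <- scan_offtargets(txo$guides, txo$transcripts, max_mm = 1)
  expect_identical(nrow(h1), 2L)
  # expressed flags planted in the count matrix match the CPM classifier
  expect_identical(unname(expressed_genes(txo$counts)),
                   unname(txo$truth$expressed))
})

test_that("radial sampling reproduces uniform bin weights at large n", {
  r <- gen_radial_cells(1e5, rep(1, 10), seed = 8)
  pct <- radial_distribution(r$depths, 10)$percent
  expect_true(all(abs(pct - 10) <= 1))
  expect_error(gen_radial_cells(10, rep(0, 10)), "not all zero")
})

test_that("chromatogram peaks encode planted methylation", {
  full <- gen_chromatogram(100, noise = 0, seed = 1)
  expect_equal(full$peaks$a_height, 0)
  expect_equal(methylation_percent(full$peaks$g_height,
                                   full$peaks$a_height), 100)
  mixed <- gen_chromatogram(c(80, 20), noise = 0, seed = 1)
  expect_equal(methylation_percent(mixed$peaks$g_height,
                                   mixed$peaks$a_height), c(80, 20))
})

test_that("fraction generator recovers chromatin-dominant planted truth", {
  fr <- gen_fraction_qpcr(seed = 6)
  pct <- fraction_percent(fr$levels)
  expect_equal(pct$chromatin, c(90.64, 92.12, 94.35), tolerance = 0.02)
  expect_equal(rowSums(pct[, c("cytosol", "nucleoplasm", "chromatin")]),
               rep(100, 3), ignore_attr = TRUE)
})

test_that("child seeds are fixed by the schedule and artifact-specific", {
  expect_identical(child_seed(1, "de"), child_seed(1, "de"))
  arts <- c("universe", "de", "sequences", "ct", "transcriptome",
            "radial", "chromatogram", "fractions")
  seeds <- vapply(arts, child_seed, integer(1), seed = 42)
  expect_false(anyDuplicated(seeds) > 0)
  expect_true(all(seeds >= 1 & seeds < 2^31))
})
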