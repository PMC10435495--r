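# Gene-set concordance metrics and the resampling enrichment test.

test_that("jaccard matches hand-worked values and its invariants", {
  expect_equal(jaccard(c("g1", "g2", "g3"), c("g2", "g3", "g4")), 0.5)
  A <- sprintf("x%d", 1:7)
  expect_equal(jaccard(A, A), 1)
  expect_equal(jaccard(A, character(0)), 0)
  expect_equal(jaccard(character(0), character(0)), 0)
  set.seed(1)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    expect_identical(jaccard(a, b), jaccard(b, a))
    expect_true(jaccard(a, b) >= 0 && jaccard(a, b) <= 1)
  }
})

test_that("fisher_overlap reproduces the closed-form full-overlap case", {
  u <- sprintf("g%02d", 1:10)
  ov <- fisher_overlap(u[1:5], u[1:5], u)
  expect_equal(ov$fisher_p, 1 / choose(10, 5))
  expect_identical(ov$intersection, 5L)
  # disjoint sets carry no enrichment signal
  ov0 <- fisher_overlap(u[1:5], u[6:10], u)
  expect_gte(ov0$fisher_p, 0.5)
  expect_error(fisher_overlap(c(u[1:3], "zz"), u[1:5], u), "subsets")
})

test_that("fisher_overlap equals exhaustive enumeration on small universes", {
  set.seed(42)
  for (rep in 1:15) {
    N <- sample(5:12, 1)
    u <- sprintf("g%02d", seq_len(N))
    a <- sample(u, sample(1:(N - 1), 1))
    b <- sample(u, sample(1:(N - 1), 1))
    expect_equal(fisher_overlap(a, b, u)$fisher_p, enum_overlap_p(a, b, u),
                 tolerance = 1e-12)
  }
})

test_that("resampling null moments converge to the hypergeometric moments", {
  u <- sprintf("g%03d", 1:60)
  q <- u[1:12]; tg <- u[30:49]
  r <- resample_enrichment(q, tg, u, B = 40000, seed = 3)
  N <- 60; K <- 20; n <- 12
  mu <- n * K / N
  v <- n * K / N * (N - K) / N * (N - n) / (N - 1)
  expect_equal(r$null_mean, mu, tolerance = 0.02)
  expect_equal(r$null_sd, sqrt(v), tolerance = 0.02)
})

test_that("maximal overlap gives an extreme upper-tail p", {
  u <- gen_universe(5000)
  q <- u[1:100]
  r <- resample_enrichment(q, q, u, B = 1000, seed = 1)
  expect_lt(r$p, 1e-6)
  expect_false(r$degenerate)
})

test_that("degenerate null falls back to the exact hypergeometric tail", {
  u <- sprintf("g%d", 1:20)
  r <- resample_enrichment(u, u[1:5], u, B = 100, seed = 1)
  expect_true(r$degenerate)
  expect_true(is.na(r$z))
  expect_equal(r$p, 1)  # overlap is forced, so the tail includes everything
  expect_error(resample_enrichment(character(0), u[1:5], u), "non-empty")
  expect_error(resample_enrichment(u[1:5], u[1:5], u, B = 1), "at least 2")
})

test_that("resampling is deterministic for a fixed seed", {
  u <- gen_universe(300)
  r1 <- resample_enrichment(u[1:30], u[20:80], u, B = 200, seed = 7)
  r2 <- resample_enrichment(u[1:30], u[20:80], u, B = 200, seed = 7)
  expect_identical(r1, r2)
})

test_that("normal-approximation p tracks the exact tail on small universes", {
  # the z-based p is a normal approximation without continuity correction,
  # so on a 20-gene universe it can deviate from the exact hypergeometric
  # tail by up to ~0.18 in the central range (the half-count shift at the null mean); against the same plain-z
  # formula evaluated at the exact moments (isolating resampling error) it
  # agrees tightly
  set.seed(5)
  u <- sprintf("g%02d", 1:20)
  for (rep in 1:10) {
    q <- sample(u, 8); tg <- sample(u, 10)
    r <- resample_enrichment(q, tg, u, B = 20000, seed = rep)
    k <- length(intersect(q, tg))
    p_exact <- phyper(k - 1, 10, 10, 8, lower.tail = FALSE)
    if (p_exact >= 0.001 && p_exact <= 0.999) {
      expect_lt(abs(r$p - p_exact), 0.2)
      mu <- 8 * 10 / 20
      sg <- sqrt(8 * 0.5 * 0.5 * 12 / 19)
      p_plain <- pnorm((k - mu) / sg, lower.tail = FALSE)
      expect_lt(abs(r$p - p_plain), 0.05)
    }
  }
})

test_that("BH adjustment matches the step-up formula and base behaviour", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  set.seed(2)
  p <- runif(25)
  expect_equal(bh_adjust(p), manual_bh(p))
  perm <- sample(25)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("multi-set enrichment corrects across the tested family", {
  u <- gen_universe(1000)
  res <- enrich_gene_sets(u[1:50],
                          list(hit = u[1:60], miss = u[500:700]),
                          u, B = 300, seed = 11)
  expect_identical(res$set, c("hit", "miss"))
  expect_equal(res$q, bh_adjust(res$p))
  expect_lt(res$q[1], 0.05)
})

test_that("consistent_degs recovers a planted common core exactly", {
  u <- gen_universe(4000)
  de <- gen_de_tables(u, list(conditions = c("a", "b", "c", "d"),
                              n_up = c(200, 220, 250, 240),
                              n_down = c(150, 140, 130, 120),
                              shared_up = 90, shared_down = 60), seed = 13)
  expect_setequal(consistent_degs(de$tables, "up"), de$truth$shared_up)
  expect_setequal(consistent_degs(de$tables, "down"), de$truth$shared_down)
  expect_error(consistent_degs(de$tables[1], "up"), "at least two")
})

test_that("consistent_degs of disjoint inputs is empty", {
  t1 <- data.frame(gene = c("a", "b"), log2fc = 1, fdr = 0.01)
  t2 <- data.frame(gene = c("c", "d"), log2fc = 1, fdr = 0.01)
  expect_length(consistent_degs(list(t1, t2), "up"), 0)
})

test_that("directional concordance partitions by sign pattern", {
  x <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(2, -1, 1),
                  fdr = c(0.01, 0.01, 0.2))
  y <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(-2, -1, 1),
                  fdr = c(0.01, 0.01, 0.01))
  cc <- directional_concordance(x, y)
  expect_identical(cc$up_down, "g1")
  expect_identical(cc$down_down, "g2")
  expect_length(cc$up_up, 0)
  same <- directional_concordance(x, x)
  expect_length(same$up_down, 0)
  expect_length(same$down_up, 0)
})

test_that("a planted opposite-direction block is counted exactly", {
  u <- gen_universe(6000)
  de <- gen_de_tables(u, list(conditions = c("vivo", "vitro"),
                              n_up = c(900, 700), n_down = c(600, 1000),
                              shared_up = 0, shared_down = 0,
                              opposite = 367), seed = 17)
  cc <- directional_concordance(de$tables$vivo, de$tables$vitro)
  expect_identical(unname(cc$counts["up_down"]), 367L)
  expect_setequal(cc$up_down, de$truth$opposite)
})
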