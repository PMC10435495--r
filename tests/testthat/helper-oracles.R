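# Independent oracles used across the suite. Each is deliberately naive and
# shares no code with the implementation it checks.

# Exhaustive-enumeration p-value for overlap enrichment: over all subsets of
# size |a| of the universe, the fraction with overlap >= k_obs with b.
enum_overlap_p <- function(a, b, universe) {
  k_obs <- length(intersect(a, b))
  subsets <- utils::combn(universe, length(a), simplify = FALSE)
  mean(vapply(subsets, function(s) length(intersect(s, b)) >= k_obs,
              logical(1)))
}

# Exhaustive-enumeration upper tail for the bin co-occurrence test: over all
# placements of n b-bins among N bins, the fraction sharing >= k bins with a
# fixed set of K a-bins.
enum_hyper_tail <- function(N, K, n, k) {
  placements <- utils::combn(N, n, simplify = FALSE)
  a_bins <- seq_len(K)
  mean(vapply(placements, function(s) length(intersect(s, a_bins)) >= k,
              logical(1)))
}

# Step-up BH adjustment written from the textbook formula.
manual_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Naive position-by-position k-mismatch scan of one pattern (already
# oriented) against one transcript string; returns 0-based offsets.
naive_scan_one <- function(tx, pattern, max_mm) {
  tc <- strsplit(tx, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  L <- length(tc); m <- length(pc)
  if (L < m) return(data.frame(offset = integer(), mismatches = integer()))
  hits <- list()
  for (i in 0:(L - m)) {
    mm <- 0L
    for (j in seq_len(m)) {
      if (tc[i + j] != pc[j]) mm <- mm + 1L
      if (mm > max_mm) break
    }
    if (mm <= max_mm)
      hits[[length(hits) + 1]] <- data.frame(offset = i, mismatches = mm)
  }
  if (length(hits) == 0)
    return(data.frame(offset = integer(), mismatches = integer()))
  do.call(rbind, hits)
}

# Independent re-check that a reported G4 hit matches the canonical pattern:
# the substring must decompose into >= 4 G-tracts of >= min_tract separated
# by loops of 1..max_loop, spanning the whole interval.
is_canonical_g4 <- function(sub, min_tract = 3, max_loop = 7) {
  pat <- sprintf("^G{%d,}([ACGTN]{1,%d}G{%d,}){3,}$",
                 min_tract, max_loop, min_tract)
  grepl(pat, sub)
}

rand_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
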