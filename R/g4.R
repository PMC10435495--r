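# Positional co-occurrence of predicted G-quadruplexes and protein binding
# sites along transposon sequences: a canonical-pattern G4 finder, BED
# interval loading, 50-bp binning with relative-position density, and a
# hypergeometric bin-overlap test with a minus-strand control.
#
# Intervals are 0-based half-open [start, end), as in BED.

#' Construct a validated interval table
#'
#' @param seqid Character vector of sequence identifiers.
#' @param start,end Integer 0-based half-open coordinates, `start < end`.
#' @param strand `"+"` or `"-"` (recycled).
#' @param score Numeric score (recycled; default `NA`).
#' @param label Feature label, e.g. `"G4"` or `"Suz12_site"` (recycled).
#' @param seq_lengths Optional named integer vector of sequence lengths; when
#'   given, intervals are checked to lie within bounds.
#' @return A data.frame of class `interval_set` with those six columns.
#' @export
intervals <- function(seqid, start, end, strand = "+", score = NA_real_,
                      label = "feature", seq_lengths = NULL) {
  n <- length(seqid)
  out <- data.frame(seqid = as.character(seqid),
                    start = as.integer(start), end = as.integer(end),
                    strand = rep_len(as.character(strand), n),
                    score = rep_len(as.numeric(score), n),
                    label = rep_len(as.character(label), n))
  if (nrow(out) > 0L) {
    if (any(out$start < 0L) || any(out$start >= out$end))
      stop_invalid("intervals must satisfy 0 <= start < end")
    if (!all(out$strand %in% c("+", "-")))
      stop_invalid("strand must be '+' or '-'")
    if (!is.null(seq_lengths)) {
      unknown <- setdiff(out$seqid, names(seq_lengths))
      if (length(unknown) > 0L)
        stop_invalid("interval on unknown sequence '%s'", unknown[[1L]])
      if (any(out$end > seq_lengths[out$seqid]))
        stop_invalid("interval exceeds sequence length")
    }
  }
  class(out) <- c("interval_set", "data.frame")
  out
}

# Internal: pattern and score of canonical G4 matches in one sequence string.
g4_scan_string <- function(s, min_tract, max_loop) {
  pat <- sprintf("G{%d,}(?:[ACGTN]{1,%d}?G{%d,}){3}",
                 min_tract, max_loop, min_tract)
  m <- gregexpr(pat, s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = integer(), end = integer(),
                                      score = numeric()))
  st <- as.integer(m) - 1L
  en <- st + attr(m, "match.length")
  score <- vapply(seq_along(st), function(i) {
    sub <- substr(s, st[i] + 1L, en[i])
    runs <- gregexpr("G+", sub)[[1L]]
    len <- attr(runs, "match.length")
    sum(len[len >= min_tract])
  }, numeric(1L))
  data.frame(start = st, end = en, score = score)
}

#' Find canonical G-quadruplex motifs
#'
#' Scans sequences for the canonical pattern of four runs of at least
#' `min_tract` guanines separated by loops of 1 to `max_loop` bases,
#' reporting non-overlapping left-greedy matches. The score is the total
#' number of guanines in the four (or more) G-tracts of the match. This is a
#' deliberately canonical-pattern finder — it does not model bulged or
#' imperfect quadruplexes — and results carry a `finder = "canonical"` tag;
#' externally predicted, scored G4 intervals can be supplied through
#' [load_intervals()] instead.
#'
#' @param seqs Named character vector of sequences (or a
#'   `Biostrings::DNAStringSet`) over the alphabet `A, C, G, T, N`.
#' @param min_tract Minimum G-run length (default 3).
#' @param max_loop Maximum loop length in bases (default 7).
#' @param strand `"+"` scans the given strand; `"-"` scans the reverse
#'   complement and reports reflected coordinates on the input sequence.
#' @return An `interval_set` with label `"G4"` and attribute
#'   `finder = "canonical"`.
#' @export
find_g4 <- function(seqs, min_tract = 3L, max_loop = 7L, strand = "+") {
  strand <- match.arg(strand, c("+", "-"))
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop_invalid("sequences must be named")
  if (any(grepl("[^ACGTN]", seqs)))
    stop_invalid("sequences may contain only A, C, G, T, N")
  hits <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    if (strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    h <- g4_scan_string(s, min_tract, max_loop)
    if (nrow(h) == 0L) return(NULL)
    if (strand == "-") {
      L <- nchar(seqs[[id]])
      h <- data.frame(start = L - h$end, end = L - h$start, score = h$score)
      h <- h[order(h$start), , drop = FALSE]
    }
    cbind(seqid = id, h)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(seqid = character(), start = integer(),
                       end = integer(), score = numeric())
  out <- intervals(hits$seqid, hits$start, hits$end, strand = strand,
                   score = hits$score, label = "G4")
  attr(out, "finder") <- "canonical"
  out
}

#' Load scored intervals from a BED file
#'
#' Reads a BED3-BED6 file into an `interval_set`, keeping records with score
#' at or above `min_score` (boundary inclusive; default 45, the conventional
#' threshold applied to quadruplex-prediction scores). Malformed lines raise
#' a parse error naming the offending line.
#'
#' @param path Path to a tab-separated BED file (no header).
#' @param min_score Minimum score to retain (default 45); use `-Inf` to keep
#'   everything.
#' @param seq_lengths Optional named lengths for bounds validation.
#' @param label Default label for BED3 records lacking a name field.
#' @return An `interval_set`.
#' @export
load_intervals <- function(path, min_score = 45, seq_lengths = NULL,
                           label = "feature") {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(intervals(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop_invalid("malformed BED line %d: fewer than 3 fields",
                 which(nf < 3L)[1L])
  get <- function(i, default) vapply(fields, function(f)
    if (length(f) >= i) f[[i]] else default, character(1L))
  start <- suppressWarnings(as.integer(get(2L, NA_character_)))
  end <- suppressWarnings(as.integer(get(3L, NA_character_)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L)
    stop_invalid("malformed BED line %d: non-integer coordinates", bad[[1L]])
  if (any(start < 0L))
    stop_invalid("malformed BED line %d: negative start", which(start < 0)[1L])
  score <- suppressWarnings(as.numeric(get(5L, NA_character_)))
  out <- intervals(get(1L, NA_character_), start, end,
                   strand = ifelse(get(6L, "+") %in% c("+", "-"),
                                   get(6L, "+"), "+"),
                   score = score,
                   label = ifelse(nzchar(get(4L, label)), get(4L, label), label),
                   seq_lengths = seq_lengths)
  # records without a score column are treated as score 0
  sc <- ifelse(is.na(out$score), 0, out$score)
  out[sc >= min_score, , drop = FALSE]
}

#' Write an interval set as BED6
#'
#' @param x An `interval_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  bed <- data.frame(x$seqid, x$start, x$end, x$label,
                    ifelse(is.na(x$score), 0, x$score), x$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Internal: per-interval bin assignment by START position.
assign_bins <- function(ints, seq_lengths, window) {
  if (window < 1L) stop_invalid("window must be at least 1 bp")
  unknown <- setdiff(ints$seqid, names(seq_lengths))
  if (length(unknown) > 0L)
    stop_invalid("interval on unknown sequence '%s'", unknown[[1L]])
  bin <- ints$start %/% window
  data.frame(seqid = ints$seqid, bin = bin,
             rel_pos = (bin * window) / seq_lengths[ints$seqid])
}

#' Bin feature positions along sequences
#'
#' Assigns each interval to the fixed-width bin containing its start
#' position (bins are half-open `[i*w, (i+1)*w)`; the last bin of a sequence
#' may be short), computes each feature's relative position as the bin start
#' divided by the sequence length — which allows pooling sequences of unequal
#' length — and accumulates the pooled cumulative density over relative
#' positions.
#'
#' @param ints An `interval_set`.
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param window Bin width in bp (default 50).
#' @return A list of class `binned_profile`: `window`, `assignments`
#'   (per-interval seqid/bin/relative position), `profile` (data.frame of
#'   distinct relative positions with `count` and `cumdensity`), `n_features`
#'   and a `degenerate` flag set when no feature exists.
#' @export
bin_profile <- function(ints, seq_lengths, window = 50L) {
  asg <- assign_bins(ints, seq_lengths, window)
  if (nrow(asg) == 0L) {
    prof <- data.frame(relative_position = numeric(), count = integer(),
                       cumdensity = numeric())
    return(structure(list(window = as.integer(window), assignments = asg,
                          profile = prof, n_features = 0L, degenerate = TRUE),
                     class = "binned_profile"))
  }
  tab <- table(asg$rel_pos)
  prof <- data.frame(relative_position = as.numeric(names(tab)),
                     count = as.integer(tab))
  prof <- prof[order(prof$relative_position), , drop = FALSE]
  prof$cumdensity <- cumsum(prof$count) / sum(prof$count)
  rownames(prof) <- NULL
  structure(list(window = as.integer(window), assignments = asg,
                 profile = prof, n_features = nrow(asg), degenerate = FALSE),
            class = "binned_profile")
}

#' Hypergeometric test for bin co-occurrence of two feature sets
#'
#' Discretizes every sequence into fixed-width bins and asks whether bins
#' containing a feature of `a` coincide with bins containing a feature of
#' `b` more often than expected by chance. With `N` total bins across all
#' sequences, `K` bins holding at least one a-feature, `n` bins holding at
#' least one b-feature and `k` bins holding both, the p-value is the
#' hypergeometric upper tail `P[X >= k]` — the peak-overlap statistic
#' popularized by genome-wide peak-merging tools, applied here on the bin
#' universe of the supplied sequences.
#'
#' @param a,b `interval_set`s referencing the same sequences.
#' @param seq_lengths Named integer vector of sequence lengths.
#' @param window Bin width in bp (default 50).
#' @return A list of class `overlap_test_result`: `n_bins`, `a_bins`,
#'   `b_bins`, `both_bins`, `p`, and `degenerate` (`TRUE` when either input
#'   is empty, in which case `p = 1`).
#' @export
overlap_test <- function(a, b, seq_lengths, window = 50L) {
  if (window < 1L) stop_invalid("window must be at least 1 bp")
  N <- sum(ceiling(seq_lengths / window))
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(structure(list(n_bins = N, a_bins = 0L, b_bins = 0L,
                          both_bins = 0L, p = 1, degenerate = TRUE),
                     class = "overlap_test_result"))
  key <- function(ints) {
    asg <- assign_bins(ints, seq_lengths, window)
    unique(paste(asg$seqid, asg$bin))
  }
  ka <- key(a); kb <- key(b)
  K <- length(ka); n <- length(kb); k <- length(intersect(ka, kb))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  structure(list(n_bins = as.integer(N), a_bins = K, b_bins = n,
                 both_bins = k, p = p, degenerate = FALSE),
            class = "overlap_test_result")
}

#' Minus-strand negative control for the bin co-occurrence test
#'
#' Re-runs [overlap_test()] with G4 motifs predicted on the minus strand of
#' the same sequences against the same binding sites. Because a plus-strand
#' RNA cannot fold quadruplexes encoded on the opposite strand, a strong
#' association that survives this control would indicate a compositional
#' artifact rather than a strand-specific structural signal.
#'
#' @param seqs Named character vector (or `DNAStringSet`) of plus-strand
#'   sequences.
#' @param b Binding-site `interval_set`.
#' @param seq_lengths Named lengths; defaults to `nchar(seqs)`.
#' @param window Bin width in bp (default 50).
#' @param min_tract,max_loop Passed to [find_g4()].
#' @return An `overlap_test_result` (degenerate when no minus-strand G4
#'   exists).
#' @export
strand_control <- function(seqs, b, seq_lengths = NULL, window = 50L,
                           min_tract = 3L, max_loop = 7L) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(seq_lengths))
    seq_lengths <- stats::setNames(nchar(seqs), names(seqs))
  g4m <- find_g4(seqs, min_tract = min_tract, max_loop = max_loop,
                 strand = "-")
  overlap_test(g4m, b, seq_lengths, window = window)
}

#' @export
print.overlap_test_result <- function(x, ...) {
  cat(sprintf("Bin co-occurrence: %d/%d a-bins, %d/%d b-bins, %d shared\n",
              x$a_bins, x$n_bins, x$b_bins, x$n_bins, x$both_bins))
  cat(sprintf("  hypergeometric upper-tail p = %.3g%s\n", x$p,
              if (x$degenerate) " (degenerate: empty input)" else ""))
  invisible(x)
}
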