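# End-to-end k-mismatch scan of shRNA guide sequences against a transcript
# set, with expressed/non-expressed classification from a count matrix.

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# Hamming mismatch counts of `guide` against every window of one transcript;
# vectorized over offsets (one pass per guide position). 'N' in the
# transcript never equals a guide base, so it counts as a mismatch.
window_mismatches <- function(tx_chars, guide_chars) {
  L <- length(tx_chars); m <- length(guide_chars)
  n_win <- L - m + 1L
  if (n_win < 1L) return(integer(0L))
  mm <- integer(n_win)
  for (j in seq_len(m))
    mm <- mm + (tx_chars[j:(n_win + j - 1L)] != guide_chars[j])
  mm
}

#' Scan shRNA guides against transcripts allowing up to k mismatches
#'
#' Reports every end-to-end (ungapped, full guide length) alignment of each
#' guide, in both orientations, against every transcript with Hamming
#' distance at most `max_mm`. Sense hits are windows matching the guide
#' itself; antisense hits are windows matching its reverse complement.
#' There are no indels, and each qualifying window is reported exactly once.
#'
#' @param guides Data.frame with columns `id` and `sequence`
#'   (A/C/G/T, 15-30 nt), or a single named character vector of guides.
#' @param transcripts Named character vector of transcript sequences (or a
#'   `Biostrings::DNAStringSet`); alphabet A/C/G/T/N. Duplicate transcript
#'   identifiers are rejected.
#' @param max_mm Maximum number of mismatches: 0, 1 or 2 (default 0).
#' @return A data.frame with columns `shrna`, `transcript`, `offset`
#'   (0-based), `orientation` (`"sense"`/`"antisense"`), `mismatches`.
#'   Empty (with a warning) when every transcript is shorter than the guide.
#' @export
scan_offtargets <- function(guides, transcripts, max_mm = 0L) {
  if (!max_mm %in% 0:2) stop_invalid("max_mm must be 0, 1 or 2")
  if (is.character(guides))
    guides <- data.frame(id = names(guides), sequence = unname(guides))
  if (!all(c("id", "sequence") %in% names(guides)))
    stop_invalid("guides must have columns id, sequence")
  guides$sequence <- toupper(guides$sequence)
  glen <- nchar(guides$sequence)
  if (any(glen < 15L | glen > 30L))
    stop_invalid("guide length must be between 15 and 30 nt")
  if (any(grepl("[^ACGT]", guides$sequence)))
    stop_invalid("guides may contain only A, C, G, T")
  if (methods::is(transcripts, "DNAStringSet"))
    transcripts <- stats::setNames(as.character(transcripts), names(transcripts))
  if (length(transcripts) == 0L) stop_invalid("transcript set is empty")
  if (is.null(names(transcripts)) || anyDuplicated(names(transcripts)))
    stop_invalid("transcripts must carry unique identifiers")
  transcripts <- toupper(transcripts)
  tx_chars <- lapply(transcripts, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  rows <- list()
  for (gi in seq_len(nrow(guides))) {
    gid <- guides$id[gi]
    patterns <- list(sense = guides$sequence[gi],
                     antisense = revcomp(guides$sequence[gi]))
    for (ori in names(patterns)) {
      pc <- strsplit(patterns[[ori]], "", fixed = TRUE)[[1L]]
      for (ti in names(tx_chars)) {
        mm <- window_mismatches(tx_chars[[ti]], pc)
        hit <- which(mm <= max_mm)
        if (length(hit) > 0L)
          rows[[length(rows) + 1L]] <-
            data.frame(shrna = gid, transcript = ti, offset = hit - 1L,
                       orientation = ori, mismatches = mm[hit])
      }
    }
  }
  if (length(rows) == 0L) {
    if (all(vapply(tx_chars, length, integer(1L)) < min(glen)))
      warning("every transcript is shorter than the guide", call. = FALSE)
    return(data.frame(shrna = character(), transcript = character(),
                      offset = integer(), orientation = character(),
                      mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$shrna, out$transcript, out$offset, out$orientation), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Counts-per-million normalization
#'
#' @param counts Numeric matrix of raw counts, genes in rows, samples in
#'   columns; column sums must be positive.
#' @return Matrix of the same shape whose columns each sum to 1e6.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_invalid("counts must be non-negative")
  tot <- colSums(counts)
  if (any(tot == 0)) stop_invalid("sample with zero total counts")
  sweep(counts, 2L, tot, "/") * 1e6
}

#' Flag expressed genes by a CPM threshold across samples
#'
#' A gene counts as expressed when its CPM is at least `cpm_min` in at least
#' `ceiling(sample_fraction * n_samples)` samples — the a-priori filter used
#' to include genes in differential-expression analysis (default: 2 CPM in
#' at least three quarters of the samples).
#'
#' @param counts Raw count matrix (genes x samples) with rownames.
#' @param cpm_min CPM threshold (default 2).
#' @param sample_fraction Required fraction of samples (default 0.75).
#' @return Named logical vector over the genes of `counts`.
#' @export
expressed_genes <- function(counts, cpm_min = 2, sample_fraction = 0.75) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop_invalid("count matrix is empty")
  if (is.null(rownames(counts))) stop_invalid("count matrix needs rownames")
  need <- ceiling(sample_fraction * ncol(counts))
  rowSums(cpm(counts) >= cpm_min) >= need
}

#' Annotate off-target hits with expression status
#'
#' Joins the expressed/non-expressed classification of [expressed_genes()]
#' onto a hit table; hit transcripts absent from the count matrix get `NA`
#' (unknown).
#'
#' @param hits Hit table from [scan_offtargets()].
#' @param counts Raw count matrix (genes x samples) with rownames matching
#'   transcript identifiers.
#' @inheritParams expressed_genes
#' @return `hits` with an added logical `expressed` column.
#' @export
classify_expressed <- function(hits, counts, cpm_min = 2,
                               sample_fraction = 0.75) {
  expr <- expressed_genes(counts, cpm_min, sample_fraction)
  hits$expressed <- unname(expr[match(hits$transcript, names(expr))])
  hits
}
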