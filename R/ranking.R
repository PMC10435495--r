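# Protein-RNA interaction ranking: combine a normalized interaction
# propensity, an RNA-binding-protein propensity and a motif-evidence
# component into one score in [0, 1], then rank candidate pairs.

#' Normalize an interaction propensity z-score to [0, 1]
#'
#' z-scores between -4 and 4 are mapped linearly onto `[0, 1]`; values under
#' -4 are assigned 0 and values above 4 are assigned 1.
#'
#' @param z Numeric vector of finite propensity z-scores.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' normalize_propensity(c(-5, 0, 4))  # 0, 0.5, 1
normalize_propensity <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z)))
    stop_invalid("z must be finite numeric")
  (pmin(pmax(z, -4), 4) + 4) / 8
}

#' Motif-evidence component of the ranking score
#'
#' 0 if no protein-specific RNA motif is found on the RNA, 0.5 if exactly one
#' occurrence is found, 1 if multiple occurrences are found.
#'
#' @param n Non-negative integer vector of motif occurrence counts.
#' @return Numeric vector over `{0, 0.5, 1}`.
#' @export
motif_component <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0) || any(n != floor(n)))
    stop_invalid("n must be a non-negative integer count")
  ifelse(n == 0, 0, ifelse(n == 1, 0.5, 1))
}

#' Combined protein-RNA ranking score
#'
#' Sums the three components — normalized propensity, RBP propensity and
#' motif component, each already in `[0, 1]` — and scales the sum back to
#' `[0, 1]` by dividing by 3. The score is strictly monotone in each
#' component, so the induced ranking does not depend on the scaling choice.
#'
#' @param norm_prop,rbp_prop,motif_comp Numeric vectors in `[0, 1]`.
#' @return Numeric vector in `[0, 1]`.
#' @export
ranking_score <- function(norm_prop, rbp_prop, motif_comp) {
  for (v in list(norm_prop, rbp_prop, motif_comp))
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0 | v > 1))
      stop_invalid("all ranking-score components must lie in [0, 1]")
  (norm_prop + rbp_prop + motif_comp) / 3
}

#' Rank protein-RNA interaction candidates
#'
#' Computes the ranking score for every record and sorts in decreasing score
#' order; rank 1 is the strongest candidate. Ties share a deterministic order
#' (lexicographic on protein then RNA identifier). A min-max rescale of the
#' scores over the supplied table is available behind `rescale = "minmax"`;
#' it changes the score values but never the ranking order.
#'
#' @param records Data.frame with columns `protein`, `rna`, `propensity_z`,
#'   `rbp_propensity`, `motif_count` and optionally `subfamily`.
#' @param rescale `"fixed"` (divide the component sum by 3, default) or
#'   `"minmax"` (rescale the sums over the table to span `[0, 1]`).
#' @return The input data.frame with added columns `normalized_propensity`,
#'   `motif_component`, `ranking_score` and `rank`, sorted by rank.
#' @export
rank_interactions <- function(records, rescale = c("fixed", "minmax")) {
  rescale <- match.arg(rescale)
  req <- c("protein", "rna", "propensity_z", "rbp_propensity", "motif_count")
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_invalid("records must be a non-empty data.frame")
  if (!all(req %in% names(records)))
    stop_invalid("records must have columns %s", paste(req, collapse = ", "))
  key <- paste(records$protein, records$rna, sep = "\r")
  if (anyDuplicated(key))
    stop_invalid("duplicate (protein, rna) pair: %s",
                 sub("\r", " / ", key[duplicated(key)][1L]))
  if (any(records$rbp_propensity < 0 | records$rbp_propensity > 1))
    stop_invalid("rbp_propensity must lie in [0, 1]")
  out <- records
  out$normalized_propensity <- normalize_propensity(records$propensity_z)
  out$motif_component <- motif_component(records$motif_count)
  sums <- out$normalized_propensity + out$rbp_propensity + out$motif_component
  out$ranking_score <- if (rescale == "fixed") sums / 3
    else if (diff(range(sums)) == 0) rep(1, length(sums))
    else (sums - min(sums)) / diff(range(sums))
  ord <- order(-out$ranking_score, out$protein, out$rna)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Five-number boxplot statistics
#'
#' Median and quartiles by linear interpolation between order statistics
#' (quantile type 7); whiskers extend the quartiles by 1.5 times the
#' interquartile range, clipped to the observed data range.
#'
#' @param values Non-empty numeric vector.
#' @return A list of class `box_stats`: `median`, `q25`, `q75`,
#'   `whisker_lo`, `whisker_hi`.
#' @export
box_stats <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values)))
    stop_invalid("values must be a non-empty finite numeric vector")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  structure(list(median = q[2L], q25 = q[1L], q75 = q[3L],
                 whisker_lo = max(q[1L] - 1.5 * iqr, min(values)),
                 whisker_hi = min(q[3L] + 1.5 * iqr, max(values))),
            class = "box_stats")
}

#' Per-subfamily motif burden
#'
#' Summarizes how many sequences in each subfamily host at least one binding
#' motif and the distribution of motif counts per sequence — the per
#' evolutionary time-point view of motif acquisition along a transposon
#' family's history.
#'
#' @param motif_hits Integer vector of motif counts, one per sequence.
#' @param groups Character or factor vector of subfamily labels, parallel to
#'   `motif_hits`.
#' @return A data.frame with one row per subfamily: `subfamily`,
#'   `n_sequences`, `fraction_with_motif`, quartile/whisker columns of the
#'   count distribution, plus a `counts` list-column of the raw counts.
#' @export
motif_burden <- function(motif_hits, groups) {
  if (length(motif_hits) != length(groups))
    stop_invalid("motif_hits and groups must have equal length")
  if (any(is.na(groups)) || any(!nzchar(as.character(groups))))
    stop_invalid("every sequence needs a subfamily label")
  if (any(motif_hits < 0) || any(motif_hits != floor(motif_hits)))
    stop_invalid("motif_hits must be non-negative integer counts")
  groups <- as.character(groups)
  levs <- unique(groups)
  rows <- lapply(levs, function(g) {
    cnt <- motif_hits[groups == g]
    bs <- box_stats(cnt)
    data.frame(subfamily = g, n_sequences = length(cnt),
               fraction_with_motif = mean(cnt >= 1),
               median = bs$median, q25 = bs$q25, q75 = bs$q75,
               whisker_lo = bs$whisker_lo, whisker_hi = bs$whisker_hi)
  })
  out <- do.call(rbind, rows)
  out$counts <- lapply(levs, function(g) motif_hits[groups == g])
  out
}
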