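# Gene-set concordance metrics and the resampling overlap-enrichment test.
#
# Gene sets are plain character vectors of identifiers; the universe is the
# background of expressed genes against which enrichment is judged.

#' Jaccard similarity between two gene sets
#'
#' `|A intersect B| / |A union B|`, defined as 0 when both sets are empty.
#'
#' @param a,b Character vectors of gene identifiers.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' jaccard(c("g1", "g2", "g3"), c("g2", "g3", "g4"))  # 0.5
jaccard <- function(a, b) {
  a <- clean_ids(a, "set a"); b <- clean_ids(b, "set b")
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' One-sided Fisher's exact test for gene-set overlap
#'
#' Tests enrichment of the overlap between two gene sets against a finite
#' universe using the hypergeometric 2x2 table: membership in `a` crossed
#' with membership in `b` over all genes of `universe`.
#'
#' @param a,b Character vectors of gene identifiers; must be subsets of
#'   `universe`.
#' @param universe Character vector, the expressed-gene background.
#' @param alternative `"greater"` (enrichment, default), `"less"` or
#'   `"two.sided"`.
#' @return A list of class `overlap_summary` with elements `intersection`,
#'   `jaccard`, `fisher_p`, `odds_ratio`, and the table margins.
#' @export
fisher_overlap <- function(a, b, universe, alternative = "greater") {
  a <- clean_ids(a, "set a"); b <- clean_ids(b, "set b")
  universe <- clean_ids(universe, "universe")
  if (length(universe) == 0L) stop_invalid("universe must be non-empty")
  bad <- c(setdiff(a, universe), setdiff(b, universe))
  if (length(bad) > 0L)
    stop_invalid("sets must be subsets of the universe (%d foreign ids, e.g. '%s')",
                 length(bad), bad[[1L]])
  k <- length(intersect(a, b))
  tab <- matrix(c(k,
                  length(a) - k,
                  length(b) - k,
                  length(universe) - length(a) - length(b) + k),
                nrow = 2L)
  ft <- stats::fisher.test(tab, alternative = alternative)
  structure(list(intersection = k,
                 jaccard = jaccard(a, b),
                 fisher_p = unname(ft$p.value),
                 odds_ratio = unname(ft$estimate),
                 n_a = length(a), n_b = length(b), n_universe = length(universe),
                 alternative = alternative),
            class = "overlap_summary")
}

#' Resampling overlap-enrichment test
#'
#' Measures whether `query` overlaps `target` more than expected for a random
#' gene set of the same size drawn from the expressed-gene universe. For each
#' of `B` iterations an equal number of genes is drawn uniformly without
#' replacement from the universe and its overlap with `target` recorded; the
#' observed overlap is converted to a z-score against the resampled null and
#' then to an upper-tail normal p-value (enrichment). When the null is
#' degenerate (zero resampling standard deviation) the exact hypergeometric
#' upper tail is used instead and the result is flagged.
#'
#' @param query,target Character vectors of gene identifiers, subsets of
#'   `universe`; both non-empty.
#' @param universe Character vector of background identifiers.
#' @param B Number of resampling iterations (default 1000).
#' @param seed Optional integer seed for reproducible draws.
#' @param alternative `"greater"` (enrichment, default) or `"less"`
#'   (depletion; lower-tail p).
#' @return A list of class `enrichment_result` with `k_obs`, `B`,
#'   `null_mean`, `null_sd`, `z`, `p` and `degenerate` (logical, `TRUE` when
#'   the hypergeometric fallback was taken).
#' @export
resample_enrichment <- function(query, target, universe, B = 1000L,
                                seed = NULL, alternative = "greater") {
  alternative <- match.arg(alternative, c("greater", "less"))
  query <- clean_ids(query, "query"); target <- clean_ids(target, "target")
  universe <- clean_ids(universe, "universe")
  if (length(query) == 0L || length(target) == 0L)
    stop_invalid("query and target must be non-empty")
  if (B < 2L) stop_invalid("B must be at least 2")
  bad <- c(setdiff(query, universe), setdiff(target, universe))
  if (length(bad) > 0L)
    stop_invalid("query and target must be subsets of the universe (e.g. '%s')",
                 bad[[1L]])
  N <- length(universe); nq <- length(query)
  in_target <- universe %in% target
  k_obs <- length(intersect(query, target))
  null_k <- with_seed(seed, {
    vapply(seq_len(B),
           function(i) sum(in_target[sample.int(N, nq, useHash = FALSE)]),
           integer(1L))
  })
  mu <- mean(null_k); s <- stats::sd(null_k)
  nt <- sum(in_target)
  if (s == 0) {
    # |query| == |universe| or similar degenerate null: exact tail instead
    p <- if (alternative == "greater")
      stats::phyper(k_obs - 1L, nt, N - nt, nq, lower.tail = FALSE)
    else stats::phyper(k_obs, nt, N - nt, nq)
    z <- NA_real_
    degenerate <- TRUE
  } else {
    z <- (k_obs - mu) / s
    p <- stats::pnorm(z, lower.tail = (alternative == "less"))
    degenerate <- FALSE
  }
  structure(list(k_obs = k_obs, B = as.integer(B), null_mean = mu, null_sd = s,
                 z = z, p = p, alternative = alternative,
                 degenerate = degenerate),
            class = "enrichment_result")
}

#' Test one query set against many gene sets, with BH correction
#'
#' Runs [resample_enrichment()] of `query` against each element of `targets`
#' and adjusts the resulting p-values with the Benjamini-Hochberg step-up
#' procedure; the family for correction is the full collection of gene sets
#' tested in the call. Significance threshold convention: 0.05 on `q`.
#'
#' @inheritParams resample_enrichment
#' @param targets Named list of character vectors (the gene sets of interest).
#' @return A data.frame with columns `set`, `k_obs`, `null_mean`, `null_sd`,
#'   `z`, `p`, `q`.
#' @export
enrich_gene_sets <- function(query, targets, universe, B = 1000L,
                             seed = NULL, alternative = "greater") {
  if (!is.list(targets) || length(targets) == 0L)
    stop_invalid("targets must be a non-empty named list of gene sets")
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    stop_invalid("every target gene set must be named")
  seeds <- if (is.null(seed)) vector("list", length(targets))
           else as.list(seed + seq_along(targets) - 1L)
  rows <- mapply(function(tg, s) {
    r <- resample_enrichment(query, tg, universe, B = B, seed = s,
                             alternative = alternative)
    data.frame(k_obs = r$k_obs, null_mean = r$null_mean, null_sd = r$null_sd,
               z = r$z, p = r$p)
  }, targets, seeds, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  out <- cbind(set = names(targets), out)
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `p.adjust(method = "BH")`: adjusted values
#' are capped at 1 and returned in input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of the same length.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stop_invalid("pvals must be numeric")
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_invalid("all p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# Significant genes of a DE table (columns gene, log2fc, fdr) in a direction.
de_significant <- function(de, direction = c("up", "down"), threshold = 0.05) {
  direction <- match.arg(direction)
  req <- c("gene", "log2fc", "fdr")
  if (!all(req %in% names(de)))
    stop_invalid("DE table must have columns %s", paste(req, collapse = ", "))
  if (any(de$fdr < 0 | de$fdr > 1, na.rm = TRUE))
    stop_invalid("fdr values must lie in [0, 1]")
  keep <- !is.na(de$fdr) & de$fdr <= threshold &
    (if (direction == "up") de$log2fc > 0 else de$log2fc < 0)
  unique(trimws(as.character(de$gene[keep])))
}

#' Consistently dysregulated genes across comparisons
#'
#' Returns the genes that are significant (FDR at or below `threshold`) with
#' the stated direction of change in every one of the supplied
#' differential-expression tables — the stringent intersection filter used to
#' combine independent knockdown comparisons.
#'
#' @param comparisons List of at least two DE tables, each a data.frame with
#'   columns `gene`, `log2fc`, `fdr`.
#' @param direction `"up"` or `"down"`.
#' @param threshold Significance threshold on `fdr` (default 0.05).
#' @return Character vector of gene identifiers.
#' @export
consistent_degs <- function(comparisons, direction = c("up", "down"),
                            threshold = 0.05) {
  direction <- match.arg(direction)
  if (!is.list(comparisons) || length(comparisons) < 2L)
    stop_invalid("need at least two DE tables")
  sets <- lapply(comparisons, de_significant, direction = direction,
                 threshold = threshold)
  Reduce(intersect, sets)
}

#' Directional concordance between two differential-expression tables
#'
#' Partitions the genes significant in both tables by the pattern of their
#' fold-change signs, exposing concordant (up/up, down/down) and opposite
#' (up/down, down/up) behaviour between two systems — e.g. an in vivo versus
#' an in vitro knockdown.
#'
#' @param de_x,de_y Data.frames with columns `gene`, `log2fc`, `fdr`.
#' @param threshold Significance threshold on `fdr` (default 0.05).
#' @return A list of class `directional_concordance` with the four gene-set
#'   members (`up_up`, `down_down`, `up_down`, `down_up`) and a `counts`
#'   named integer vector.
#' @export
directional_concordance <- function(de_x, de_y, threshold = 0.05) {
  ux <- de_significant(de_x, "up", threshold)
  dx <- de_significant(de_x, "down", threshold)
  uy <- de_significant(de_y, "up", threshold)
  dy <- de_significant(de_y, "down", threshold)
  out <- list(up_up = intersect(ux, uy),
              down_down = intersect(dx, dy),
              up_down = intersect(ux, dy),
              down_up = intersect(dx, uy))
  out$counts <- vapply(out[1:4], length, integer(1L))
  class(out) <- "directional_concordance"
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Resampling overlap enrichment (B = %d)\n", x$B))
  cat(sprintf("  observed overlap: %d\n  null mean (sd): %.3f (%.3f)\n",
              x$k_obs, x$null_mean, x$null_sd))
  if (x$degenerate)
    cat(sprintf("  degenerate null; exact hypergeometric p = %.3g\n", x$p))
  else
    cat(sprintf("  z = %.3f, %s-tail p = %.3g\n", x$z,
                if (x$alternative == "greater") "upper" else "lower", x$p))
  invisible(x)
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("Gene-set overlap: %d of %d x %d on universe %d\n",
              x$intersection, x$n_a, x$n_b, x$n_universe))
  cat(sprintf("  Jaccard = %.4f, Fisher %s p = %.3g, OR = %.3g\n",
              x$jaccard, x$alternative, x$fisher_p, x$odds_ratio))
  invisible(x)
}
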