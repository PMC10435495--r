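# Small quantification formulas: delta-delta-Ct knockdown, radial cell
# distribution, bisulfite peak-height methylation, subcellular fractions.

#' Knockdown quantification by the delta-delta-Ct method
#'
#' For each condition, delta-Ct is the mean target Ct minus the mean
#' reference Ct; delta-delta-Ct is the treated minus the control delta-Ct.
#' Relative expression is `2^-ddct` under the conventional assumption of
#' 100% primer efficiency (amplification base 2; an `efficiency` parameter
#' is exposed for calibrated assays), and knockdown percent is
#' `100 * (1 - relative expression)`. The standard error of delta-delta-Ct
#' is propagated from the replicate variances of the four Ct means and
#' mapped to the expression scale by the delta method.
#'
#' @param ct Data.frame with columns `condition` (`"control"`/`"treated"`),
#'   `ct_target` and `ct_ref`, one row per replicate. Extra columns
#'   (`sample`, `target`, `reference`, `replicate`) are ignored.
#' @param efficiency Amplification efficiency as fold change per cycle
#'   (default 2, i.e. perfect doubling).
#' @return A list of class `knockdown_result`: `dct_control`, `dct_treated`,
#'   `ddct`, `ddct_se`, `rel_expr`, `rel_expr_se`, `kd_percent`.
#' @export
#' @examples
#' ct <- data.frame(condition = rep(c("control", "treated"), each = 3),
#'                  ct_target = c(24, 24, 24, 25, 25, 25),
#'                  ct_ref    = rep(20, 6))
#' ddct(ct)$kd_percent  # 50
ddct <- function(ct, efficiency = 2) {
  req <- c("condition", "ct_target", "ct_ref")
  if (!is.data.frame(ct) || !all(req %in% names(ct)))
    stop_invalid("ct table needs columns %s", paste(req, collapse = ", "))
  if (!all(c("control", "treated") %in% ct$condition))
    stop_invalid("both control and treated conditions are required")
  if (any(ct$ct_target <= 0) || any(ct$ct_ref <= 0))
    stop_invalid("Ct values must be positive")
  grp <- function(cond) ct[ct$condition == cond, , drop = FALSE]
  dstat <- function(g) {
    se2 <- function(x) if (length(x) > 1L) stats::var(x) / length(x) else 0
    list(d = mean(g$ct_target) - mean(g$ct_ref),
         v = se2(g$ct_target) + se2(g$ct_ref))
  }
  c0 <- dstat(grp("control")); c1 <- dstat(grp("treated"))
  dd <- c1$d - c0$d
  dd_se <- sqrt(c0$v + c1$v)
  rel <- efficiency^(-dd)
  structure(list(dct_control = c0$d, dct_treated = c1$d,
                 ddct = dd, ddct_se = dd_se,
                 rel_expr = rel,
                 rel_expr_se = log(efficiency) * rel * dd_se,
                 kd_percent = 100 * (1 - rel)),
            class = "knockdown_result")
}

#' Radial distribution of cells across equal-sized bins
#'
#' Positions are depths in `[0, 1]` measured from the pia (0) to the upper
#' edge of the white matter (1). The axis is divided into `n_bins`
#' equal-sized half-open bins `[i/n, (i+1)/n)`, with depth exactly 1 closed
#' into the last bin; bin 1 is the bin adjacent to the pia. Returns the
#' percentage of cells per bin.
#'
#' @param depths Numeric vector of relative depths in `[0, 1]`.
#' @param n_bins Number of bins (default 10).
#' @return A list of class `radial_distribution`: `n_bins`, `counts`,
#'   `percent` (sums to 100).
#' @export
radial_distribution <- function(depths, n_bins = 10L) {
  if (length(depths) == 0L) stop_invalid("no cell positions supplied")
  if (n_bins < 1L) stop_invalid("n_bins must be at least 1")
  if (any(!is.finite(depths)) || any(depths < 0 | depths > 1))
    stop_invalid("depths must lie in [0, 1]")
  bin <- pmin(floor(depths * n_bins), n_bins - 1L) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(n_bins = as.integer(n_bins), counts = counts,
                 percent = 100 * counts / sum(counts)),
            class = "radial_distribution")
}

#' Percent methylation from bisulfite chromatogram peak heights
#'
#' On reverse-strand direct bisulfite sequencing, a methylated cytosine
#' reads as G and an unmethylated (converted) cytosine as A, so percent
#' methylation at a CpG is `100 * g / (g + a)` from the two peak heights.
#'
#' @param g,a Non-negative peak heights for G and A; vectors are paired
#'   element-wise.
#' @return Numeric vector of percentages in `[0, 100]`.
#' @export
#' @examples
#' methylation_percent(80, 20)  # 80
methylation_percent <- function(g, a) {
  if (any(g < 0) || any(a < 0)) stop_invalid("peak heights must be non-negative")
  if (any(g + a == 0))
    stop_invalid("percent methylation undefined when both peaks are zero")
  100 * g / (g + a)
}

#' Subcellular fraction percentages
#'
#' Converts per-compartment RNA levels (cytosol, nucleoplasm, chromatin)
#' into percentages of the total for each target RNA.
#'
#' @param levels Data.frame with columns `target`, `cytosol`, `nucleoplasm`,
#'   `chromatin` of non-negative levels, or a single named numeric vector of
#'   three compartments.
#' @return A data.frame of class `fraction_profile` with columns `target`,
#'   `cytosol`, `nucleoplasm`, `chromatin` holding percentages that sum to
#'   100 per row.
#' @export
#' @examples
#' fraction_percent(c(cytosol = 1, nucleoplasm = 1, chromatin = 2))
fraction_percent <- function(levels) {
  comp <- c("cytosol", "nucleoplasm", "chromatin")
  if (is.numeric(levels)) {
    if (!all(comp %in% names(levels)))
      stop_invalid("vector input needs names %s", paste(comp, collapse = ", "))
    levels <- data.frame(target = "target", cytosol = levels[["cytosol"]],
                         nucleoplasm = levels[["nucleoplasm"]],
                         chromatin = levels[["chromatin"]])
  }
  if (!all(c("target", comp) %in% names(levels)))
    stop_invalid("fraction table needs columns target, %s",
                 paste(comp, collapse = ", "))
  m <- as.matrix(levels[, comp])
  if (any(m < 0)) stop_invalid("compartment levels must be non-negative")
  tot <- rowSums(m)
  if (any(tot == 0)) stop_invalid("all compartments zero for some target")
  out <- data.frame(target = levels$target, 100 * m / tot)
  class(out) <- c("fraction_profile", "data.frame")
  out
}

#' @export
print.knockdown_result <- function(x, ...) {
  cat(sprintf("ddCt = %.3f (se %.3f); relative expression = %.3f; knockdown = %.1f%%\n",
              x$ddct, x$ddct_se, x$rel_expr, x$kd_percent))
  invisible(x)
}
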