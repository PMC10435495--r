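# Seeded synthetic-data generators. Every generator returns its artifact
# together with a machine-readable truth record of the planted quantities,
# so each downstream stage can be tested for exact recovery without any
# external download. All randomness flows from a single root seed through
# child_seed(), on a fixed schedule.

truth_record <- function(artifact, seed, ...) {
  list(artifact = artifact, seed = seed, ...)
}

#' Generate a synthetic expressed-gene universe
#'
#' Identifiers are synthetic uppercase tokens (`"G000001"`, ...) that cannot
#' collide with real gene symbols.
#'
#' @param n Number of genes (at least 1).
#' @param seed Integer seed (kept for interface symmetry; identifier
#'   construction is deterministic).
#' @return Character vector of `n` unique identifiers.
#' @export
gen_universe <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1L || n != floor(n))
    stop_invalid("n must be a positive integer")
  sprintf("G%06d", seq_len(n))
}

#' Generate differential-expression tables with exact planted intersections
#'
#' Builds one DE table (columns `gene`, `log2fc`, `fdr`) per condition such
#' that each condition's up- and down-regulated sets have exactly the
#' requested sizes and exactly the requested shared cores. Construction
#' samples the shared cores first and then disjoint per-condition
#' remainders, so all requested counts are achieved exactly rather than in
#' expectation: the pairwise intersection of any two conditions' up
#' (respectively down) sets equals `shared_up` (`shared_down`). Members get
#' `fdr` below the 0.05 significance threshold and sign-matched `log2fc`;
#' non-members get `fdr` above it.
#'
#' @param universe Character vector of gene identifiers.
#' @param de_spec List with elements:
#'   \describe{
#'     \item{conditions}{character vector of condition names (>= 1);}
#'     \item{n_up, n_down}{per-condition set sizes, recycled or named;}
#'     \item{shared_up, shared_down}{sizes of the cores common to all
#'       conditions (default 0);}
#'     \item{opposite}{number of genes up in the first condition and down in
#'       the second (default 0; needs >= 2 conditions).}
#'   }
#' @param seed Integer seed.
#' @return List with `tables` (named list of data.frames) and `truth` (the
#'   planted sets and achieved intersection sizes).
#' @export
gen_de_tables <- function(universe, de_spec, seed = 1L) {
  conds <- de_spec$conditions
  if (is.null(conds) || length(conds) < 1L)
    stop_invalid("de_spec$conditions must name at least one condition")
  nc <- length(conds)
  fill <- function(x, default = 0L) {
    if (is.null(x)) x <- default
    x <- rep_len(x, nc); names(x) <- conds; x
  }
  n_up <- fill(de_spec$n_up); n_down <- fill(de_spec$n_down)
  shared_up <- if (is.null(de_spec$shared_up)) 0L else de_spec$shared_up
  shared_down <- if (is.null(de_spec$shared_down)) 0L else de_spec$shared_down
  opp <- if (is.null(de_spec$opposite)) 0L else de_spec$opposite
  if (opp > 0L && nc < 2L)
    stop_invalid("an opposite block needs at least two conditions")
  if (shared_up > min(n_up) || shared_down > min(n_down))
    stop_invalid("requested shared core exceeds the smallest set size")
  uniq_up <- n_up - shared_up - c(opp, rep(0L, nc - 1L))
  uniq_down <- n_down - shared_down - if (nc >= 2L)
    c(0L, opp, rep(0L, nc - 2L)) else 0L
  if (any(uniq_up < 0L) || any(uniq_down < 0L))
    stop_invalid("requested intersections are infeasible for the set sizes")
  total <- shared_up + shared_down + opp + sum(uniq_up) + sum(uniq_down)
  if (total > length(universe))
    stop_invalid("universe too small: need %d distinct genes, have %d",
                 total, length(universe))
  with_seed(seed, {
    pool <- sample(universe)
    take <- local({
      cursor <- 0L
      function(k) {
        if (k == 0L) return(character(0L))
        out <- pool[(cursor + 1L):(cursor + k)]
        cursor <<- cursor + k
        out
      }
    })
    core_up <- take(shared_up); core_down <- take(shared_down)
    opp_genes <- take(opp)
    up_sets <- down_sets <- stats::setNames(vector("list", nc), conds)
    for (i in seq_len(nc)) {
      up_sets[[i]] <- c(core_up, if (i == 1L) opp_genes, take(uniq_up[i]))
      down_sets[[i]] <- c(core_down, if (i == 2L) opp_genes, take(uniq_down[i]))
    }
    tables <- stats::setNames(vector("list", nc), conds)
    for (i in seq_len(nc)) {
      up <- universe %in% up_sets[[i]]; down <- universe %in% down_sets[[i]]
      log2fc <- stats::runif(length(universe), -0.4, 0.4)
      log2fc[up] <- stats::runif(sum(up), 0.5, 4)
      log2fc[down] <- -stats::runif(sum(down), 0.5, 4)
      fdr <- stats::runif(length(universe), 0.0501, 1)
      fdr[up | down] <- stats::runif(sum(up | down), 0, 0.0499)
      tables[[i]] <- data.frame(gene = universe, log2fc = log2fc, fdr = fdr)
    }
    truth <- truth_record("de_tables", seed,
                          conditions = conds,
                          up_sets = up_sets, down_sets = down_sets,
                          shared_up = core_up, shared_down = core_down,
                          opposite = opp_genes,
                          n_up = n_up, n_down = n_down,
                          shared_up_size = shared_up,
                          shared_down_size = shared_down,
                          opposite_size = opp)
    list(tables = tables, truth = truth)
  })
}

# A canonical G4 cassette: four G-tracts of `tract` guanines with 3-base
# non-G loops; found by find_g4 at its default parameters.
g4_cassette <- function(tract = 4L) {
  paste0(strrep("G", tract),
         paste0(rep(paste0("ACT", strrep("G", tract)), 3L), collapse = ""))
}

# Background with no G-run of length >= 3 outside planted tracts: draw from
# A/C/G/T with G at `g_freq`, then force the base after any "GG" to be non-G.
gen_background <- function(len, g_freq) {
  probs <- c(A = (1 - g_freq) / 3, C = (1 - g_freq) / 3, G = g_freq,
             T = (1 - g_freq) / 3)
  x <- sample(names(probs), len, replace = TRUE, prob = probs)
  if (g_freq > 0 && len >= 3L) {
    repeat {
      g <- x == "G"
      # positions completing a G-run of length 3
      run3 <- g & c(FALSE, g[-len]) & c(FALSE, FALSE, g[-c(len - 1L, len)])
      bad <- which(run3)
      if (length(bad) == 0L) break
      x[bad] <- sample(c("A", "C", "T"), length(bad), replace = TRUE)
    }
  }
  x
}

#' Generate L1-like sequences with planted G4 tracts and binding motifs
#'
#' Produces a panel of synthetic transposon-like sequences grouped into
#' subfamilies. The background is drawn over A/C/T plus G at a reduced,
#' configurable frequency and is post-processed to contain no G-run of
#' length three or more, so the only canonical G-quadruplex motifs present
#' are the planted cassettes — under zero noise every planted feature is
#' recovered exactly by [find_g4()]. Binding motifs are planted as
#' coordinate intervals (their base content is irrelevant to downstream
#' stages); a configurable fraction is co-localized with a planted G4 (start
#' in the same bin), the rest fall in bins free of G4 starts.
#'
#' @param seq_spec List with elements:
#'   \describe{
#'     \item{subfamilies}{data.frame with columns `subfamily`, `n`, `length`
#'       (lengths >= 300);}
#'     \item{n_g4}{planted G4 cassettes per sequence (default 3);}
#'     \item{g4_region}{relative interval for G4 placement (default
#'       `c(0.5, 1)`, the 3' half);}
#'     \item{n_motif}{planted motifs per sequence (default 2);}
#'     \item{motif_len}{motif width in bp (default 15);}
#'     \item{motif_colocal}{fraction of motifs placed in the bin of a planted
#'       G4 (default 0);}
#'     \item{motif_intervals}{optional list of `c(start, end)` pairs planted
#'       verbatim in every sequence instead of random motifs;}
#'     \item{window}{bin width used for co-localization (default 50);}
#'     \item{g_freq}{background G frequency (default 0.1);}
#'     \item{motif_label}{label for motif intervals (default `"site"`).}
#'   }
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector), `g4` and `motifs`
#'   (`interval_set`s of the planted features) and `truth`.
#' @export
gen_l1_sequences <- function(seq_spec, seed = 1L) {
  sf <- seq_spec$subfamilies
  if (is.null(sf) || !all(c("subfamily", "n", "length") %in% names(sf)))
    stop_invalid("seq_spec$subfamilies needs columns subfamily, n, length")
  if (any(sf$length < 300L)) stop_invalid("sequence lengths must be >= 300 bp")
  n_g4 <- seq_spec$n_g4 %||% 3L
  g4_region <- seq_spec$g4_region %||% c(0.5, 1)
  n_motif <- seq_spec$n_motif %||% 2L
  motif_len <- seq_spec$motif_len %||% 15L
  colocal <- seq_spec$motif_colocal %||% 0
  window <- seq_spec$window %||% 50L
  g_freq <- seq_spec$g_freq %||% 0.1
  label <- seq_spec$motif_label %||% "site"
  fixed_motifs <- seq_spec$motif_intervals
  cassette <- g4_cassette()
  clen <- nchar(cassette)
  with_seed(seed, {
    seqs <- character(0L); g4_rows <- list(); motif_rows <- list()
    for (r in seq_len(nrow(sf))) for (i in seq_len(sf$n[r])) {
      id <- sprintf("%s_%03d", sf$subfamily[r], i)
      L <- sf$length[r]
      x <- gen_background(L, g_freq)
      # G4 placement: one cassette per equal slot of the allowed region,
      # jittered, with one guard base on each side kept non-G
      g4_starts <- integer(0L)
      if (n_g4 > 0L) {
        lo <- ceiling(g4_region[1L] * L); hi <- floor(g4_region[2L] * L)
        slot <- (hi - lo - 2L) / n_g4
        if (slot < clen + 2L)
          stop_invalid("planted G4 cassettes do not fit the requested region")
        for (k in seq_len(n_g4)) {
          s0 <- lo + floor((k - 1L) * slot)
          st <- s0 + sample.int(max(1L, floor(slot) - clen - 2L), 1L)
          x[(st + 1L):(st + clen)] <- strsplit(cassette, "")[[1L]]
          if (st >= 1L && x[st] == "G") x[st] <- "A"
          if (st + clen < L && x[st + clen + 1L] == "G") x[st + clen + 1L] <- "A"
          g4_starts <- c(g4_starts, st)
          g4_rows[[length(g4_rows) + 1L]] <-
            data.frame(seqid = id, start = st, end = st + clen)
        }
      }
      # motif placement (coordinates only; sequence content untouched)
      if (!is.null(fixed_motifs)) {
        for (iv in fixed_motifs) {
          if (iv[2L] > L) stop_invalid("planted motif exceeds sequence length")
          motif_rows[[length(motif_rows) + 1L]] <-
            data.frame(seqid = id, start = iv[1L], end = iv[2L])
        }
      } else if (n_motif > 0L) {
        g4_bins <- unique(g4_starts %/% window)
        all_bins <- 0L:((L - 1L) %/% window)
        free_bins <- setdiff(all_bins, g4_bins)
        for (k in seq_len(n_motif)) {
          in_g4_bin <- length(g4_bins) > 0L && stats::runif(1L) < colocal
          bin <- if (in_g4_bin) g4_bins[sample.int(length(g4_bins), 1L)]
                 else free_bins[sample.int(length(free_bins), 1L)]
          st <- min(bin * window + sample.int(window, 1L) - 1L, L - motif_len)
          motif_rows[[length(motif_rows) + 1L]] <-
            data.frame(seqid = id, start = st, end = st + motif_len)
        }
      }
      seqs[id] <- paste0(x, collapse = "")
    }
    mk <- function(rows, lab, sc) {
      if (length(rows) == 0L)
        return(intervals(character(), integer(), integer(), label = lab))
      d <- do.call(rbind, rows)
      intervals(d$seqid, d$start, d$end, score = sc, label = lab)
    }
    g4 <- mk(g4_rows, "G4", 16)
    motifs <- mk(motif_rows, label, 100)
    subfam <- sub("_[0-9]+$", "", names(seqs))
    truth <- truth_record("l1_sequences", seed,
                          subfamily = stats::setNames(subfam, names(seqs)),
                          g4 = g4, motifs = motifs,
                          n_g4 = n_g4, n_motif = if (is.null(fixed_motifs))
                            n_motif else length(fixed_motifs),
                          motif_colocal = colocal, window = window,
                          g_freq = g_freq)
    list(sequences = seqs, g4 = g4, motifs = motifs, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a qPCR Ct table with planted knockdown
#'
#' For each target the treated condition's target Ct is shifted by
#' `-log2(1 - kd)` relative to control (so the delta-delta-Ct pipeline
#' recovers the planted knockdown exactly under zero noise), plus Gaussian
#' replicate noise on each replicate's target Ct — equivalently, on the
#' replicate's delta-Ct, the reference assay acting as the anchor.
#'
#' @param ct_spec List with `targets` (character), `kd` (true knockdown
#'   fractions in `[0, 1)`, recycled), `replicates` (default 3), `noise_sd`
#'   (default 0.1), `base_ct_target` (default 24), `base_ct_ref`
#'   (default 20), `reference` (default `"UbC"`).
#' @param seed Integer seed.
#' @return List with `ct` (data.frame: `sample`, `condition`, `target`,
#'   `reference`, `replicate`, `ct_target`, `ct_ref`) and `truth`.
#' @export
gen_ct_table <- function(ct_spec, seed = 1L) {
  targets <- ct_spec$targets %||% "L1MdA"
  kd <- rep_len(ct_spec$kd %||% 0.6, length(targets))
  reps <- ct_spec$replicates %||% 3L
  noise <- ct_spec$noise_sd %||% 0.1
  b_t <- ct_spec$base_ct_target %||% 24
  b_r <- ct_spec$base_ct_ref %||% 20
  ref <- ct_spec$reference %||% "UbC"
  if (reps < 1L) stop_invalid("replicates must be at least 1")
  if (noise < 0) stop_invalid("noise_sd must be non-negative")
  if (any(kd < 0 | kd >= 1))
    stop_invalid("true knockdown fraction must lie in [0, 1)")
  with_seed(seed, {
    rows <- list()
    for (i in seq_along(targets)) {
      shift <- -log2(1 - kd[i])
      for (cond in c("control", "treated")) for (r in seq_len(reps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sprintf("%s_%s", cond, targets[i]),
          condition = cond, target = targets[i], reference = ref,
          replicate = r,
          # replicate noise enters on the target Ct, i.e. at the level of
          # the replicate's delta-Ct; the reference assay is the anchor
          ct_target = b_t + (cond == "treated") * shift +
            stats::rnorm(1L, 0, noise),
          ct_ref = b_r)
      }
    }
    ct <- do.call(rbind, rows)
    list(ct = ct,
         truth = truth_record("ct_table", seed,
                              kd_percent = stats::setNames(100 * kd, targets),
                              replicates = reps, noise_sd = noise))
  })
}

#' Generate a synthetic transcriptome with planted shRNA off-target sites
#'
#' Transcripts are uniform random A/C/G/T sequences; each planted site
#' substitutes the guide (or its reverse complement) at a recorded offset
#' with a recorded number of substitutions. An accompanying raw count matrix
#' marks designated transcripts as expressed (positive counts in every
#' sample) or not expressed (zero counts), so the CPM filter recovers the
#' planted flags exactly.
#'
#' @param offtarget_spec List with `n_tx` (default 10), `tx_len` (recycled,
#'   default 2000), `guides` (data.frame `id`, `sequence`; default one
#'   random 21-nt guide `"shX"`), `planted` (data.frame `guide`,
#'   `transcript` index, `mismatches`, `orientation`; default empty),
#'   `expressed` (logical per transcript; default all `TRUE`),
#'   `n_samples` (default 4).
#' @param seed Integer seed.
#' @return List with `transcripts` (named character), `guides`, `counts`
#'   (matrix) and `truth` (planted site coordinates and expressed flags).
#' @export
gen_transcriptome <- function(offtarget_spec, seed = 1L) {
  n_tx <- offtarget_spec$n_tx %||% 10L
  tx_len <- rep_len(offtarget_spec$tx_len %||% 2000L, n_tx)
  n_samples <- offtarget_spec$n_samples %||% 4L
  planted <- offtarget_spec$planted
  expressed <- rep_len(offtarget_spec$expressed %||% TRUE, n_tx)
  with_seed(seed, {
    guides <- offtarget_spec$guides %||%
      data.frame(id = "shX",
                 sequence = paste0(sample(c("A", "C", "G", "T"), 21L,
                                          replace = TRUE), collapse = ""))
    if (!is.null(planted) && nrow(planted) > 0L) {
      gl <- nchar(guides$sequence[match(planted$guide, guides$id)])
      if (any(is.na(gl))) stop_invalid("planted site names an unknown guide")
      if (any(tx_len[planted$transcript] < gl))
        stop_invalid("transcript length must be at least the guide length")
    }
    tx <- lapply(tx_len, function(L)
      sample(c("A", "C", "G", "T"), L, replace = TRUE))
    names(tx) <- sprintf("TX%04d", seq_len(n_tx))
    truth_sites <- list()
    if (!is.null(planted)) for (i in seq_len(nrow(planted))) {
      g <- guides$sequence[match(planted$guide[i], guides$id)]
      ori <- planted$orientation[i] %||% "sense"
      mmk <- planted$mismatches[i]
      pat <- if (ori == "antisense") revcomp(g) else g
      pc <- strsplit(pat, "")[[1L]]
      if (mmk > 0L) {
        pos <- sample.int(length(pc), mmk)
        for (p in pos)
          pc[p] <- sample(setdiff(c("A", "C", "G", "T"), pc[p]), 1L)
      }
      ti <- planted$transcript[i]
      L <- tx_len[ti]
      off <- sample.int(L - length(pc) + 1L, 1L) - 1L
      tx[[ti]][(off + 1L):(off + length(pc))] <- pc
      truth_sites[[length(truth_sites) + 1L]] <-
        data.frame(guide = planted$guide[i], transcript = names(tx)[ti],
                   offset = off, orientation = ori, mismatches = mmk)
    }
    transcripts <- vapply(tx, paste0, character(1L), collapse = "")
    counts <- matrix(0L, nrow = n_tx, ncol = n_samples,
                     dimnames = list(names(tx),
                                     sprintf("S%d", seq_len(n_samples))))
    counts[expressed, ] <- stats::rpois(sum(expressed) * n_samples, 100) + 1L
    truth <- truth_record("transcriptome", seed,
                          sites = if (length(truth_sites) > 0L)
                            do.call(rbind, truth_sites)
                          else data.frame(),
                          expressed = stats::setNames(expressed, names(tx)))
    list(transcripts = transcripts, guides = guides, counts = counts,
         truth = truth)
  })
}

#' Generate radial cell positions from planted bin weights
#'
#' Samples each cell's bin from the (normalized) planted weights and a
#' uniform depth within the bin.
#'
#' @param n Number of cells.
#' @param bin_weights Non-negative weights, one per radial bin; must not be
#'   all zero.
#' @param seed Integer seed.
#' @return List with `depths` (numeric in `[0, 1]`) and `truth` (normalized
#'   weights and sampled bin counts).
#' @export
gen_radial_cells <- function(n, bin_weights, seed = 1L) {
  if (any(bin_weights < 0) || sum(bin_weights) == 0)
    stop_invalid("bin weights must be non-negative and not all zero")
  nb <- length(bin_weights)
  w <- bin_weights / sum(bin_weights)
  with_seed(seed, {
    bins <- sample.int(nb, n, replace = TRUE, prob = w)
    depths <- (bins - 1L + stats::runif(n)) / nb
    list(depths = depths,
         truth = truth_record("radial_cells", seed, weights = w,
                              counts = tabulate(bins, nb)))
  })
}

#' Generate bisulfite chromatogram peak heights with planted methylation
#'
#' Each CpG's G and A peak heights are proportional to the planted percent
#' methylation (scale 1000), plus truncated Gaussian noise.
#'
#' @param meth Numeric vector of true percent methylation per CpG, in
#'   `[0, 100]`.
#' @param noise Gaussian noise s.d. on peak heights (default 0).
#' @param seed Integer seed.
#' @return List with `peaks` (data.frame: `position`, `g_height`,
#'   `a_height`) and `truth`.
#' @export
gen_chromatogram <- function(meth, noise = 0, seed = 1L) {
  if (any(meth < 0 | meth > 100))
    stop_invalid("true methylation must lie in [0, 100]")
  with_seed(seed, {
    g <- pmax(0, 1000 * meth / 100 + stats::rnorm(length(meth), 0, noise))
    a <- pmax(0, 1000 * (1 - meth / 100) + stats::rnorm(length(meth), 0, noise))
    list(peaks = data.frame(position = seq_along(meth),
                            g_height = g, a_height = a),
         truth = truth_record("chromatogram", seed, meth_percent = meth,
                              noise = noise))
  })
}

#' Default subcellular fraction proportions
#'
#' Chromatin-dominant profiles for the three youngest L1 subfamilies
#' (90.64, 92.12 and 94.35 percent chromatin), with the residual split
#' equally between nucleoplasm and cytosol.
#'
#' @return Data.frame with columns `target`, `cytosol`, `nucleoplasm`,
#'   `chromatin` (percentages summing to 100 per row).
#' @export
default_fraction_spec <- function() {
  chrom <- c(L1MdA = 90.64, L1MdGf = 92.12, L1MdTf = 94.35)
  data.frame(target = names(chrom),
             cytosol = (100 - chrom) / 2,
             nucleoplasm = (100 - chrom) / 2,
             chromatin = unname(chrom))
}

#' Generate subcellular fractionation qPCR levels with planted proportions
#'
#' Per-compartment RNA levels are the planted proportions times a scale
#' factor, with multiplicative log-normal noise.
#'
#' @param fraction_spec Data.frame as returned by [default_fraction_spec()],
#'   optionally with attribute-free extra rows; or a list with element
#'   `proportions` (that data.frame) and `noise_sd` (log-scale s.d.,
#'   default 0.02).
#' @param seed Integer seed.
#' @return List with `levels` (data.frame of compartment levels) and `truth`
#'   (the planted percentages).
#' @export
gen_fraction_qpcr <- function(fraction_spec = default_fraction_spec(),
                              seed = 1L) {
  if (is.data.frame(fraction_spec))
    fraction_spec <- list(proportions = fraction_spec, noise_sd = 0.02)
  pr <- fraction_spec$proportions
  noise <- fraction_spec$noise_sd %||% 0.02
  comp <- c("cytosol", "nucleoplasm", "chromatin")
  if (!all(c("target", comp) %in% names(pr)))
    stop_invalid("proportions need columns target, %s",
                 paste(comp, collapse = ", "))
  m <- as.matrix(pr[, comp])
  if (any(m < 0) || any(rowSums(m) == 0))
    stop_invalid("proportions must be non-negative and normalizable")
  m <- 100 * m / rowSums(m)
  with_seed(seed, {
    lv <- m / 100 * exp(matrix(stats::rnorm(length(m), 0, noise), nrow(m)))
    levels <- data.frame(target = pr$target, lv)
    list(levels = levels,
         truth = truth_record("fraction_qpcr", seed,
                              percent = data.frame(target = pr$target, m),
                              noise_sd = noise))
  })
}
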