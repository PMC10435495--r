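# End-to-end orchestration: generate the synthetic inputs, run every
# analysis stage on them, and write plain-file outputs plus a JSON run
# report. All randomness flows from the single config seed through the
# fixed child-seed schedule.

pipeline_stages <- function()
  c("synthetic", "setstats", "ranking", "g4", "quant", "offtarget")

default_config <- function() {
  list(
    stages = "all",
    synthetic = list(
      universe_size = 2000L,
      de = list(conditions = c("shL1_a", "shL1_b"),
                n_up = c(400, 480), n_down = c(390, 300),
                shared_up = 270, shared_down = 200, opposite = 0),
      sequences = list(subfamilies = data.frame(
                         subfamily = c("L1MdA", "L1MdGf", "L1MdTf"),
                         n = c(4L, 4L, 4L), length = 6000L),
                       n_g4 = 3L, n_motif = 3L, motif_colocal = 0.8),
      ct = list(targets = c("L1MdA", "L1MdGf", "L1MdTf"),
                kd = c(0.60, 0.56, 0.54), replicates = 3L, noise_sd = 0.1),
      transcriptome = list(n_tx = 12L, tx_len = 2000L,
                           planted = data.frame(guide = "shX",
                                                transcript = c(1L, 2L),
                                                mismatches = c(0L, 1L),
                                                orientation = "sense"),
                           expressed = rep(c(TRUE, FALSE), 6L)),
      radial = list(n = 2000L, bin_weights = rep(1, 10L)),
      chromatogram = list(meth = c(80, 60, 40, 20), noise = 10),
      fractions = list()
    ),
    setstats = list(B = 1000L),
    g4 = list(window = 50L, min_score = 45),
    offtarget = list(max_mm = 1L),
    quant = list(n_bins = 10L)
  )
}

# Merge user config over defaults, recursively for named lists.
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.data.frame(user[[nm]]) && !is.data.frame(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes the selected stages in dependency order (synthetic data first,
#' then the analysis stages on its outputs), writing each stage's outputs as
#' plain files under `out_dir` and a JSON run report at
#' `out_dir/run_report.json`. Identical configuration and seed produce
#' identical outputs. Unknown stage names or invalid parameters fail before
#' any stage executes.
#'
#' @param config Either a path to a YAML configuration file or a named list;
#'   omitted entries fall back to the bundled demo defaults (see
#'   `inst/extdata/demo_config.yaml`).
#' @param out_dir Output directory, created if needed.
#' @param seed Integer root seed.
#' @return The run report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("l1run"),
                         seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (nm in c("de", "sequences", "ct", "transcriptome"))
    if (!is.null(config$synthetic[[nm]]) &&
        is.list(config$synthetic[[nm]]$subfamilies))
      config$synthetic[[nm]]$subfamilies <-
        as.data.frame(config$synthetic[[nm]]$subfamilies)
  if (!is.null(config$synthetic$transcriptome$planted) &&
      is.list(config$synthetic$transcriptome$planted) &&
      !is.data.frame(config$synthetic$transcriptome$planted))
    config$synthetic$transcriptome$planted <-
      as.data.frame(config$synthetic$transcriptome$planted)
  cfg <- merge_config(default_config(), config)
  stages <- cfg$stages
  if (identical(stages, "all")) stages <- pipeline_stages()
  unknown <- setdiff(stages, pipeline_stages())
  if (length(unknown) > 0L)
    stop_invalid("unknown stage '%s'", unknown[[1L]])
  # synthetic inputs are always regenerated in-memory (cheap, seeded); the
  # synthetic stage's files and report entry appear only when selected
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = seed, out_dir = out_dir, stages = list())
  t_all <- proc.time()[["elapsed"]]
  note <- function(stage, params, outputs, stats, t0) {
    report$stages[[stage]] <<- list(
      stage = stage, params = params, outputs = outputs, stats = stats,
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    message(sprintf("[%s] done (%.2fs)", stage,
                    report$stages[[stage]]$elapsed_s))
  }

  # --- synthetic ---------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  syn <- cfg$synthetic
  universe <- gen_universe(syn$universe_size, child_seed(seed, "universe"))
  de <- gen_de_tables(universe, syn$de, child_seed(seed, "de"))
  sq <- gen_l1_sequences(syn$sequences, child_seed(seed, "sequences"))
  ct <- gen_ct_table(syn$ct, child_seed(seed, "ct"))
  txo <- gen_transcriptome(syn$transcriptome, child_seed(seed, "transcriptome"))
  rad <- gen_radial_cells(syn$radial$n, syn$radial$bin_weights,
                          child_seed(seed, "radial"))
  chrm <- gen_chromatogram(syn$chromatogram$meth, syn$chromatogram$noise,
                           child_seed(seed, "chromatogram"))
  fr <- do.call(gen_fraction_qpcr,
                c(if (length(syn$fractions) > 0L) list(syn$fractions),
                  list(seed = child_seed(seed, "fractions"))))
  if ("synthetic" %in% stages) {
    write_gene_set(universe, file.path(out_dir, "universe.txt"))
    for (cond in names(de$tables))
      write_tsv(de$tables[[cond]], file.path(out_dir,
                                             paste0("de_", cond, ".tsv")))
    write_fasta(sq$sequences, file.path(out_dir, "l1_sequences.fa"))
    write_intervals(sq$g4, file.path(out_dir, "truth_g4.bed"))
    write_intervals(sq$motifs, file.path(out_dir, "truth_motifs.bed"))
    write_tsv(ct$ct, file.path(out_dir, "ct_table.tsv"))
    write_fasta(txo$transcripts, file.path(out_dir, "transcriptome.fa"))
    write_tsv(txo$guides, file.path(out_dir, "guides.tsv"))
    write_tsv(data.frame(gene = rownames(txo$counts), txo$counts),
              file.path(out_dir, "counts.tsv"))
    write_tsv(data.frame(depth = rad$depths),
              file.path(out_dir, "radial_positions.tsv"))
    write_tsv(chrm$peaks, file.path(out_dir, "chromatogram.tsv"))
    write_tsv(fr$levels, file.path(out_dir, "fraction_levels.tsv"))
    truths <- list(de = de$truth, sequences = sq$truth, ct = ct$truth,
                   transcriptome = txo$truth, radial = rad$truth,
                   chromatogram = chrm$truth, fractions = fr$truth)
    write_truth(truths, file.path(out_dir, "truth.json"))
    note("synthetic", syn["universe_size"],
         list.files(out_dir), list(n_genes = length(universe)), t0)
  }

  # --- setstats ----------------------------------------------------------
  if ("setstats" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    conds <- names(de$tables)
    up_sets <- lapply(de$tables, de_significant, direction = "up")
    ov <- fisher_overlap(up_sets[[1L]], up_sets[[2L]], universe)
    enr <- enrich_gene_sets(up_sets[[1L]],
                            list(up_core = de$truth$shared_up,
                                 down_core = de$truth$shared_down),
                            universe, B = cfg$setstats$B, seed = seed)
    cons_up <- consistent_degs(de$tables, "up")
    conc <- directional_concordance(de$tables[[1L]], de$tables[[2L]])
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    write_gene_set(cons_up, file.path(out_dir, "consistent_up.txt"))
    note("setstats", cfg$setstats, c("enrichment.tsv", "consistent_up.txt"),
         list(jaccard_up = ov$jaccard, fisher_p_up = ov$fisher_p,
              n_consistent_up = length(cons_up),
              concordance_counts = as.list(conc$counts)), t0)
  }

  # --- ranking -----------------------------------------------------------
  if ("ranking" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    motif_counts <- table(factor(sq$motifs$seqid,
                                 levels = names(sq$sequences)))
    recs <- with_seed(seed, {
      prot <- c("Suz12", "Ezh2", "CtrlProt")
      do.call(rbind, lapply(prot, function(p)
        data.frame(protein = p, rna = names(sq$sequences),
                   subfamily = unname(sq$truth$subfamily),
                   propensity_z = stats::rnorm(length(sq$sequences),
                                               mean = switch(p, Suz12 = 6,
                                                             Ezh2 = 1, 0)),
                   rbp_propensity = if (p == "CtrlProt") 0.3 else 1,
                   motif_count = if (p == "CtrlProt") 0L
                                 else as.integer(motif_counts))))
    })
    ranked <- rank_interactions(recs)
    burden <- motif_burden(as.integer(motif_counts),
                           unname(sq$truth$subfamily))
    write_tsv(ranked, file.path(out_dir, "ranked_interactions.tsv"))
    write_tsv(burden[, setdiff(names(burden), "counts")],
              file.path(out_dir, "motif_burden.tsv"))
    note("ranking", list(rescale = "fixed"),
         c("ranked_interactions.tsv", "motif_burden.tsv"),
         list(top_protein = ranked$protein[1L]), t0)
  }

  # --- g4 ----------------------------------------------------------------
  if ("g4" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    lens <- stats::setNames(nchar(sq$sequences), names(sq$sequences))
    g4 <- find_g4(sq$sequences)
    prof <- bin_profile(g4, lens, window = cfg$g4$window)
    ot <- overlap_test(g4, sq$motifs, lens, window = cfg$g4$window)
    ctrl <- strand_control(sq$sequences, sq$motifs, lens,
                           window = cfg$g4$window)
    write_intervals(g4, file.path(out_dir, "g4_found.bed"))
    write_tsv(prof$profile, file.path(out_dir, "g4_profile.tsv"))
    jsonlite::write_json(list(test = unclass(ot), control = unclass(ctrl)),
                         file.path(out_dir, "g4_overlap.json"),
                         auto_unbox = TRUE, digits = NA)
    note("g4", cfg$g4, c("g4_found.bed", "g4_profile.tsv", "g4_overlap.json"),
         list(n_g4 = nrow(g4), p_test = ot$p, p_control = ctrl$p), t0)
  }

  # --- quant -------------------------------------------------------------
  if ("quant" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    kd <- vapply(unique(ct$ct$target), function(tg)
      ddct(ct$ct[ct$ct$target == tg, ])$kd_percent, numeric(1L))
    radial <- radial_distribution(rad$depths, cfg$quant$n_bins)
    meth <- methylation_percent(chrm$peaks$g_height, chrm$peaks$a_height)
    frac <- fraction_percent(fr$levels)
    write_tsv(data.frame(target = names(kd), kd_percent = kd),
              file.path(out_dir, "knockdown.tsv"))
    write_tsv(data.frame(bin = seq_len(radial$n_bins),
                         percent = radial$percent),
              file.path(out_dir, "radial_distribution.tsv"))
    write_tsv(data.frame(position = chrm$peaks$position,
                         percent_meth = meth),
              file.path(out_dir, "methylation.tsv"))
    write_tsv(frac, file.path(out_dir, "fractions.tsv"))
    note("quant", cfg$quant,
         c("knockdown.tsv", "radial_distribution.tsv", "methylation.tsv",
           "fractions.tsv"),
         list(kd_percent = as.list(kd),
              chromatin_percent = as.list(stats::setNames(frac$chromatin,
                                                          frac$target))), t0)
  }

  # --- offtarget ---------------------------------------------------------
  if ("offtarget" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    hits <- scan_offtargets(txo$guides, txo$transcripts,
                            max_mm = cfg$offtarget$max_mm)
    hits <- classify_expressed(hits, txo$counts)
    write_tsv(hits, file.path(out_dir, "offtarget_hits.tsv"))
    note("offtarget", cfg$offtarget, "offtarget_hits.tsv",
         list(n_hits = nrow(hits)), t0)
  }

  report$elapsed_s <- round(proc.time()[["elapsed"]] - t_all, 3)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
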