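---
title: "Statistical methods for LINE-1 regulatory RNA analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for LINE-1 regulatory RNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1regkit)
```

## Scope and motivation

LINE-1 (L1) retrotransposon transcripts can act as chromatin-associated
regulatory RNAs during cortical development: knocking them down with shRNAs
perturbs thousands of genes, their transcripts co-purify with chromatin, and
their sequences carry predicted binding sites for Polycomb (PRC2) subunits
that co-occur positionally with RNA G-quadruplex (rG4) motifs. Studies of
this kind rest on a set of small, bespoke computations that are rarely
packaged or tested: a resampling gene-set enrichment test against an
expressed-gene background, concordance filters across knockdown
comparisons, a protein--RNA interaction ranking score, positional
co-occurrence statistics along transposon sequences, an shRNA off-target
scan, and the bench quantification formulas (ΔΔCt, radial bin counts,
bisulfite peak heights, subcellular fractions).

`l1regkit` implements each of these as a documented, unit-tested function,
together with a synthetic-data module that generates every input with
machine-readable planted truth. The package deliberately does **not**
re-implement the heavy upstream machinery — read alignment, limma/DESeq2
model fitting, catRAPID interaction prediction, pqsfinder G4 scoring, peak
calling — whose outputs it consumes as plain tables.

## The resampling overlap-enrichment test

Given a query gene set $Q$ (e.g. upregulated genes after knockdown), a
target set $T$ (a gene set of interest) and the expressed-gene universe
$U$, the observed overlap $k_{\mathrm{obs}} = |Q \cap T|$ is compared to a
null built by drawing, $B$ times, a uniform random subset of $U$ of size
$|Q|$ without replacement and recording its overlap with $T$. With null
mean $\mu$ and standard deviation $\sigma$,

$$ z = \frac{k_{\mathrm{obs}} - \mu}{\sigma}, \qquad
   p = P(Z \ge z), \ Z \sim \mathcal N(0,1), $$

and p-values across the gene sets tested in one call are adjusted by the
Benjamini--Hochberg step-up procedure (`p.adjust`), with 0.05 as the
significance convention. Design notes:

* **Upper tail by default.** The scientific question is enrichment of
  dysregulated genes in a set; depletion is available via
  `alternative = "less"` but is not the default. Whether the original
  analyses used one- or two-sided conversion is not stated anywhere we
  could anchor to, so the one-sided enrichment reading is exposed and
  documented.
* **Degenerate nulls.** When $\sigma = 0$ (e.g. the query is the whole
  universe) the z-score is undefined; the implementation falls back to the
  exact hypergeometric upper tail and flags the result, instead of
  emitting an infinite z.
* **Accuracy of the normal approximation.** As $B \to \infty$ the
  resampled $(\mu, \sigma)$ converge to the hypergeometric moments (a
  property test asserts this). The plain $z \to p$ mapping carries no
  continuity correction, so on very small universes (tens of genes) it can
  deviate from the exact hypergeometric tail by up to roughly the
  half-count shift (&approx;0.18 at the null mean on a 20-gene universe).
  This is inherent to the method, not a defect of the implementation; at
  the universe sizes the method is meant for (thousands of expressed
  genes) the approximation is excellent, and the test-suite calibration
  check (20,000-gene universe, 2,000 replicates) finds the size of the
  α = 0.05 test within [0.03, 0.07].
* **Identifier hygiene.** Identifiers are compared case-sensitively after
  whitespace stripping; duplicates are collapsed with a warning.

Concordance between two comparisons is summarized by the Jaccard index
$|A \cap B| / |A \cup B|$ (defined as 0 for two empty sets) and a
one-sided Fisher's exact test on the 2×2 membership table over the
universe (`fisher.test`). The stringent multi-comparison filter
`consistent_degs()` intersects the significant, direction-concordant genes
of every table; `directional_concordance()` partitions genes significant
in two systems by sign pattern, which is how an opposite in vivo / in
vitro response is counted.

## The interaction ranking score

Candidate protein--RNA pairs are scored by three components, each in
$[0,1]$:

1. **Normalized propensity**: the interaction-propensity z-score clamped
   to $[-4, 4]$ and mapped linearly, so $z \le -4 \mapsto 0$,
   $0 \mapsto 0.5$, $z \ge 4 \mapsto 1$.
2. **RBP propensity**: taken as given (1 for proteins in the curated
   RNA-binding-protein library, otherwise an external signature score);
   this package never computes it.
3. **Motif component**: 0 with no protein-specific RNA motif on the
   transcript, 0.5 with exactly one occurrence, 1 with multiple.
   Occurrences (not distinct motif types) are counted, the more natural
   reading of "multiple motif occurrences".

The final score sums the components and rescales to $[0,1]$. Dividing by 3
is used because it is deterministic, dataset-independent and strictly
monotone in each component; a min--max rescale over the candidate table is
available behind `rescale = "minmax"`. The two choices always induce the
same ranking order, which is what downstream conclusions use. Ties are
broken lexicographically on (protein, RNA) so ranks are reproducible
across platforms. Boxplot summaries (`box_stats`, `motif_burden`) use
type-7 quantiles and whiskers at quartile ± 1.5·IQR clipped to the data
range, matching the figure convention of the field.

## Positional co-occurrence of G4 motifs and binding sites

`find_g4()` scans for the canonical quadruplex pattern
$G_{\ge 3}(N_{1..7}G_{\ge 3})_3$, reporting non-overlapping left-greedy
matches scored by the number of tract guanines. This is intentionally a
canonical-pattern finder, labelled as such in its output metadata: it does
not reproduce the scoring model of dedicated G4 predictors (bulges,
imperfections, mismatch penalties). Externally predicted, scored G4
intervals are the fidelity path and are ingested as BED via
`load_intervals()`, which applies the conventional score threshold of 45
inclusively.

Positions are discretized into half-open 50-bp bins; each feature is
assigned to the bin containing its **start** — the binned quantity is a
position, not a footprint, which sidesteps the ambiguity of features
spanning bins. A feature's relative position is its bin start divided by
the sequence length, allowing sequences of unequal length to be pooled
into one cumulative-density profile.

Co-occurrence of two feature sets is tested on the bin universe: with $N$
total bins, $K$ bins holding a feature of the first set, $n$ of the
second and $k$ of both, the p-value is the hypergeometric upper tail
$P(X \ge k)$ — the same statistic genome-wide peak-merging tools use, here
with bins rather than base pairs as the universe because the published
invocation details are unavailable; the bin width is an exposed parameter.
The negative control re-runs the test with G4 motifs predicted on the
minus strand: a plus-strand RNA cannot fold quadruplexes encoded on the
opposite strand, so signal surviving the control would indicate a
compositional artifact.

## shRNA off-target scanning

`scan_offtargets()` reports every end-to-end, ungapped alignment of each
guide (and its reverse complement) against every transcript with Hamming
distance at most `max_mm` ∈ {0, 1, 2} — the same match definition as an
end-to-end short-read aligner run with `-v 0/1/2`, re-implemented here as
a transparent vectorized scan so the whole pipeline stays dependency-light
and oracle-checkable. `N` bases in transcripts count as mismatches against
every guide base. Expression classification follows the a-priori filter
used for differential-expression inclusion: a gene is expressed when its
CPM is at least 2 in at least ⌈3/4 · n_samples⌉ samples; hits on
transcripts absent from the count matrix are flagged unknown rather than
guessed.

## Bench quantification formulas

* **ΔΔCt**: per condition, ΔCt is the mean target Ct minus the mean
  reference Ct; ΔΔCt is treated minus control; relative expression is
  $2^{-\Delta\Delta Ct}$ (100% primer efficiency assumed, base exposed as
  a parameter) and knockdown% is $100(1 - 2^{-\Delta\Delta Ct})$.
  Replicates are aggregated by arithmetic mean of Ct (geometric mean on
  the expression scale, the conventional reading); the standard error of
  ΔΔCt propagates the four replicate variances and maps to the expression
  scale by the delta method. The statistic is invariant to a constant
  shift of all Ct values.
* **Radial distribution**: depths in $[0,1]$ measured from the pia are cut
  into `n_bins` equal half-open bins (depth 1 closes into the last bin);
  bin 1 is anchored at the pia, per the stated counting procedure. Figure
  numbering conventions elsewhere may differ; this package documents its
  own and takes no side.
* **Bisulfite peak heights**: on reverse-strand direct sequencing a
  methylated cytosine reads G and a converted one reads A, so percent
  methylation is $100\,g/(g+a)$, undefined (an error) when both peaks are
  zero.
* **Subcellular fractions**: compartment levels are normalized to
  percentages of their total per target RNA.

## The synthetic-data module

Every generator is seeded and returns a truth record of exactly what was
planted, so each pipeline stage has an exact recovery test. A single root
seed expands into per-artifact child seeds by a fixed multiplicative
schedule (`child_seed()`), so adding a generator never perturbs earlier
artifacts. What the generators emulate, and their default conditions:

* **DE tables** (`gen_de_tables`): per-condition up/down sets of exactly
  the requested sizes with exactly the requested shared cores, built by
  sampling the cores first and disjoint remainders after — counts are
  exact, not in expectation. An optional opposite-direction block plants
  genes up in one condition and down in another. Significant members get
  FDR < 0.05 and sign-matched log2 fold changes (|log2FC| ∈ [0.5, 4]);
  non-members get FDR > 0.05.
* **L1-like sequences** (`gen_l1_sequences`): background drawn over
  A/C/T with G at a reduced frequency (default 0.10) and post-processed so
  no G-run of length ≥ 3 survives outside planted tracts; the accidental
  canonical-G4 rate in the background is therefore exactly zero and every
  planted cassette (four G₄ tracts with 3-base loops) is recovered exactly.
  G4s default to the 3′ half, where real L1 rG4 density concentrates.
  Binding motifs are planted as coordinate intervals only — downstream
  stages consume site coordinates, not site sequence — with a configurable
  fraction co-localized into G4-start bins.
* **Ct tables** (`gen_ct_table`): the treated target Ct is shifted by
  $-\log_2(1-\mathrm{kd})$; Gaussian replicate noise (default sd 0.1,
  3 replicates) enters on the target Ct, i.e. at the level of each
  replicate's ΔCt, with the reference assay as the anchor. Under this model
  the estimated knockdown lands within ±5 points of truth in ≥95% of
  replicates at the default noise, which the suite verifies over 500 seeded
  replicates. The default planted knockdowns are 60/56/54% for the three
  youngest subfamilies.
* **Transcriptomes** (`gen_transcriptome`): uniform-random transcripts
  with guide sites substituted in at recorded offsets, orientations and
  mismatch counts; expressed transcripts get positive Poisson counts in
  every sample and non-expressed ones all zeros, so the CPM filter
  recovers the planted flags exactly.
* **Radial positions, chromatograms, fractions**: multinomial bins with
  uniform within-bin depth; peak heights proportional to planted percent
  methylation with truncated Gaussian noise; fraction levels with
  log-normal noise around planted proportions. The default fraction
  profile is chromatin-dominant (90.64, 92.12, 94.35% chromatin for the
  three subfamilies) with the residual split equally between nucleoplasm
  and cytosol, a choice made once because the residual split is not
  itself a quantity of interest.

What the generators do **not** emulate: raw reads and alignment artifacts,
real L1 consensus sequences base-by-base, overdispersed count noise,
correlated replicate structure, or single-cell data. Passing recovery
tests therefore demonstrates the correctness of the computations under
clean planted signal — not robustness to every artifact of real data.

One known bookkeeping discrepancy in published L1 panels (subfamily
counts summing to 515 against a stated total of 508 sequences) is outside
what a generator can resolve; subfamily counts are plain parameters here
and the package takes no side.

## Validation scale and reproduction

The test suite validates, among ~1,700 assertions: calibration of the
resampling test under the null (20,000-gene universe, |query| = 100,
|target| = 500, B = 1,000, 2,000 replicates; rejection rate within
[0.03, 0.07] at α = 0.05) and its power against overlap planted at three
times the hypergeometric expectation (≥0.95); equality of the exact tests
with exhaustive-enumeration oracles (universes ≤ 12 genes, ≤ 15 bins);
equality of the off-target scanner with a naive position-by-position
oracle on 100 random transcriptomes; and exact recovery of every planted
truth. These problem sizes were chosen to exercise each asymptotic regime
while keeping the default suite under a couple of minutes on one CPU.

`scripts/acceptance.R` (repository root) recomputes the package's
reference quantities from scratch against the installed package and writes
them as JSON; see the README for invocation.

## Known limitations

* The built-in G4 finder is canonical-pattern only; scored predictions
  from a dedicated predictor should be imported for fidelity work.
* The bin-based overlap universe is one defensible discretization of the
  peak co-occurrence question; base-pair universes give different absolute
  p-values (the ordering of associations is typically stable).
* Quantities that require the real mouse (mm10) resources — genome-wide DE
  counts, rankings over the full 1,946-protein RBP library, published
  overlap p-values on real L1 sequences — cannot be reproduced at desk
  scale and are explicitly out of scope; the package covers their
  computational skeletons.
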