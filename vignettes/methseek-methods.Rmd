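---
title: "Coverage-threshold methylation peak calling for MBD-Seq: models and design"
author: "methseek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-threshold methylation peak calling for MBD-Seq: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methseek)
```

## The measurement and the model

MBD-Seq enriches sheared genomic DNA for methylated fragments with a
methyl-CpG-binding domain protein and sequences the captured fraction.
After alignment and duplicate removal, local read depth is a proxy for DNA
methylation density: a methylated promoter accumulates a pile of fragment
spans, unmethylated background stays near zero. `methseek` turns that signal
into discrete *methylation sites* and a site-by-sample count matrix:

1. **Scan windows.** For each transcript, the promoter window runs from
   `up` bases upstream of the transcriptional start site through `down`
   bases downstream (defaults 5000 and 2000; the downstream segment includes
   the TSS base, so an unclipped window is exactly `up + down` = 7000 bp
   wide). Intragenic windows are full transcript spans. Windows are
   strand-aware, clipped at contig ends rather than dropped, and may overlap
   freely — duplicate calls are resolved later by consolidation.
2. **Peak calling.** Depth at a base is the number of whole fragment spans
   covering it. A peak is a *maximal run* of consecutive bases with depth at
   or above `depth_threshold` (default 10). By construction the first base
   of a peak has depth ≥ threshold and the base just past its end has depth
   < threshold, unless the run hits the window edge, where the peak is
   clipped: scanning is confined to the declared windows. Peak ends are
   defined left-to-right in genome coordinates regardless of transcript
   strand, which keeps two-condition comparisons symmetric.
3. **Consolidation.** Per-sample peak lists from all samples and both
   conditions are unioned into a master list (identical intervals collapse,
   provenance merges). The master list is condensed by merging sites whose
   start coordinates differ by at most `merge_dist` (default 100 bp) *and*
   whose end coordinates do too; this is deliberately not an interval-gap
   rule, so a short peak never merges into a distant long one that shares a
   single boundary. Merging applies over the transitive closure of that
   relation, repeated to a fixed point, which makes the result independent
   of input order and idempotent. A merged site spans from the most
   upstream member start to the most downstream member end.
4. **Counting.** A fragment counts toward a site when it overlaps it by at
   least one base; a fragment straddling two sites increments both. The
   result is a `RangedSummarizedExperiment` of integer counts with condition
   labels, exportable as TSV.
5. **Screening.** Counts are normalized by median-of-ratios size factors
   (each sample's factor is the median ratio of its counts to the per-site
   geometric mean across samples, over sites positive everywhere). The
   per-site statistic is `log2fc = log2((meanA + pc) / (meanB + pc))` with
   pseudocount `pc = 1`; sites pass at `|log2fc| > 1` strictly, and when the
   permutation test is on, additionally at BH-adjusted permutation
   `p < 0.05` strictly.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `up`, `down` | 5000, 2000 | bases | the promoter definition used throughout: regulatory methylation concentrates around the TSS |
| `depth_threshold` | 10 | fragments/base | separates enriched pile-ups from sparse background at typical MBD-Seq depths |
| `min_width` | 1 | bases | no minimum by default; raise to suppress single-base blips at noisy thresholds |
| `merge_dist` | 100 | bases | peaks of the same site jitter by roughly a fragment radius across samples; 100 bp condenses them without fusing neighbours |
| `lfc_cutoff` | 1.0 | log2 units | a two-fold change, the conventional enrichment criterion |
| `padj_cutoff` | 0.05 | — | conventional FDR level (Benjamini–Hochberg step-up) |
| `pseudocount` | 1.0 | normalized counts | stabilizes the log ratio at low counts; a deliberate simplification relative to shrinkage estimators |
| `n_permutations` | 10000 | — | cap on label splits; designs with fewer distinct splits are enumerated exactly |

## The permutation screen and its granularity

The built-in screen is intentionally lightweight: the canonical route for a
full differential analysis is exporting `counts.tsv` to a dedicated
count-model tool, and `apply_de_filter()` then applies the strict
double-threshold selection (`padj < 0.05` and `|log2fc| > 1`) to any table
such a tool produces. The internal alternative is a label-permutation test
on `|log2fc|`: with `nA` and `nB` samples there are `choose(nA + nB, nA)`
distinct label splits; all are enumerated when that number is at most
`n_permutations`, and the +1-smoothed p-value is
`(1 + #{null ≥ observed}) / (1 + #splits)`. Two consequences matter for
interpretation. First, the p-values are discrete: a 4-vs-4 design has 70
splits, so the smallest possible p is 2/71 ≈ 0.028 and the exact rejection
rate of a true null at the 0.05 level is 2/70 ≈ 0.029 — the test is valid
but conservative (super-uniform). Calibration checks in the test suite are
therefore written against this exact attainable level plus a one-sided
binomial bound at 0.05, not against a two-sided interval centred on 0.05,
which any discrete permutation test would eventually fail as the number of
sites grows. Second, fewer than two samples per condition leaves no usable
null and is an error.

## Normalization: what is and is not invariant

Median-of-ratios size factors are only defined up to one common constant:
rescaling one sample's counts by `c` moves that sample's factor *relative
to every other sample's* by exactly `c`, while the per-site geometric-mean
reference absorbs a common drift of `c^(1/m)` across all `m` samples. Ratios
of normalized group means — the fold change proper — are therefore exactly
invariant to any single sample's sequencing depth, and the test suite
asserts this at 1e-9. The pseudocounted `log2fc` inherits only the common
drift, which is indistinguishable from sequencing every sample uniformly
deeper and is left alone by design.

## What the simulator emulates

`sim_config()` encodes the experimental conditions the package is validated under:

- **Replicate structure.** Two conditions, M1 and M2, with 4 biological
  replicates each by default.
- **Fragments.** Sonication fragments with hard bounds 200–500 bp and modal
  length 350 bp, drawn from a triangular distribution — the simplest
  distribution with hard bounds and a controllable mode. Fragments are
  simulated directly as aligned spans; no read pairs, base qualities or
  sequencing errors, because peak calling only ever sees aligned spans.
- **Signal.** Each planted methylated region (default width 1000 bp,
  centered in its promoter window) receives a Poisson number of fragments
  with mean `enriched_depth × width / mean_fragment_length` per sample
  (default depth 20, twice the calling threshold), with uniform midpoints —
  an analytically checkable depth parameterization.
- **Background.** Unmethylated genome emits Poisson background at
  `background_rate` fragments per kb (default 2, i.e. expected depth
  ≈ 0.7×, far below threshold).
- **Differential signal.** A chosen fraction of planted regions gets its
  depth multiplied by `differential_effect` in condition M1 only. The
  default is no effect (`differential_effect = 1`, `diff_fraction = 0`):
  two conditions sharing one methylation landscape, the null regime that a
  two-condition comparison should call as "no differential sites".

Everything derives from `seed`, and reruns are byte-identical.

What the simulator does **not** model: CpG-density-dependent MBD binding
affinity, mappability and GC biases, copy-number variation, donor-to-donor
methylation heterogeneity (which in real data can dominate
condition-to-condition differences), or genome-scale annotation complexity.
Passing the planted-signal tests shows the algorithmic chain is correct
under its stated model, not that threshold 10 is optimal for any particular
library depth or that real promoters behave like uniform planted blocks.

## Numerical and degenerate-input choices

- All internal intervals are `GRanges` (1-based, closed); BED's 0-based
  half-open convention is converted exactly once, inside the readers and
  writers, and site identifiers (`contig:start-end`) use the BED
  convention.
- Depth is computed by coverage accumulation but is contractually equal to
  per-base membership counting; the tests enforce equality against a
  brute-force oracle.
- Empty inputs flow through: an empty alignment set yields an all-zero
  depth profile, no peaks, an empty master list and an empty count matrix;
  a promoter window that is empty after clipping drops its transcript with
  a warning rather than an error.
- Thresholds are strict where the selection rules say strict: `|log2fc| >
  1` excludes exactly 1, `padj < 0.05` excludes exactly 0.05.
- Size factors are undefined when no site is positive in every sample; this
  is a hard error with advice, not a silent fallback.
- `merge_dist = 0` collapses only exactly identical intervals; ties in
  sorting are broken by (contig order, start, end).

## Validation problem sizes

The test suite validates the peak caller against a maximal-run oracle on
1000 random depth vectors at three thresholds, the merge rule against a
transitive-closure oracle on 500 random site sets, counting against a
pairwise-overlap oracle on 100 fixtures, and the end-to-end pipeline on
simulated datasets of 20 planted promoters (recovery, 3 seeds), ~300
consolidated null sites (screen calibration) and 200 planted promoters with
10 four-fold differential regions (effect ranking, 3 seeds). These sizes
give stable statistics for every property while keeping the full suite fast
to run routinely.

## Known limitations

- The depth threshold is applied to raw coverage; no input-fraction
  (unenriched control) correction or depth normalization happens before
  peak calling, so samples with very different library sizes should be
  compared with care at the peak-calling stage (counting and screening do
  normalize).
- "Intragenic" means the full transcript span; promoter and intragenic
  windows of the same transcript overlap over the TSS-downstream segment.
- The screen's pseudocount and permutation test are simplifications of a
  negative-binomial shrinkage model; with few replicates the permutation
  p-values are coarse (see above) and the fold-change criterion alone
  drives most decisions.
- One promoter window per transcript: multiple isoforms sharing a TSS
  produce duplicate windows, which consolidation collapses but which still
  cost compute.
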