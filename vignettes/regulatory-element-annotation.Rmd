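---
title: "Building and analysing regulatory-element catalogs with recatalog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analysing regulatory-element catalogs with recatalog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recatalog)
```

## Overview

`recatalog` post-processes multi-tissue chromatin-state segmentations into
a catalog of regulatory elements (REs) and carries that catalog through
the downstream analyses a comparative epigenomics study needs: class
labels relative to gene annotation, TAD prediction from CTCF motif
orientation, enhancer-to-gene linking by correlation within TADs,
cross-species conservation calls, ChIP-seq library QC, and GWAS-SNP
enrichment. Every coordinate inside the package is 0-based half-open (the
BED convention); GFF3 input is converted at the boundary, which keeps a
single convention throughout and eliminates a whole class of off-by-one
errors.

A seeded simulator (`simulate_study()`) produces every input the pipeline
consumes together with the planted ground truth, so each stage can be
validated end-to-end against known answers. This vignette documents the
models, the tunable parameters and the design decisions.

## From chromatin states to a regulatory-element catalog

The input is one dense segmentation per tissue: non-overlapping intervals
labelled with a chromatin state 1-14 from a hidden-Markov segmentation of
histone-mark ChIP-seq tracks. States 1-6, 8, 9 and 11 carry active
promoter/enhancer signatures and form the default `ACTIVE_STATES`; state
14 is the low-signal background and 12-13 are repressed.

`consolidate_active()` merges consecutive or abutting active-state runs
within each tissue (bookended merging, matching BEDTools `merge`
semantics), and `combine_tissues()` union-merges the per-tissue runs into
catalog elements, recording for each element the set of tissues that
contribute at least 1 bp. Elements active in exactly one tissue are
flagged tissue-specific. Merging across tissues avoids artefacts such as
a broad acetylation domain fragmenting a promoter into spurious
enhancer-state slivers.

`classify_re()` assigns one class per element with a fixed precedence:

1. **tss_proximal** - within 2,000 bp (inclusive, measured from the
   nearest element edge to the TSS base) of any protein-coding TSS;
2. **excluded** - otherwise within 2,000 bp of a non-coding or
   unannotated TSS (these are neither clean promoters nor clean
   enhancers, so they are set aside);
3. **genic** - otherwise overlapping a protein-coding gene body by at
   least 1 bp;
4. **intergenic** - the remainder.

Coding-TSS proximity deliberately outranks the exclusion rule: the
exclusion exists to avoid mislabelling promoters as enhancers, which
cannot happen for an element already sitting at a coding TSS.
TSS-proximal elements behave like promoters; genic and intergenic
elements carry enhancer-like signatures.

## TAD prediction from CTCF motif orientation

Without chromatin-conformation data, TADs can be approximated from CTCF
binding: loop anchors carry convergently oriented CTCF motifs.
`predict_tads()` chains four steps:

* `scan_pwm()` scores peak sequences on both strands with a pseudocounted
  log-odds matrix (`log2((p + 1e-3, renormalised)/0.25)`, in bits). The
  hit threshold for a given p-value is computed by exact dynamic
  programming over scores discretized at 1e-3 bits under the uniform
  background - deterministic, no sampling. Default p-value 1e-4.
* `orient_peaks()` keeps one site per peak - its best-scoring hit (ties:
  smaller start, then `+` strand). One site per peak prevents a single
  broad peak from spawning multiple boundaries.
* `pair_loops()` pairs each forward-oriented site with its nearest
  downstream reverse-oriented site within `max_span` (default 1 Mb).
  The nearest-partner convergent rule is the standard reading of CTCF
  loop-extrusion orientation logic; the cap and the one-partner rule are
  both configurable because the literature varies on them.
* `merge_loops()` takes the transitive union of overlapping or nested
  loops; abutting loops stay separate.

`tad_coverage()` reports the covered genome fraction, the usual headline
statistic for TAD callers.

## Linking enhancers to target genes

Counts are normalized with TMM (`tmm_factors()`, reimplementing the
trimmed-mean-of-M-values estimator: reference sample by upper-quartile
proximity to the mean, 30%/5% two-sided trims on M and A, inverse
asymptotic-variance weights, factors rescaled to geometric mean 1) and
converted to CPM with effective library sizes. `variance_filter()`
removes rows whose max/min ratio across samples is at most 6 - low
variance rows (housekeeping-like genes, constitutive elements) cannot
support rank correlation and only inflate the test count. The threshold
follows the convention of removing roughly the housekeeping fraction of
the transcriptome; rows touching zero with a positive maximum are kept
(infinite ratio).

`predict_links()` tests every (RE, gene) pair that shares a TAD - an RE
by its midpoint, a gene by its 5'-most TSS - using Spearman rank
correlation across all samples, with the two-sided t-approximation
p-value on n-2 degrees of freedom. One Benjamini-Hochberg adjustment is
applied genome-wide (a single family, since the analysis makes one joint
claim about the catalog), and pairs with q < 0.05 and positive rho are
retained. Positive-only is the default because the predictive signal is
an activating mark; anti-correlated pairs are not interpretable as
activation and can be re-enabled with `positive_only = FALSE`.
`naive_pairs()` supplies the overlap/nearest-gene baseline used to report
what fraction of linked genic/intergenic elements simply target their
naive partner.

Zero-variance rows are skipped and counted (`skipped_zero_variance`)
rather than propagating NaNs.

## Cross-species conservation

`map_intervals()` carries catalog coordinates through a gapless
alignment-block map: all aligned bases of an element are projected,
positions inside minus-strand blocks are mirrored within the block, the
target chromosome receiving the most aligned bases wins (ties:
lexicographic), and the span `[min, max+1)` of the projected positions is
returned. "Mapped" requires at least one aligned base - the most
permissive reading; `min_mapped_frac` tightens it for sensitivity
analyses. `call_conservation()` marks a mapped element conserved when its
projected span overlaps any target-species element by at least 1 bp, and
reports the mapping rate (mapped/total) and conservation rate
(conserved/mapped). `lineage_conserved()` intersects per-target
conservation sets to find elements conserved across a whole lineage.

## ChIP-seq library QC

`qc_report()` computes the standard complexity and enrichment metrics on
mapped-read interval tables: NRF (distinct locations / reads), PBC1 and
PBC2 (one-read locations over all / over two-read locations, with an
infinity sentinel when no location has exactly two reads), FRiP (fraction
of reads overlapping peaks by >= 1 bp), and the Jensen-Shannon distance
between the ChIP and input libraries - binned read-start distributions
(default 500 bp bins), JS divergence in log base 2, square root, so the
distance lies in [0, 1]. Location identity includes strand, the usual
ENCODE duplicate definition. The JSD is computed between raw binned
distributions; input-subtracted variants exist in the wild and could be
added, but raw is the documented dialect here.

## GWAS-SNP enrichment

`flag_in_re()` marks SNPs inside catalog elements (half-open
containment), `pvalue_density()` contrasts the association-p-value
histograms of SNPs inside vs outside elements, and
`category_enrichment()` tests each annotation category (e.g. geQTL,
mQTL) for enrichment inside elements against the *uncategorized* SNPs
with `fisher_exact_2x2()` - the sample odds ratio `ad/bc` plus the exact
two-sided p-value by hypergeometric enumeration. The uncategorized
baseline (rather than the complement of the category) matches how such
comparisons are usually phrased; multi-category SNPs count in each of
their categories. Both the frequency ratio (`ratio_vs_other`) and the
odds ratio are reported - they differ noticeably once the baseline in-RE
fraction is not small, so conflating them is a common source of
confusion.

## The simulator

`simulate_study()` generates, under one seed:

* **Layout** (`simulate_truth()`): disjoint TADs in regular jittered
  slots (default 40 TADs on 2 x 10 Mb), genes and REs in interleaved
  non-overlapping slots inside each TAD, per-RE tissue-activity sets, and
  planted RE-gene links (10% of in-TAD pairs; each RE drives at most one
  gene so the latent model stays coherent).
* **Segmentations**: each RE becomes a run of active states in its
  active tissues; the background tiles the chromosome with state 14
  interleaved with 12-13. Consolidating these tracks recovers the
  planted catalog exactly.
* **Counts**: gene expression and RE signal are negative-binomial
  (dispersion 0.05 by default) around means driven by a latent
  log-activity per sample. The latent has a tissue-consistent component
  (`tissue_share = 0.3`) and a sample-specific component - replicates
  are different animals, so most activity variation is individual - and
  a true link's RE shares its gene's *per-sample* latent with
  correlation `link_rho`, because both assays of a replicate come from
  the same tissue sample. This detail matters statistically: if
  replicates shared their entire latent, the two replicates of a tissue
  would be near-duplicates, the effective sample size would drop from 16
  toward 8, and the t-approximation p-values would be anti-conservative,
  inflating the false-discovery rate well past its nominal level.
  With the per-sample latent the null is calibrated at n = 16.
  Setting `nb_dispersion = 0` switches to the noise-free limit (expected
  counts emitted directly), which makes invariance checks exact.
  Per-sample depth factors span a 3.3-fold range so TMM has real work.
* **CTCF architecture**: a random genome with the motif consensus
  embedded forward at each TAD start and reverse-complemented at each
  TAD end (motif midpoints coincide exactly with the recorded TAD
  boundaries), peaks around every embedded motif, and decoy peaks
  rejection-sampled to contain no motif hit at the scan threshold. The
  prediction chain therefore recovers the planted TADs
  interval-for-interval on every seed.
* **Alignment map**: co-linear gapless blocks with holes punched at REs
  planted as unmapped and block breakpoints steered away from RE bodies;
  conserved REs get their exact mapped span as a target-catalog entry.
* **SNPs**: one uncategorized group and one group per category,
  categorized SNPs falling inside REs at a planted odds ratio
  (default 2.5) relative to the uncategorized baseline (0.12); in-RE
  SNPs draw p-values from Beta(0.4, 3), out-of-RE SNPs from
  Uniform(0, 1).

What the simulator does *not* emulate: realistic chromatin-state
transition statistics, read-level data, gapped alignments, paralogy
(multi-locus mappings), linkage disequilibrium between SNPs, and
correlated gene networks. Tests passing on simulated data therefore
demonstrate the correctness of the algorithms under the stated model,
not the biological accuracy of any particular threshold on real data.

## Numerical choices and degenerate inputs

* Spearman p-values use the t-approximation; |rho| = 1 maps to p = 0.
* The PWM p-value threshold is exact to the 1e-3-bit discretization; `N`
  bases never match.
* `pbc2` reports `Inf` when no location carries exactly two reads;
  empty read sets are errors for all QC metrics.
* `fisher_exact_2x2` treats zero-denominator odds ratios with
  `Inf`/`NaN` sentinels and compares hypergeometric probabilities with a
  1e-12 tolerance.
* Ties in peak orientation break by position then strand; nearest-gene
  ties break lexicographically - all deterministic.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
study <- simulate_study(cfg)

catalog <- combine_tissues(consolidate_active(study$segmentations))
catalog$re_class <- classify_re(catalog, study$truth$genes)

pred <- predict_tads(study$ctcf$genome, study$ctcf$peaks, study$ctcf$pwm)

links <- predict_links(normalize_counts(study$expression$re_counts),
                       normalize_counts(study$expression$gene_counts),
                       catalog, study$truth$genes, pred$tads)
links$summary
```

The problem sizes used throughout the tests (2 chromosomes of 10 Mb or
1 Mb, 300-1,000 features, 10-20 seeds per stochastic check) were chosen
so that a full validation run completes in minutes on a single CPU while
keeping binomial/Monte-Carlo error small relative to the tested margins.
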