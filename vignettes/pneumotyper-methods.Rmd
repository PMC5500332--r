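---
title: "Methods: low-biomass lung microbiome analysis and its synthetic bench"
author: "pneumotyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-biomass lung microbiome analysis and its synthetic bench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumotyper)
```

## The problem

Lung tissue is a low-bacterial-biomass sample: nearly all of its DNA is
host-derived, so the bacterial 16S signal amplified from it is small
enough that DNA intrinsic to extraction and amplification reagents can
dominate the sequenced reads. Any claim about a "lung microbiome"
therefore stands or falls on how reagent contamination is identified and
removed, and on whether the remaining signal is distinguishable from the
no-template controls. This package implements one complete analysis
built around that constraint — read-level decontamination against
negative controls, genus-level community statistics, a three-way
pneumotype classification of lung samples, and diversity analysis — and
pairs it with a synthetic-data generator that emulates the statistical
structure of such a study, so every stage can be validated against known
ground truth.

## Decontamination model

Paired reads are joined into contigs over their best suffix/prefix
overlap. The published rule fixes only the 6 bp minimum overlap; we
additionally require 90% identity inside the overlap window and resolve
overlap mismatches in favour of the forward read (synthetic qualities
are constant, so there is no quality arbitration to prefer one read).
An unjoinable pair is a value, not an error.

Contigs from reagent controls and NTC water samples form the
*contaminant index* (NTCs are processed identically to reagent controls
and are included by default; `check_reverse_complement` and the index
membership are configurable). A specimen contig is removed when it
aligns to any indexed contig with **identity ≥ 0.99 over ≥ 250 aligned
bases**. Identity is matching columns divided by alignment columns of an
*ungapped* sliding alignment, in both orientations. Gapped alignment is
deliberately omitted: simulated V4 contigs are fixed-length and
indel-free, and this is a documented limitation for real indel-bearing
data (the published pipeline's aligner settings beyond 99%/250 bp are
not stated, so whether its identities were gap-compressed is unknowable;
we record our semantics in output headers rather than guess).

Candidate index hits are retrieved through shared 31-mers before
alignment verification. The prefilter is lossless for the removal rule:
a ≥ 250 bp match at ≥ 99% identity contains at most 3 mismatches, which
cannot break every 31-mer in a 250 bp window. At the genus-assignment
threshold (> 97%, up to 7 mismatches over 254 bp) a pathological
mismatch spacing could in principle defeat the prefilter; at the error
rates simulated here (≤ 1 substitution per read on average) this has no
practical effect.

Genus assignment is direct reference matching: the reference with the
highest identity wins if that identity strictly exceeds 0.97, ties going
to the lexicographically first genus; everything else is counted in a
reserved `unassigned` column that downstream statistics exclude. De novo
OTU clustering, chimera filtering and external taxonomy databases are
out of scope; for real data a per-contig genus annotation can be
supplied to `process_fastq()`.

## Community statistics

Counts are normalised to per-sample proportions totalling 100%
(all-zero samples stay zero and are flagged). *Representative
microbiomes* are per-genus arithmetic means of `log2(count + 1)` over a
group's members: the pseudocount of 1 keeps zeros at zero and preserves
monotonicity, since the published transform does not state its zero
handling. Sample-to-profile correlations are Pearson on the log2 scale
across the full genus set (Spearman behind a flag); in the intra-group
case each member is compared against the profile of *all* members —
the simplest reading of comparing each sample to its group
representative — with leave-one-out available behind a flag.

The percent **overlap** statistic is implemented in its pooled form:
over the pooled samples of the two groups, each genus detected in both
groups contributes its pooled count times the fraction of pooled
samples containing it, normalised by the pooled total. Read literally,
the published wording ("the average number of sequences/genus …
divided by the total number of sequences in all samples") divides an
*average* by a *total* and yields values roughly 1/n_samples of the
published table's scale; the pooled form reproduces the one
analytically checkable anchor (an intra-URT overlap near the dominant
genus's ~75% share, as published) and is the default, with the literal
variant kept behind `method = "literal"` for comparison. Between-group
overlap restricts to genera detected in both groups, so communities
with disjoint support score 0 — consistent with the near-zero published
drinking-water overlaps. The variant in force is recorded in every
output header.

Group abundance reports list a genus when its group-mean relative
abundance strictly exceeds 1% in *any* group; listed genera show their
actual mean in every group (including sub-threshold means), with "-"
reserved for groups where the genus was never detected, mirroring the
published composition table.

## Pneumotype classification

Lung samples (upper and lower lobes pooled as "lung") are classified in
three steps:

1. **Background**: total retained counts strictly below 50 reads. The
   published rule couples the count floor with "did not differ from the
   water controls" but states no test or threshold for the latter; we
   therefore gate only on the count and report each background sample's
   Bray–Curtis distance to the NTC centroid as QC, because inventing an
   unstated statistical test would be over-reach.
2. **Initialisation**: remaining samples are provisionally `aspirate`
   when their Pearson correlation to the URT representative reaches 0.6
   (a neutral midpoint; the published analysis describes only
   "iterative comparisons"), else `unique`.
3. **Refinement**: recompute the aspirate and unique representatives
   from current members and reassign every sample to the
   better-correlated profile, until stable or 20 iterations — a
   two-group Pearson analogue of k-means. Exact ties go to `unique`,
   the conservative direction that avoids inflating the URT-like group.
   If a group empties, iteration stops with the current labels, so the
   procedure degrades gracefully when only one non-background community
   exists.

`pneumotype()` returns a classed fit with `print`, `summary`, `coef`
(the representative profiles), `predict` (labels new samples with the
fitted profiles and background rule) and `plot` methods.

## Diversity

Chao1 uses the classic form `S_obs + F1²/(2 F2)` with the bias-corrected
branch `S_obs + F1(F1−1)/(2(F2+1))` when `F2 = 0` (the classic form is
undefined there; whether the published curves used bias correction is
unstated, so the branch in force is recorded in output headers).
Rarefaction subsamples without replacement to a fixed depth — default
340 reads with 50 random subsamplings, the published setting — and
samples below the target depth are skipped with a warning rather than
aborting a group comparison. Reported SDs are sample standard deviations
(n−1). Inverse Simpson is `1/Σp²`. Bray–Curtis is `Σ|x−y| / Σ(x+y)`.

PERMANOVA partitions the squared-distance total into among/within-group
sums, giving the pseudo-F; the p-value is `(1 + #{F_perm ≥ F_obs}) /
(1 + n_permutations)` (never exactly zero) over seeded label
permutations, 999 by default. Multi-factor variance partitioning is
reduced to running the one-factor procedure per factor
(`permanova_factors()`), reporting each factor's R² — full two-factor
partitioning is out of scope.

## The synthetic bench

The generator emulates the study's structure, not its raw data:

- **Profiles**: the shipped URT, lung-aspirate and lung-unique profiles
  are the published group compositions at the > 1% reporting threshold,
  renormalised; the contaminant community is dominated by *Pseudomonas*
  (53%) and *Escherichia* (15%) as published, with the remaining 32%
  spread over common reagent genera chosen here. Bedding and chow
  profiles share *Streptococcus* / *Acinetobacter* / *Flavobacterium*
  with the specimen groups (matching the published environmental
  overlap pattern); drinking water uses freshwater genera absent
  elsewhere, making its overlaps ~0.
- **Counts**: per sample, depth ~ log-normal and composition ~
  Dirichlet(dispersion × profile), then multinomial. Per-group depths
  are unstated in the publication; defaults are calibrated once to its
  two quantitative anchors — the > 1,000-fold URT/lung 16S asymmetry
  and the reagent-control yield (~9,000 reads over 11 controls):
  URT ~5×10⁴ reads/sample (dispersion 500: "highly reproducible"),
  lung-unique ~300 (dispersion 20: strong mouse-to-mouse variability),
  lung-aspirate ~2×10³ (more reads than other lung samples),
  lung-background ~15 (below the 50-read floor), NTC ~30, reagent
  controls ~800, environmental ~5×10³.
- **Reads**: 150 bp pairs drawn from per-genus 254 bp reference
  sequences (random, mutually < 90% identical so the 97% assignment
  threshold is unambiguous), uniform per-base substitution errors
  (default 0.002), no indels, no chimeras, constant qualities. Every
  specimen gains Poisson(100) contaminant pairs; controls contain only
  contaminant reads. Read ids carry the true genus for test oracles
  only; `mask_provenance = TRUE` scrambles them to verify inference
  never peeks.
- **Design** (`scenario_paper_default()`): 18 animals × (1 URT + 2 lung)
  samples, 8 reagent + 3 NTC controls, 3 samples per environmental
  source; lung samples split 12/21/3 = 33/58/9% across
  background/unique/aspirate, the published mix. The split is assigned
  deterministically and shuffled across animals per seed.

What passing tests on this bench do **not** show: the generator has no
rare-genus tail (profiles stop at the 1% reporting threshold), no
phylogenetic structure, no chimeras or indels, and its groups are
cleaner than real tissue. Correlations and overlaps on synthetic data
therefore run higher than the published values (e.g. intra-URT overlap
near 100 versus 74 published); only directional structure — URT
conserved, lung-unique diverse, aspirate intermediate — is expected to
transfer, and that is what the acceptance checks assert.

## Numerical and reproducibility choices

- All RNG flows through R's generator, including the C++ read mutation,
  so a single seed governs a run; per-operation fixed offsets give each
  stage its own substream, and per-sample substreams mean adding samples
  does not perturb earlier ones.
- Degenerate inputs are values, not crashes, where the analysis needs
  them (unjoined pairs, all-zero proportion rows, empty contaminant
  index, shallow samples in rarefaction); they are errors where a
  statistic is undefined (Chao1/inverse Simpson on empty samples,
  correlation of a constant vector, PERMANOVA with singleton groups).
- Problem sizes in the test suite and acceptance script are the
  default 18-animal design (~10⁶ read pairs end to end) for the single
  full pipeline run, a 20-seed counts-level replication for recovery,
  and 10³ replicates at 199 permutations for the PERMANOVA
  type-I-error study; these sizes give stable estimates while keeping a
  full validation run in minutes on one CPU.
- Every output table carries the package version, seed, config hash and
  statistic-variant flags in a header comment, and the run manifest
  lists md5 checksums of the bundle, which is byte-identical across
  reruns at a fixed seed.

## Known limitations

Ungapped identity only (no indel tolerance); no quality-aware merging;
direct reference-based genus assignment in place of OTU clustering and
database taxonomy; one-factor PERMANOVA only; and the synthetic bench's
simplifications listed above. Real-data mode (`process_fastq()`)
deliberately stops after decontamination unless a per-contig genus
annotation is supplied.
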