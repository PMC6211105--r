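---
title: "Read-depth copy number of B-chromosome-derived fragments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth copy number of B-chromosome-derived fragments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bchromcnv)
```

## The problem

B chromosomes are dispensable, supernumerary chromosomes that occur in
variable copy number between cells, individuals and populations. When
B-derived sequence fragments are homologous to regions of the standard
(A-chromosome) genome, their abundance in an individual can be read off
whole-genome sequencing data as excess read depth over those regions:
a fragment present in the normal two copies attracts the diploid baseline
depth, one present in ten copies attracts roughly five times that.

`bchromcnv` implements this personalized read-depth analysis as a
reusable pipeline: windowed depth of coverage over a repeat-masked
reference, GC-bias correction, calibration of the depth-to-copy-number
scale on designated diploid control regions, aggregation to fragment- and
population-level copy numbers, and the two auxiliary computations that
accompany such a study — spacer-joined pseudo-scaffold construction from
consensus fragments, and flow-cytometry genome-size estimation with its
sequence-density bookkeeping. A fully specified synthetic-cohort
generator with known planted copy numbers makes every stage testable
without any external data.

## The copy-number model

For each individual, reads are aligned to the reference reporting *all*
alignments of multi-mapping reads (the all-alignments convention keeps
collapsed repeats from losing depth; duplicates are not removed). The
repeat-masked genome is tiled into windows of exactly $W = 1000$
*unmasked* bases — masked or N bases are skipped, so a window's genomic
span can exceed 1 kb; the terminal remainder of each contig is dropped.
Fixing the unmasked length rather than the genomic length keeps the
depth denominator constant, following the read-depth
segmental-duplication tradition.

With $d_w$ the mean per-base depth over the window's 1000 member bases,
the model is:

1. **GC correction.** Windows are binned by GC fraction (bin width
   0.025). The corrected depth is
   $\tilde d_w = d_w \cdot \bar d / \bar d_{b(w)}$, where $\bar d$ is the
   global mean depth and $\bar d_{b(w)}$ the mean depth of the window's
   GC bin. Bins with fewer than 20 windows are too noisy to estimate and
   fall back to $\bar d$ (no correction).
2. **Robust fitting.** Both $\bar d$ and the $\bar d_b$ are computed
   after iterative 3-sigma clipping of outlier windows: windows whose
   depth departs from the running mean by more than three standard
   deviations — i.e. strongly deleted or duplicated regions — are
   excluded from the *fit* (they are still corrected). Without this,
   planted duplications contaminate their GC bins and drag high
   copy-number estimates down by tens of percent; the clipping mirrors
   the iterative outlier exclusion used by the classical read-depth
   copy-number callers.
3. **Control calibration.** The scale anchor is
   $c = \mathrm{median}\{\tilde d_w : w \text{ fully inside a control
   region}\}$, over regions assumed diploid in every individual (two
   single-exon control genes and one ~400 kb control fragment). The
   median is robust to residual copy-number variation in individual
   control windows. At least 5 control windows are required.
4. **Copy number.** $\mathrm{cn}_w = 2\,\tilde d_w / c$, so a window at
   control depth reads as exactly diploid.

A fragment's copy number is the unweighted mean of the windows lying
fully inside it; fragments containing no complete window are reported as
missing, never as zero. Window and fragment copy numbers are classified
into bands on the continuous axis: absent $[0, 0.1)$, homozygous
deletion $[0.1, 1.5)$, heterozygous deletion $[1.5, 2.6)$, normal
diploid $[2.6, 4]$, heterozygous duplication $(4, 6]$, multiple
duplication $(6, \infty)$. The printed one-decimal band edges
(0.1–1.4 / 1.5–2.5 / 2.6–4 / >4) are realized as these half-open
continuous boundaries; the open-ended "multiple duplications" class is
taken to start above 6, one full extra diploid copy beyond the
heterozygous-duplication band. Copy numbers are throughout on the
*diploid* scale (controls read ~2), which matches the control band of
1.5–3 used for validation; the alternative per-haploid reading would
halve every number and is not used.

Per population, each fragment is summarized by the min, max, range and
mean of its per-individual copy numbers. A fragment is flagged
*variable* when any individual leaves the normal-control band
$[1.5, 3]$ — the study's own operational criterion for a diploid-normal
control — and *multiplied* when any individual exceeds 3 copies.

## What the simulator emulates

`sim_config()` fixes the study conditions; all outputs are a pure
function of it, including the seed.

* **Reference** (default 2 Mb, one contig): a mosaic of constant-GC
  blocks (default 20 kb at GC 0.35/0.45/0.55/0.65) so that GC bias is
  identifiable; ~17% of bases repeat-masked in blocks of 0.2–2 kb,
  matching the repeat content scale of a fish genome assembly. Masking
  is annotational (ordinary sequence under the mask): the analysis never
  looks there, and generating literal repeat copies would only exercise
  the aligner, which is not the object under test.
* **B fragments** (default 30 of 1–5 kb) and **controls** (two 3 kb
  single-exon genes, one 400 kb fragment) are placed disjointly and
  unmasked, placement exactly uniform over the remaining free space.
* **Copy numbers**: per population, per individual and fragment,
  $\max(0, \mathrm{round}(\mathcal N(\mu, \sigma)))$, or a fixed value
  ladder for recovery experiments. The three default populations carry
  decreasing dispersion — $\sigma = 6, 3, 1.5$ around means 6, 5, 4
  with 4 individuals each — reproducing the qualitative
  wide/intermediate/narrow ordering of the Indian, South-East-Asian
  and Australian groups; the study reports no per-population
  distributions, so only this ordering (not the numbers) is the target.
* **Individual genomes**: two haplotypes; copy number 0/1 deletes the
  fragment from both/one haplotype, values above 2 insert extra copies
  at uniformly chosen unmasked, non-control, non-fragment loci —
  dispersed rather than tandem, because the pipeline measures depth
  only and dispersed insertion keeps the structural signal out of the
  way.
* **Reads** (default 100 bp at 7-fold coverage): sampled with
  replacement from all start positions of both haplotypes, with weight
  $\exp(\beta \cdot 2(g - 0.5))$ for read GC fraction $g$ and bias
  strength $\beta$ (default 0.5), normalized genome-wide; strand
  uniform; constant quality; substitution errors optional (default 0).
  The read count is set so an unduplicated, unbiased locus has expected
  depth equal to the configured coverage.
* **Alignment**: an exact matcher reports every full-length exact match
  of each read in either orientation (Aho–Corasick via
  `Biostrings::matchPDict`), emulating the all-alignments mode of a
  production aligner for error-free reads; unmatched reads are counted.
  Externally produced SAM alignments can be supplied instead, in which
  case CIGAR reference consumption is honoured and secondary alignments
  are counted.

What the simulator does *not* model: paired-end inserts, indels and
structural breakpoint realism, quality-score profiles, true repeat
sequence similarity, and intra-individual (cell-to-cell) mosaicism of
B counts. Passing tests therefore demonstrate the statistical machinery
(windowing, GC correction, calibration, aggregation) under a clean
mapping model — not robustness to alignment artifacts in repeat-rich
real data, which the repeat mask is there to avoid in the first place.

## Numerical and design choices

* Coordinates are 0-based half-open in every table and BED file;
  1-based closed only inside IRanges machinery and SAM ingestion.
* GC bins are indexed by `floor(gc / 0.025)` with a `1e-9` epsilon so
  exact boundary values (a window at GC 0.300) land deterministically
  in their nominal bin; GC 1 collapses into the last bin.
* Window GC and depth are computed over exactly the 1000 member bases.
* A corrected bin mean of zero with nonzero window depth is an error
  (it would imply division by zero), but zero raw depth corrects to
  zero.
* Consensus calling: maximal runs with depth ≥ `min_support` (default
  3) and length ≥ `min_len` (default 200 bp); per-base majority vote
  among covering reads with ties resolved to the reference base (or the
  alphabetically first leader if the reference base is not among the
  leaders). Defaults are conventional small-support values; both are
  exposed on the CLI.
* Chaining uses the ascending spacer ladder 100 bp / 1 kb / 10 kb; the
  final 10 kb value is fixed by the joined-pseudo-scaffold convention,
  the earlier rungs mirror the incremental construction. Because the
  ladder ascends, the result equals a single pass at 10 kb — asserted
  as an invariant. Chains never cross contigs; spacer Ns are excluded
  from every GC, repeat and density denominator.
* Flow-cytometry sizes: $\text{pg} = \text{pg}_{\text{std}} \cdot
  I_{\text{sample}} / I_{\text{std}}$ and 1 pg = 0.978e9 bp; all sizes
  are 2C (diploid) values. Group comparison uses the pooled-variance
  Student t (not Welch), matching the classical test named for such
  comparisons; means/sd are reported in Mb.
* The printed worked example "2901 SNVs per 361,036 kb" alongside
  "approximately eight per kb" is only consistent if the denominator is
  read as base pairs (361,036 bp ≈ the 386,725 bp joined assembly minus
  masked bases); `snv_density()` therefore takes its length argument in
  bp, and 2901/361.036 kb = 8.04/kb reproduces the printed "eight".

## Scales used by the tests

The test-suite simulations are sized to exercise the full pipeline while
keeping a complete run comfortable on a single CPU: the control-diploidy
and recovery checks run at the full default scale (2 Mb, 12 or 3
individuals, 7×); the 20-replicate population-ordering check runs at a
reduced 300 kb / 12-fragment scale, which preserves the dispersion
ordering signal (truth ranges of ~12 vs ~6 vs ~3 copies dwarf the
~0.2–0.4 estimation noise); oracle comparisons run on ≤50 kb instances
where brute-force recounting is instant.

## Known limitations

* **Band-boundary degeneracy.** Planted copy numbers 4 and 6 sit
  exactly on the category boundaries (normal/heterozygous-duplication
  at 4.0, heterozygous/multiple at 6.0). Fragment-mean estimates at
  7-fold coverage have a standard deviation of roughly 0.2–0.3, so an
  unbiased estimate of a boundary value falls on the "wrong" side with
  probability approaching one half, and no estimator can assign the
  nominal band much more than ~60% of the time for those values. Over
  the recovery ladder {0, 1, 2, 4, 6, 10} the expected band-recovery
  fraction is therefore ~87%, and the observed value in the packaged
  recovery run is 84%: a property of the band geometry at this
  coverage, not of the estimator — the non-boundary values recover
  essentially perfectly and estimates are monotone in truth throughout.
* **Junction attrition at high copy number.** Reads spanning the ends
  of a dispersed extra copy are chimeric with respect to the reference
  and are dropped by the exact full-length matcher (a production
  aligner would soft-clip them). Each extra copy of length $F$ loses
  about $L/F$ of its depth contribution for read length $L$ — ~0.2
  copies at copy number 10 with 5 kb fragments — so the highest copy
  numbers are estimated with a slight downward bias and occasional
  fragment-mean errors up to ~0.8 copies.
* The GC model needs populated bins: on references much below ~1 Mb,
  tail GC bins fall under the 20-window minimum and revert to the
  global mean, leaving residual GC bias for windows in those bins.
* Copy numbers are relative to the control regions; if the controls
  were themselves copy-number variable in some individual, that
  individual's whole scale would shift — the control validation table
  is the guard against this.
* The exact matcher requires error-free reads; with a nonzero simulated
  error rate, align externally and supply the SAM.
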