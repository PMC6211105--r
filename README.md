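# bchromcnv

Read-depth copy-number analysis of B-chromosome-derived genome fragments
across individuals and populations.

B chromosomes are dispensable, supernumerary chromosomes whose count
varies between individuals and populations. Where B-derived fragments
are homologous to regions of the standard (A) genome, an individual's
B content is visible in whole-genome resequencing data as excess read
depth over those regions. `bchromcnv` is for researchers who want to
quantify that signal reproducibly: it estimates a GC-corrected copy
number for every 1 kb window of a repeat-masked reference, calibrated so
that designated diploid control regions read as copy number 2, and
aggregates windows into per-fragment, per-individual and per-population
copy-number summaries. It also covers the two satellite computations of
such a study — building spacer-joined pseudo-scaffolds from consensus
fragments of chromosome-microdissection reads, and flow-cytometry
genome-size estimation with SNV/gene-density bookkeeping — plus a fully
specified synthetic-cohort simulator with known planted copy numbers, so
the whole pipeline is testable end to end without external data.

## The model

For window *w* with mean per-base depth *d<sub>w</sub>* over exactly
1000 unmasked bases:

- GC correction by binned scaling:
  *d̃<sub>w</sub> = d<sub>w</sub> · d̄ / d̄<sub>b(w)</sub>*, with GC bins
  of width 0.025, a 20-window minimum per bin, and iterative 3-sigma
  clipping of copy-number-variant windows from the fit;
- control calibration: *c* = median corrected depth over windows fully
  inside the control regions (two single-exon control genes and one
  ~400 kb control fragment, assumed diploid in everyone);
- copy number: **cn<sub>w</sub> = 2 · d̃<sub>w</sub> / c**.

Fragment copy number is the mean of its member windows; values classify
into the bands absent (<0.1), homozygous deletion (0.1–1.5),
heterozygous deletion (1.5–2.6), normal diploid (2.6–4), heterozygous
duplication (4–6) and multiple duplication (>6). Genome sizes convert
fluorescence ratios via pg = pg<sub>standard</sub> ·
I<sub>sample</sub>/I<sub>standard</sub> and 1 pg = 0.978 × 10⁹ bp.

## Worked example

Simulate a 400 kb cohort — two populations of two individuals, one with
wide and one with narrow planted copy-number dispersion — and run the
full pipeline:

```r
library(bchromcnv)

cfg <- sim_config(seed = 1, genome_length = 400000, n_b_fragments = 6L,
                  b_fragment_length = 4000, control_fragment_length = 80000,
                  populations = list(
                    list(label = "wide",   n = 2L, cn_mean = 6, cn_sd = 6),
                    list(label = "narrow", n = 2L, cn_mean = 4, cn_sd = 1.5)))
co  <- simulate_cohort(cfg)
res <- run_cohort_pipeline(co)

co$truth$cn_matrix_true      # what was planted
round(res$matrix$cn, 2)      # what the pipeline recovered
```

```
truth:                               estimates:
          frag_001 ... frag_006                frag_001 ... frag_006  ctrl_frag
wide_01          0          13       wide_01       0.00      13.55       2.01
wide_02          6          13       wide_02       6.21      13.78       2.03
narrow_01        3           4       narrow_01     2.97       3.82       1.99
narrow_02        4           3       narrow_02     4.65       2.77       1.99
```

Planted copy numbers from 0 to 15 are recovered to a few tenths of a
copy, and every control region reads as diploid
(`res$controls`: `range [1.92, 2.38]; PASS (all within [1.5, 3])`).
Per-population summaries (`res$summary`) give each fragment's min, max,
range and mean per population — the wide population shows per-fragment
ranges of ~4–6 copies against ~1–2 in the narrow one.

The scalar computations print, for example:

```r
genome_size(0.72, 1, 2.5)   # genome_size_estimate: 1.800 pg = 1,760,400,000 bp
snv_density(2901, 361036)   # 8.035 variants per kb
density_ratio(30.2, 5.16)   # ratio 5.85, nearest integer 6
```

A command-line wrapper with `simulate`, `depth`, `population`,
`scaffold` and `run` subcommands is installed under
`inst/cli/bchromcnv.R`.

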