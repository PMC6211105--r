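# Shared fixtures: small configurations and hand-built objects used
# across the test files. Everything is generated in code at test time.

# a compact cohort configuration that still leaves room for all reserved
# intervals (control fragment + genes + B fragments + repeats)
tiny_config <- function(seed = 11, ...) {
  defaults <- list(seed = seed,
                   genome_length = 150000,
                   gc_block_length = 10000,
                   repeat_fraction = 0.1,
                   n_b_fragments = 4L,
                   b_fragment_length = 2000,
                   control_gene_length = 2000,
                   control_fragment_length = 20000,
                   populations = list(list(label = "p1", n = 2L,
                                           cn_mean = 3, cn_sd = 1)),
                   coverage = 7, gc_bias_strength = 0)
  dots <- list(...)
  args <- defaults
  for (nm in names(dots)) args[[nm]] <- dots[[nm]]
  do.call(sim_config, args)
}

# a window table built directly, bypassing tiling (for GC/calibration
# unit tests); gc and raw_depth given per window, genomic span contiguous
fake_windows <- function(raw_depth, gc = rep(0.5, length(raw_depth)),
                         window = 1000L) {
  n <- length(raw_depth)
  data.frame(chrom = "ctg1",
             start = (seq_len(n) - 1L) * window,
             end = seq_len(n) * window,
             unmasked_len = window,
             gc = gc,
             raw_depth = raw_depth,
             stringsAsFactors = FALSE)
}

# hand-built read placements: reads (character vector) placed at given
# 1-based starts on a single contig
fake_placements <- function(reads, starts, contig_len,
                            strand = rep("+", length(starts)),
                            read_id = seq_along(reads)) {
  reads <- Biostrings::DNAStringSet(reads)
  w <- Biostrings::width(reads)[read_id]
  structure(list(
    hits = data.frame(chrom = rep("ctg1", length(starts)), start = starts,
                      end = starts + w - 1L, read = read_id,
                      strand = strand, stringsAsFactors = FALSE),
    reads = reads,
    read_length = Biostrings::width(reads)[1],
    contig_lengths = c(ctg1 = contig_len),
    n_reads = length(reads),
    unplaced = 0L), class = "read_placements")
}

# random DNA string of length n
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
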