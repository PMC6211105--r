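#' Build a synthetic repeat-annotated reference genome
#'
#' Generates a single-contig reference as a mosaic of constant-GC blocks,
#' then places, mutually disjoint and in this order: the large diploid
#' control fragment, the two single-exon control genes, the B-derived
#' fragments, and repeat-masked blocks totalling
#' \code{repeat_fraction * genome_length} (within one block length).
#' Repeats are annotational only (masked intervals over ordinary sequence);
#' downstream windowing excludes them, mirroring an analysis on a
#' repeat-masked reference.
#'
#' Placement is exactly uniform over all positions at which an interval
#' fits into the remaining free space, so the layout is a deterministic
#' function of the configuration seed.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return An object of class \code{sim_reference}: a list with
#'   \describe{
#'     \item{seq}{\code{DNAStringSet}, one contig named \code{ctg1}.}
#'     \item{mask}{Repeat intervals (BED-convention data.frame).}
#'     \item{genes}{The two control-gene intervals.}
#'     \item{controls}{All diploid control intervals (genes + fragment).}
#'     \item{fragments}{B-derived fragment intervals, named
#'       \code{frag_001}, ...}
#'     \item{insertable}{Free intervals (unmasked, non-control,
#'       non-fragment) available as insertion loci for extra copies.}
#'   }
#' @export
build_reference <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(.derive_seed(cfg$seed, 1L))
  G <- cfg$genome_length
  contig <- "ctg1"

  ## GC mosaic sequence
  n_blocks <- ceiling(G / cfg$gc_block_length)
  block_lvl <- sample(cfg$gc_levels, n_blocks, replace = TRUE)
  lvl <- rep(block_lvl, each = cfg$gc_block_length)[seq_len(G)]
  is_gc <- stats::runif(G) < lvl
  pick <- stats::runif(G) < 0.5
  base <- character(G)
  base[is_gc & pick] <- "G"
  base[is_gc & !pick] <- "C"
  base[!is_gc & pick] <- "A"
  base[!is_gc & !pick] <- "T"
  seq <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(seq) <- contig

  ## interval placement in free space
  free <- IRanges::IRanges(1L, G)
  place <- function(width, label) {
    gaps <- free[IRanges::width(free) >= width]
    if (length(gaps) == 0L)
      stop("cannot place interval '", label, "' (", width,
           " bp) disjointly in the remaining free space")
    slots <- IRanges::width(gaps) - width + 1L
    g <- if (length(gaps) == 1L) 1L else
      sample.int(length(gaps), 1L, prob = slots)
    off <- if (slots[g] == 1L) 0L else sample.int(slots[g], 1L) - 1L
    iv <- IRanges::IRanges(IRanges::start(gaps)[g] + off, width = width)
    free <<- IRanges::setdiff(free, iv)
    iv
  }

  ctrl_frag <- place(cfg$control_fragment_length, "control_fragment")
  gene1 <- place(cfg$control_gene_length, "control_gene_1")
  gene2 <- place(cfg$control_gene_length, "control_gene_2")

  frag_w <- if (cfg$b_fragment_length[1] == cfg$b_fragment_length[2])
    rep(cfg$b_fragment_length[1], cfg$n_b_fragments)
  else
    sample(seq(cfg$b_fragment_length[1], cfg$b_fragment_length[2]),
           cfg$n_b_fragments, replace = TRUE)
  frag_ids <- sprintf("frag_%03d", seq_len(cfg$n_b_fragments))
  frags <- IRanges::IRanges()
  for (i in seq_len(cfg$n_b_fragments))
    frags <- c(frags, place(frag_w[i], frag_ids[i]))
  names(frags) <- frag_ids

  target_mask <- round(cfg$repeat_fraction * G)
  mask <- IRanges::IRanges()
  masked <- 0L
  k <- 0L
  rng <- cfg$repeat_block_range
  while (masked < target_mask) {
    k <- k + 1L
    w <- if (rng[1] == rng[2]) rng[1] else
      sample(seq(rng[1], rng[2]), 1L)
    w <- min(w, target_mask - masked)  # last block trimmed to hit target
    iv <- place(w, paste0("repeat_block_", k))
    mask <- c(mask, iv)
    masked <- masked + IRanges::width(iv)
  }
  mask <- IRanges::reduce(sort(mask))

  to_bed <- function(ir, nm = NULL) {
    if (length(ir) == 0L)
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        stringsAsFactors = FALSE))
    out <- data.frame(chrom = contig, start = IRanges::start(ir) - 1L,
                      end = IRanges::end(ir), stringsAsFactors = FALSE)
    if (!is.null(nm)) out$name <- nm else if (!is.null(names(ir)))
      out$name <- names(ir)
    out
  }

  genes <- to_bed(c(gene1, gene2), c("control_gene_1", "control_gene_2"))
  controls <- rbind(genes,
                    to_bed(ctrl_frag, "control_fragment"))
  out <- list(seq = seq,
              mask = to_bed(mask,
                            if (length(mask)) sprintf("repeat_%04d",
                                                      seq_along(mask))),
              genes = genes,
              controls = controls,
              fragments = to_bed(frags),
              insertable = to_bed(IRanges::reduce(free)))
  class(out) <- "sim_reference"
  out
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("sim_reference:", sum(Biostrings::width(x$seq)), "bp,",
      nrow(x$mask), "masked blocks (",
      sum(x$mask$end - x$mask$start), "bp ),",
      nrow(x$fragments), "B fragments,",
      nrow(x$controls), "control regions\n")
  invisible(x)
}

#' Write reference artifacts to a directory
#'
#' Emits \code{reference.fa}, \code{mask.bed}, \code{genes.bed},
#' \code{controls.bed} and \code{fragments.bed}.
#'
#' @param ref A \code{sim_reference}.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(ref$seq, file.path(dir, "reference.fa"))
  write_bed(ref$mask, file.path(dir, "mask.bed"))
  write_bed(ref$genes, file.path(dir, "genes.bed"))
  write_bed(ref$controls, file.path(dir, "controls.bed"))
  write_bed(ref$fragments, file.path(dir, "fragments.bed"))
  invisible(dir)
}
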