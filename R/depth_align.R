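#' Map error-free reads to a reference at every exact match position
#'
#' An exact full-length matcher standing in for an external all-alignments
#' aligner on error-free reads: each read is reported at every position of
#' the reference where it matches exactly, in either orientation (so a read
#' whose source region occurs k times in the reference contributes k
#' placements). Reads with no exact match anywhere are dropped and counted.
#' Matching uses the Aho-Corasick machinery of
#' \code{\link[Biostrings]{matchPDict}}.
#'
#' @param reads A constant-width \code{DNAStringSet} (or FASTQ path).
#' @param reference A \code{DNAStringSet} of reference contigs (or a
#'   \code{sim_reference}).
#' @return An object of class \code{read_placements}: list with
#'   \code{hits} (data.frame: chrom, start (1-based), end, read, strand),
#'   \code{reads}, \code{read_length}, \code{contig_lengths},
#'   \code{n_reads} and \code{unplaced}.
#' @export
map_reads_exact <- function(reads, reference) {
  if (is.character(reads)) reads <- read_fastq(reads)
  if (inherits(reference, "sim_reference")) reference <- reference$seq
  if (length(unique(Biostrings::width(reads))) > 1L)
    stop("map_reads_exact requires constant-width reads")

  pd_f <- Biostrings::PDict(reads)
  pd_r <- Biostrings::PDict(Biostrings::reverseComplement(reads))
  n <- length(reads)
  hit_count <- integer(n)
  hits <- vector("list", 2L * length(reference))
  k <- 0L
  for (ci in seq_along(reference)) {
    contig <- names(reference)[ci]
    subj <- reference[[ci]]
    for (ori in c("+", "-")) {
      m <- Biostrings::matchPDict(if (ori == "+") pd_f else pd_r, subj)
      cnt <- S4Vectors::elementNROWS(m)
      hit_count <- hit_count + cnt
      if (sum(cnt) > 0L) {
        ir <- unlist(m)
        k <- k + 1L
        hits[[k]] <- data.frame(
          chrom = contig,
          start = IRanges::start(ir),
          end = IRanges::end(ir),
          read = rep(seq_len(n), cnt),
          strand = ori,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (k > 0L) do.call(rbind, hits[seq_len(k)]) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               read = integer(), strand = character(),
               stringsAsFactors = FALSE)
  out <- list(hits = hits,
              reads = reads,
              read_length = Biostrings::width(reads)[1],
              contig_lengths = stats::setNames(Biostrings::width(reference),
                                               names(reference)),
              n_reads = n,
              unplaced = sum(hit_count == 0L))
  class(out) <- "read_placements"
  out
}

#' @export
print.read_placements <- function(x, ...) {
  cat("read_placements:", x$n_reads, "reads,", nrow(x$hits),
      "placements,", x$unplaced, "unplaced\n")
  invisible(x)
}

#' Per-base read depth from alignments
#'
#' Computes depth of coverage per reference base, counting every reported
#' alignment of a multi-mapping read (all-alignments semantics; secondary
#' alignments are therefore included, duplicates are not removed). Accepts
#' either internal \code{read_placements} or a SAM file path; SAM input is
#' converted through \code{Rsamtools} and depth honours CIGAR reference
#' consumption via \code{GenomicAlignments}.
#'
#' @param x A \code{read_placements} object or a SAM file path.
#' @param reference Reference \code{DNAStringSet} (or \code{sim_reference});
#'   required for SAM input to validate contig names and lengths, optional
#'   otherwise.
#' @return A named list of integer vectors, one per contig, giving depth at
#'   every base.
#' @export
ingest_alignments <- function(x, reference = NULL) {
  if (inherits(reference, "sim_reference")) reference <- reference$seq
  if (inherits(x, "read_placements")) {
    clens <- x$contig_lengths
    if (nrow(x$hits) == 0L)
      warning("no alignments: depth is zero everywhere")
    out <- lapply(names(clens), function(contig) {
      h <- x$hits[x$hits$chrom == contig, , drop = FALSE]
      as.integer(IRanges::coverage(
        IRanges::IRanges(h$start, h$end), width = clens[[contig]]))
    })
    names(out) <- names(clens)
    return(out)
  }
  if (!is.character(x))
    stop("expected a read_placements object or a SAM file path")
  if (is.null(reference))
    stop("SAM input requires the reference sequences")
  bam <- Rsamtools::asBam(x, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  galn <- GenomicAlignments::readGAlignments(bam)
  unknown <- setdiff(unique(as.character(GenomicRanges::seqnames(galn))),
                     names(reference))
  if (length(unknown) > 0L)
    stop("alignment contig not present in reference: ", unknown[1])
  if (length(galn) == 0L)
    warning("no alignments: depth is zero everywhere")
  cov <- GenomicAlignments::coverage(galn)
  out <- lapply(names(reference), function(contig) {
    n <- Biostrings::width(reference)[match(contig, names(reference))]
    if (contig %in% names(cov)) {
      v <- as.integer(cov[[contig]])
      length(v) <- n          # pad with NA then zero-fill
      v[is.na(v)] <- 0L
      v
    } else integer(n)
  })
  names(out) <- names(reference)
  out
}
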