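## Internal interval helpers.
##
## All user-facing tables use BED convention: 0-based, half-open [start, end).
## IRanges (1-based, closed) is used internally for interval arithmetic; the
## two helpers below convert at that boundary.

# data.frame(chrom, start, end, [name]) -> named IRangesList split by chrom
.bed_to_irl <- function(bed) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  ir <- IRanges::IRanges(start = bed$start + 1L, end = bed$end)
  if (!is.null(bed$name)) names(ir) <- bed$name
  S4Vectors::split(ir, factor(bed$chrom, levels = unique(bed$chrom)))
}

.irl_to_bed <- function(irl) {
  chrom <- rep(names(irl), lengths(irl))
  ir <- unlist(irl, use.names = FALSE)
  out <- data.frame(chrom = chrom,
                    start = IRanges::start(ir) - 1L,
                    end = IRanges::end(ir),
                    stringsAsFactors = FALSE)
  nm <- names(ir)
  if (!is.null(nm)) out$name <- nm
  out
}

#' Read and write BED interval tables
#'
#' Thin wrappers around \code{rtracklayer} that exchange intervals as plain
#' data.frames with \code{chrom}, \code{start}, \code{end} and optionally
#' \code{name} columns, 0-based half-open, matching the on-disk BED format.
#'
#' @param path File path.
#' @param bed A data.frame with columns \code{chrom}, \code{start},
#'   \code{end} and optionally \code{name}.
#' @return \code{read_bed} returns the interval data.frame;
#'   \code{write_bed} returns \code{path} invisibly.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm) && !all(is.na(nm))) out$name <- nm
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(bed, path) {
  gr <- GenomicRanges::GRanges(bed$chrom,
                               IRanges::IRanges(bed$start + 1L, bed$end))
  if (!is.null(bed$name)) gr$name <- bed$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# per-base GC indicator (0/1 integer vector) for one DNAString
.gc_indicator <- function(seq) {
  v <- as.integer(Biostrings::letterFrequencyInSlidingView(
    seq, view.width = 1L, letters = "GC"))
  v
}

# derive a child RNG seed from a base seed, kept inside 32-bit integer range
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 2654435761 + offset) %% 2147483647)
}
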