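#' Tile the repeat-masked genome into fixed-size windows
#'
#' Windows are consecutive runs of exactly \code{window} unmasked, non-N
#' bases per contig; masked bases are skipped, so a window's genomic span
#' \code{[start, end)} may exceed \code{window} bp. The terminal remainder
#' of fewer than \code{window} unmasked bases on each contig is dropped.
#' Each window carries the GC fraction of its unmasked bases.
#'
#' @param reference A \code{DNAStringSet} (or \code{sim_reference}).
#' @param mask BED-convention data.frame of masked intervals (may be empty
#'   or NULL).
#' @param window Number of unmasked bases per window (default 1000).
#' @return A data.frame of class \code{depth_windows} with columns
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open genomic
#'   span), \code{unmasked_len}, \code{gc}. An attribute \code{tiling}
#'   retains the per-contig unmasked position index used later to average
#'   depth over exactly the window's bases.
#' @export
tile_windows <- function(reference, mask = NULL, window = 1000L) {
  if (inherits(reference, "sim_reference")) {
    if (is.null(mask)) mask <- reference$mask
    reference <- reference$seq
  }
  window <- as.integer(window)
  stopifnot(window > 0L)
  tiling <- list()
  rows <- list()
  for (ci in seq_along(reference)) {
    contig <- names(reference)[ci]
    n <- Biostrings::width(reference)[ci]
    keep <- rep(TRUE, n)
    if (!is.null(mask) && nrow(mask) > 0L) {
      m <- mask[mask$chrom == contig, , drop = FALSE]
      if (nrow(m) > 0L) {
        if (any(m$start < 0 | m$end > n))
          stop("mask interval outside contig bounds on ", contig)
        ir <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
        for (k in seq_along(ir))
          keep[IRanges::start(ir)[k]:IRanges::end(ir)[k]] <- FALSE
      }
    }
    ## N bases are treated as gaps regardless of the mask
    gc1 <- .gc_indicator(reference[[ci]])
    acgt <- as.integer(Biostrings::letterFrequencyInSlidingView(
      reference[[ci]], 1L, "ACGT"))
    keep[acgt == 0L] <- FALSE

    pos <- which(keep)
    n_win <- length(pos) %/% window
    if (n_win == 0L) next
    pos <- pos[seq_len(n_win * window)]
    win <- rep(seq_len(n_win), each = window)
    gc_sum <- rowsum(gc1[pos], win)
    first <- pos[seq(1L, by = window, length.out = n_win)]
    last <- pos[seq(window, by = window, length.out = n_win)]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = contig,
      start = first - 1L,
      end = last,
      unmasked_len = window,
      gc = as.numeric(gc_sum) / window,
      stringsAsFactors = FALSE)
    tiling[[contig]] <- list(pos = pos, win = win)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               unmasked_len = integer(), gc = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "tiling") <- tiling
  attr(out, "window") <- window
  class(out) <- c("depth_windows", "data.frame")
  out
}

#' Attach raw depth to tiled windows
#'
#' \code{raw_depth} of a window is the mean per-base depth over exactly its
#' \code{unmasked_len} member bases (masked bases contribute nothing).
#'
#' @param windows Output of \code{\link{tile_windows}}.
#' @param depth Per-contig depth vectors from
#'   \code{\link{ingest_alignments}}.
#' @return \code{windows} with a \code{raw_depth} column.
#' @export
window_depth <- function(windows, depth) {
  tiling <- attr(windows, "tiling")
  if (is.null(tiling)) stop("windows lack tiling info; use tile_windows()")
  window <- attr(windows, "window")
  windows$raw_depth <- NA_real_
  for (contig in names(tiling)) {
    t <- tiling[[contig]]
    if (!contig %in% names(depth))
      stop("no depth for contig ", contig)
    d <- depth[[contig]]
    means <- as.numeric(rowsum(d[t$pos], t$win)) / window
    windows$raw_depth[windows$chrom == contig] <- means
  }
  windows
}

#' Write or read the window table
#'
#' Tab-separated, BED-like: chrom, start, end, unmasked_len, gc, raw_depth,
#' corrected_depth, cn (columns present as far as the pipeline has run).
#'
#' @param windows A window data.frame.
#' @param path TSV path.
#' @return \code{read_window_table} returns the window data.frame.
#' @export
write_window_table <- function(windows, path) {
  utils::write.table(as.data.frame(windows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_table
#' @export
read_window_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
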