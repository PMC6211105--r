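#' Call consensus fragments from read placements
#'
#' Finds maximal reference intervals where per-base read depth is at least
#' \code{min_support} and whose length is at least \code{min_len}, and
#' derives a consensus sequence for each: at every base the majority base
#' among covering reads wins, with ties resolved to the reference base
#' (falling back to the alphabetically first tied base when the reference
#' base is not among the leaders).
#'
#' @param placements A \code{\link{map_reads_exact}} result (its
#'   \code{hits} must carry read indices and strands).
#' @param reference \code{DNAStringSet} or \code{sim_reference}.
#' @param min_support Minimum per-base read depth (default 3).
#' @param min_len Minimum fragment length in bp (default 200).
#' @return data.frame of class \code{consensus_fragments}: columns
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open),
#'   \code{support} (minimum depth over the fragment), \code{sequence}.
#'   Zero rows when no interval qualifies.
#' @export
call_consensus <- function(placements, reference, min_support = 3L,
                           min_len = 200L) {
  stopifnot(inherits(placements, "read_placements"))
  if (inherits(reference, "sim_reference")) reference <- reference$seq
  depth <- ingest_alignments(placements, reference)
  oriented <- NULL  # reads oriented to the reference, filled lazily
  rows <- list()
  for (contig in names(depth)) {
    d <- depth[[contig]]
    runs <- IRanges::slice(S4Vectors::Rle(d), lower = min_support,
                           rangesOnly = TRUE)
    runs <- runs[IRanges::width(runs) >= min_len]
    if (length(runs) == 0L) next
    h <- placements$hits[placements$hits$chrom == contig, , drop = FALSE]
    refseq <- reference[[match(contig, names(reference))]]
    for (k in seq_along(runs)) {
      S <- IRanges::start(runs)[k]
      E <- IRanges::end(runs)[k]
      len <- E - S + 1L
      cover <- which(h$start <= E & h$end >= S)
      counts <- matrix(0L, 4L, len)  # rows A,C,G,T
      if (is.null(oriented)) {
        oriented <- placements$reads
        neg <- unique(placements$hits$read[placements$hits$strand == "-"])
        if (length(neg))
          oriented[neg] <- Biostrings::reverseComplement(oriented[neg])
        oriented_chr <- as.character(oriented)
      }
      for (i in cover) {
        a <- max(h$start[i], S)
        b <- min(h$end[i], E)
        seg <- substr(oriented_chr[h$read[i]],
                      a - h$start[i] + 1L, b - h$start[i] + 1L)
        base_i <- match(strsplit(seg, "")[[1]], c("A", "C", "G", "T"))
        posoff <- (a:b) - S + 1L
        keep <- !is.na(base_i)
        inc <- tabulate((posoff[keep] - 1L) * 4L + base_i[keep],
                        nbins = 4L * len)
        counts <- counts + matrix(inc, 4L, len)
      }
      refchars <- strsplit(as.character(
        Biostrings::subseq(refseq, S, E)), "")[[1]]
      cons <- character(len)
      bases <- c("A", "C", "G", "T")
      for (p in seq_len(len)) {
        cc <- counts[, p]
        mx <- max(cc)
        leaders <- bases[cc == mx]
        cons[p] <- if (refchars[p] %in% leaders) refchars[p] else
          leaders[1]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = contig, start = S - 1L, end = E,
        support = min(d[S:E]),
        sequence = paste(cons, collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               support = integer(), sequence = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("consensus_fragments", "data.frame")
  out
}

#' Chain consensus fragments into spacer-joined pseudo-scaffolds
#'
#' Fragments on the same contig are merged into chains across an ascending
#' ladder of spacer lengths: at each ladder step, adjacent fragments whose
#' genomic gap does not exceed the step value join the same chain. Because
#' the ladder is ascending, the result is identical to a single pass at
#' the final (largest) spacer; the ladder mirrors the incremental
#' construction and is validated as an invariant. Each final chain is
#' emitted as a pseudo-scaffold whose member sequences are joined by runs
#' of \code{spacer_len} \code{N}s. Chains never cross contigs.
#'
#' @param fragments A \code{\link{call_consensus}}-style data.frame
#'   (columns chrom, start, end, and optionally sequence).
#' @param spacer_ladder Ascending gap thresholds in bp; the last value is
#'   the joining spacer (default \code{c(100, 1000, 10000)}).
#' @param spacer_len Length of the N spacer inserted between members
#'   (default: last ladder value).
#' @param reference Optional \code{DNAStringSet}/\code{sim_reference} used
#'   to fill member sequences when \code{fragments$sequence} is absent.
#' @return Object of class \code{pseudoscaffold_set}: a list of
#'   pseudo-scaffolds, each a list with \code{id}, \code{chrom},
#'   \code{members} (data.frame), \code{spacer_len}, \code{sequence}
#'   (\code{DNAString}) and \code{total_len}.
#' @export
chain_fragments <- function(fragments, spacer_ladder = c(100, 1000, 10000),
                            spacer_len = NULL, reference = NULL) {
  if (is.unsorted(spacer_ladder))
    stop("spacer_ladder must be ascending")
  if (is.null(spacer_len)) spacer_len <- spacer_ladder[length(spacer_ladder)]
  if (inherits(reference, "sim_reference")) reference <- reference$seq
  frags <- as.data.frame(fragments)
  frags <- frags[order(frags$chrom, frags$start), , drop = FALSE]
  if (nrow(frags) > 1L) {
    same <- frags$chrom[-1] == frags$chrom[-nrow(frags)]
    if (any(same & frags$start[-1] < frags$end[-nrow(frags)]))
      stop("fragments overlap; chaining requires disjoint fragments")
  }
  if (is.null(frags$sequence)) {
    if (is.null(reference))
      stop("fragments carry no sequence and no reference was given")
    frags$sequence <- vapply(seq_len(nrow(frags)), function(i) {
      refseq <- reference[[match(frags$chrom[i], names(reference))]]
      as.character(Biostrings::subseq(refseq, frags$start[i] + 1L,
                                      frags$end[i]))
    }, character(1))
  }

  chain_id <- seq_len(nrow(frags))
  for (s in spacer_ladder) {
    if (nrow(frags) > 1L) {
      gap <- frags$start[-1] - frags$end[-nrow(frags)]
      join <- (frags$chrom[-1] == frags$chrom[-nrow(frags)]) & (gap <= s)
      ## propagate chain membership left to right
      for (i in which(join))
        chain_id[chain_id == chain_id[i + 1L]] <- chain_id[i]
    }
  }

  spacer <- strrep("N", spacer_len)
  ids <- unique(chain_id)
  scaffolds <- lapply(seq_along(ids), function(k) {
    members <- frags[chain_id == ids[k], , drop = FALSE]
    rownames(members) <- NULL
    seqchr <- paste(members$sequence, collapse = spacer)
    list(id = sprintf("pseudoscaffold_%03d", k),
         chrom = members$chrom[1],
         members = members,
         spacer_len = spacer_len,
         sequence = Biostrings::DNAString(seqchr),
         total_len = sum(members$end - members$start) +
           spacer_len * (nrow(members) - 1L))
  })
  class(scaffolds) <- "pseudoscaffold_set"
  scaffolds
}

#' @export
print.pseudoscaffold_set <- function(x, ...) {
  cat("pseudoscaffold_set:", length(x), "pseudo-scaffolds;",
      sum(vapply(x, function(s) nrow(s$members), 1L)), "member fragments;",
      "total", sum(vapply(x, function(s) s$total_len, 1)), "bp\n")
  invisible(x)
}

#' Write pseudo-scaffolds as FASTA plus a members BED
#'
#' @param scaffolds A \code{pseudoscaffold_set}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_pseudoscaffolds <- function(scaffolds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(lapply(scaffolds, `[[`, "sequence"))
  names(seqs) <- vapply(scaffolds, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, file.path(dir, "pseudoscaffolds.fa"))
  members <- do.call(rbind, lapply(scaffolds, function(s)
    data.frame(chrom = s$members$chrom, start = s$members$start,
               end = s$members$end, name = s$id,
               stringsAsFactors = FALSE)))
  write_bed(members, file.path(dir, "members.bed"))
  invisible(dir)
}

#' Annotate pseudo-scaffolds with genes, repeats and SNV density
#'
#' All quantities are computed over member (non-spacer) bases only: the
#' spacer \code{N}s never enter a denominator. Gene counts are the number
#' of annotated genes overlapping any member interval; the repeat fraction
#' is the masked share of member bases; SNV density is variants per kb of
#' member sequence.
#'
#' @param scaffolds A \code{pseudoscaffold_set}.
#' @param genes,repeats BED-convention data.frames (NULL for none).
#' @param variants Variant positions: a data.frame with \code{chrom} and
#'   1-based \code{pos} columns, or a VCF file path (only CHROM/POS are
#'   used), or NULL.
#' @return data.frame with one row per pseudo-scaffold plus a final
#'   \code{overall} row: columns id, n_members, member_bp, total_len,
#'   gene_count, repeat_fraction, snv_count, snv_per_kb.
#' @export
annotate_pseudoscaffolds <- function(scaffolds, genes = NULL,
                                     repeats = NULL, variants = NULL) {
  if (is.character(variants)) variants <- read_variant_positions(variants)
  per <- lapply(scaffolds, function(s) {
    m <- s$members
    mir <- IRanges::IRanges(m$start + 1L, m$end)
    member_bp <- sum(IRanges::width(mir))
    gene_count <- 0L
    if (!is.null(genes) && nrow(genes) > 0L) {
      g <- genes[genes$chrom == s$chrom, , drop = FALSE]
      if (nrow(g) > 0L) {
        gir <- IRanges::IRanges(g$start + 1L, g$end)
        gene_count <- sum(IRanges::countOverlaps(gir, mir) > 0L)
      }
    }
    rep_bp <- 0L
    if (!is.null(repeats) && nrow(repeats) > 0L) {
      r <- repeats[repeats$chrom == s$chrom, , drop = FALSE]
      if (nrow(r) > 0L) {
        rir <- IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end))
        rep_bp <- sum(IRanges::width(IRanges::intersect(rir, mir)))
      }
    }
    snv <- 0L
    if (!is.null(variants) && nrow(variants) > 0L) {
      v <- variants[variants$chrom == s$chrom, , drop = FALSE]
      if (nrow(v) > 0L)
        snv <- sum(IRanges::countOverlaps(
          IRanges::IRanges(v$pos, width = 1L), mir) > 0L)
    }
    data.frame(id = s$id, n_members = nrow(m), member_bp = member_bp,
               total_len = s$total_len, gene_count = gene_count,
               repeat_fraction = rep_bp / member_bp, snv_count = snv,
               snv_per_kb = snv / (member_bp / 1000),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  overall <- data.frame(
    id = "overall", n_members = sum(out$n_members),
    member_bp = sum(out$member_bp), total_len = sum(out$total_len),
    gene_count = sum(out$gene_count),
    repeat_fraction = sum(out$repeat_fraction * out$member_bp) /
      sum(out$member_bp),
    snv_count = sum(out$snv_count),
    snv_per_kb = sum(out$snv_count) / (sum(out$member_bp) / 1000),
    stringsAsFactors = FALSE)
  out <- rbind(out, overall)
  rownames(out) <- NULL
  out
}

#' Extract CHROM/POS from a VCF
#'
#' @param path VCF file path.
#' @return data.frame with \code{chrom} and 1-based \code{pos}.
#' @export
read_variant_positions <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             stringsAsFactors = FALSE)
}
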