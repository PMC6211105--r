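#' Plant population-structured fragment copy numbers into a cohort
#'
#' Draws a true diploid copy number for every (individual, B fragment)
#' pair according to the per-population distribution in the configuration,
#' then builds each individual's diploid genome so that read depth carries
#' the planted signal: copy number 2 leaves both haplotypes untouched, 0/1
#' delete the fragment from two/one haplotype(s), and values above 2 insert
#' the corresponding number of extra fragment copies at randomly chosen
#' unmasked, non-control, non-fragment loci (dispersed, not tandem).
#' Control regions are never modified, so their true copy number is 2 in
#' every individual.
#'
#' @param ref A \code{\link{build_reference}} result.
#' @param cfg The \code{\link{sim_config}} used to build it.
#' @param cn_truth Optional matrix (individuals x fragments) of true copy
#'   numbers overriding the configured distributions; dimnames must give
#'   individual and fragment ids.
#' @return An object of class \code{cohort_truth}: a list with
#'   \code{individuals} (data.frame: id, population), \code{cn} (long
#'   data.frame: individual, population, fragment_id, cn_true),
#'   \code{fragment_coords}, \code{control_coords}, \code{mask_coords}
#'   (BED-convention data.frames) and \code{genomes} (a list per
#'   individual of two-haplotype \code{DNAStringSet}s).
#' @export
plant_copy_numbers <- function(ref, cfg, cn_truth = NULL) {
  stopifnot(inherits(ref, "sim_reference"))
  set.seed(.derive_seed(cfg$seed, 2L))
  frag_ids <- ref$fragments$name
  nf <- length(frag_ids)

  individuals <- do.call(rbind, lapply(cfg$populations, function(p)
    data.frame(id = paste0(p$label, "_", sprintf("%02d", seq_len(p$n))),
               population = p$label, stringsAsFactors = FALSE)))

  if (is.null(cn_truth)) {
    cn_truth <- matrix(0, nrow(individuals), nf,
                       dimnames = list(individuals$id, frag_ids))
    r <- 1L
    for (p in cfg$populations) {
      for (j in seq_len(p$n)) {
        cn_truth[r, ] <- if (!is.null(p$cn_values))
          rep(p$cn_values, length.out = nf)
        else
          pmax(0, round(stats::rnorm(nf, p$cn_mean, p$cn_sd)))
        r <- r + 1L
      }
    }
  } else {
    cn_truth <- cn_truth[individuals$id, frag_ids, drop = FALSE]
  }
  if (any(cn_truth < 0)) stop("true copy numbers must be non-negative")

  cn_long <- data.frame(
    individual = rep(individuals$id, each = nf),
    population = rep(individuals$population, each = nf),
    fragment_id = rep(frag_ids, nrow(individuals)),
    cn_true = as.vector(t(cn_truth)),
    stringsAsFactors = FALSE)

  genomes <- vector("list", nrow(individuals))
  names(genomes) <- individuals$id
  for (i in seq_len(nrow(individuals)))
    genomes[[i]] <- .build_individual_genome(ref, cn_truth[i, ])

  out <- list(individuals = individuals,
              cn = cn_long,
              cn_matrix_true = cn_truth,
              fragment_coords = ref$fragments,
              control_coords = ref$controls,
              mask_coords = ref$mask,
              genomes = genomes)
  class(out) <- "cohort_truth"
  out
}

# Assemble one individual's two haplotypes from per-fragment copy numbers.
# Deletions/insertions are expressed in reference coordinates and applied
# in a single left-to-right pass per haplotype.
.build_individual_genome <- function(ref, cn) {
  contig <- names(ref$seq)[1]
  refseq <- ref$seq[[1]]
  G <- length(refseq)
  frag_ir <- IRanges::IRanges(ref$fragments$start + 1L, ref$fragments$end)
  names(frag_ir) <- ref$fragments$name

  # insertion loci pool: free space recorded by build_reference
  ins_ir <- IRanges::IRanges(ref$insertable$start + 1L, ref$insertable$end)
  ins_pos_pool <- unlist(lapply(seq_along(ins_ir), function(k)
    seq(IRanges::start(ins_ir)[k], IRanges::end(ins_ir)[k])))

  del <- list(IRanges::IRanges(), IRanges::IRanges())
  ins <- list(data.frame(pos = integer(), frag = integer()),
              data.frame(pos = integer(), frag = integer()))
  for (j in seq_along(cn)) {
    c_j <- cn[j]
    if (c_j == 2) next
    if (c_j == 0) {
      del[[1]] <- c(del[[1]], frag_ir[j])
      del[[2]] <- c(del[[2]], frag_ir[j])
    } else if (c_j == 1) {
      h <- sample.int(2L, 1L)
      del[[h]] <- c(del[[h]], frag_ir[j])
    } else {
      extra <- round(c_j) - 2L
      for (e in seq_len(extra)) {
        h <- sample.int(2L, 1L)
        p <- ins_pos_pool[sample.int(length(ins_pos_pool), 1L)]
        ins[[h]] <- rbind(ins[[h]], data.frame(pos = p, frag = j))
      }
    }
  }

  haps <- lapply(1:2, function(h) {
    keep <- IRanges::setdiff(IRanges::IRanges(1L, G), del[[h]])
    insh <- ins[[h]][order(ins[[h]]$pos), , drop = FALSE]
    pieces <- list()
    cursor <- 1L
    emit_ref <- function(from, to) {
      if (to >= from) {
        ov <- IRanges::restrict(keep, start = from, end = to)
        for (k in seq_along(ov))
          pieces[[length(pieces) + 1L]] <<-
            Biostrings::subseq(refseq, IRanges::start(ov)[k],
                               IRanges::end(ov)[k])
      }
    }
    for (r in seq_len(nrow(insh))) {
      emit_ref(cursor, insh$pos[r] - 1L)
      fj <- insh$frag[r]
      pieces[[length(pieces) + 1L]] <-
        Biostrings::subseq(refseq, IRanges::start(frag_ir)[fj],
                           IRanges::end(frag_ir)[fj])
      cursor <- insh$pos[r]
    }
    emit_ref(cursor, G)
    hseq <- Biostrings::DNAStringSet(pieces)
    Biostrings::DNAStringSet(unlist(hseq))[[1]]
  })
  out <- Biostrings::DNAStringSet(haps)
  names(out) <- paste0(contig, "_hap", 1:2)
  out
}

#' Simulate GC-biased short reads from an individual genome
#'
#' Reads are sampled with replacement from every possible start position on
#' both haplotypes (the diploid sampling pool), with probability
#' proportional to \code{exp(gc_bias_strength * (gc_read - 0.5) * 2)},
#' normalized over the pool, and assigned a uniform-random strand. The read
#' count is chosen so that the expected depth at an unduplicated, unbiased
#' locus equals \code{coverage}.
#'
#' @param genome A two-haplotype \code{DNAStringSet} (one individual), or
#'   any \code{DNAStringSet} sampling pool.
#' @param cfg A \code{\link{sim_config}} (supplies coverage, read length,
#'   GC bias strength and error rate).
#' @param seed Integer seed for this individual's reads.
#' @return A named \code{DNAStringSet} of reads.
#' @export
simulate_reads <- function(genome, cfg, seed = cfg$seed) {
  if (sum(Biostrings::width(genome)) == 0L) stop("empty genome")
  L <- cfg$read_length
  if (cfg$coverage <= 0) stop("coverage must be > 0")
  if (any(Biostrings::width(genome) < L))
    stop("read_length exceeds a haplotype length")
  set.seed(seed)

  n_starts <- Biostrings::width(genome) - L + 1L
  total_len <- sum(Biostrings::width(genome))
  n_reads <- round(cfg$coverage * total_len / (2 * L))

  w <- vector("list", length(genome))
  for (h in seq_along(genome)) {
    gc <- .gc_indicator(genome[[h]])
    cs <- c(0L, cumsum(gc))
    gc_read <- (cs[(L + 1):length(cs)] - cs[1:n_starts[h]]) / L
    w[[h]] <- exp(cfg$gc_bias_strength * (gc_read - 0.5) * 2)
  }
  w <- unlist(w)
  idx <- sample.int(length(w), n_reads, replace = TRUE, prob = w)

  hap_of <- rep(seq_along(genome), n_starts)
  offs <- c(0L, cumsum(n_starts))
  pos <- idx - offs[hap_of[idx]]

  reads <- vector("list", length(genome))
  for (h in seq_along(genome)) {
    sel <- hap_of[idx] == h
    if (!any(sel)) next
    reads[[h]] <- Biostrings::extractAt(
      genome[[h]], IRanges::IRanges(pos[sel], width = L))
  }
  reads <- do.call(c, Filter(Negate(is.null), reads))
  ## restore sampling order so read ids are independent of haplotype layout
  ord <- order(order(hap_of[idx]))
  reads <- reads[ord]

  flip <- stats::runif(n_reads) < 0.5
  if (any(flip))
    reads[flip] <- Biostrings::reverseComplement(reads[flip])

  if (cfg$error_rate > 0) {
    n_err <- stats::rbinom(1L, n_reads * L, cfg$error_rate)
    if (n_err > 0) {
      at <- sample.int(n_reads * L, n_err)
      ri <- (at - 1L) %/% L + 1L
      pi <- (at - 1L) %% L + 1L
      chars <- as.character(reads)
      for (k in seq_len(n_err)) {
        old <- substr(chars[ri[k]], pi[k], pi[k])
        substr(chars[ri[k]], pi[k], pi[k]) <-
          sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
      reads <- Biostrings::DNAStringSet(chars)
    }
  }
  names(reads) <- sprintf("read_%07d", seq_len(n_reads))
  reads
}

#' Write reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads A \code{DNAStringSet} of reads.
#' @param path Output FASTQ path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#' @param path FASTQ path.
#' @return A \code{DNAStringSet}.
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write or read the cohort truth table
#'
#' Tab-separated with columns individual, population, fragment_id, cn_true.
#'
#' @param truth A \code{cohort_truth} (or its \code{$cn} data.frame).
#' @param path TSV path.
#' @return \code{read_truth} returns the truth data.frame.
#' @export
write_truth <- function(truth, path) {
  df <- if (inherits(truth, "cohort_truth")) truth$cn else truth
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: \code{\link{build_reference}} then
#' \code{\link{plant_copy_numbers}}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param cn_truth Optional copy-number truth override (see
#'   \code{\link{plant_copy_numbers}}).
#' @return A list of class \code{sim_cohort} with \code{config},
#'   \code{reference} and \code{truth}.
#' @export
simulate_cohort <- function(cfg, cn_truth = NULL) {
  ref <- build_reference(cfg)
  truth <- plant_copy_numbers(ref, cfg, cn_truth = cn_truth)
  out <- list(config = cfg, reference = ref, truth = truth)
  class(out) <- "sim_cohort"
  out
}
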