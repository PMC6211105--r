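# brute-force partition oracle: fragments on one contig belong to the
# same chain iff every adjacent gap along the way is <= threshold
oracle_partition <- function(starts, ends, threshold) {
  n <- length(starts)
  id <- seq_len(n)
  for (i in seq_len(n - 1))
    if (starts[i + 1] - ends[i] <= threshold) id[id == id[i + 1]] <- id[i]
  unname(as.integer(factor(id, levels = unique(id))))
}

make_coverage_placements <- function(refchr, blocks, depth_per_block,
                                     read_len = 100L) {
  # place `depth` staggered exact reads over each 1 kb block
  reads <- character(0); starts <- integer(0)
  for (b in seq_along(blocks)) {
    d <- depth_per_block[b]
    if (d == 0) next
    s0 <- blocks[b]
    for (k in seq_len(d)) {
      for (p in seq(s0, s0 + 1000 - read_len, by = read_len)) {
        reads <- c(reads, substr(refchr, p, p + read_len - 1))
        starts <- c(starts, p)
      }
    }
  }
  fake_placements(reads, starts, nchar(refchr))
}

test_that("consensus fragments are maximal runs above the support threshold", {
  refchr <- random_dna(6000, seed = 1)
  # per-kb depth profile 0,3,3,0,3 starting at base 501
  blocks <- c(501, 1501, 2501, 3501, 4501)
  pl <- make_coverage_placements(refchr, blocks, c(0, 3, 3, 0, 3))
  ref <- Biostrings::DNAStringSet(c(ctg1 = refchr))
  fr <- call_consensus(pl, ref, min_support = 3, min_len = 200)
  expect_equal(nrow(fr), 2L)
  expect_equal(fr$start, c(1500L, 4500L))
  expect_equal(fr$end, c(3500L, 5500L))
  expect_true(all(fr$support >= 3))
  # error-free reads reproduce the reference
  expect_equal(fr$sequence[1], substr(refchr, 1501, 3500))

  # uniform depth 5 -> one fragment spanning the covered region
  pl5 <- make_coverage_placements(refchr, blocks, c(5, 5, 5, 5, 5))
  fr5 <- call_consensus(pl5, ref, min_support = 3)
  expect_equal(nrow(fr5), 1L)

  # support above max depth -> empty
  expect_equal(nrow(call_consensus(pl, ref, min_support = 10)), 0L)
})

test_that("consensus takes the read majority, ties go to the reference", {
  refchr <- random_dna(500, seed = 2)
  stopifnot(substr(refchr, 150, 150) != "A")
  mut <- refchr
  substr(mut, 150, 150) <- "A"
  # three reads covering 101-300: two mutated, one reference
  reads <- c(substr(mut, 101, 300), substr(mut, 101, 300),
             substr(refchr, 101, 300))
  pl <- fake_placements(reads, rep(101L, 3), 500L)
  fr <- call_consensus(pl, Biostrings::DNAStringSet(c(ctg1 = refchr)),
                       min_support = 3, min_len = 100)
  expect_equal(substr(fr$sequence, 50, 50), "A")        # majority 2:1

  # 1:1 tie at the site -> reference base wins
  pl_tie <- fake_placements(reads[2:3], rep(101L, 2), 500L)
  fr_tie <- call_consensus(pl_tie,
                           Biostrings::DNAStringSet(c(ctg1 = refchr)),
                           min_support = 2, min_len = 100)
  expect_equal(substr(fr_tie$sequence, 50, 50), substr(refchr, 150, 150))
})

test_that("a single fragment yields one pseudo-scaffold of its own length", {
  fr <- data.frame(chrom = "ctg1", start = 100L, end = 1100L,
                   sequence = random_dna(1000, seed = 3))
  ps <- chain_fragments(fr)
  expect_length(ps, 1L)
  expect_equal(ps[[1]]$total_len, 1000L)
  expect_equal(length(ps[[1]]$sequence), 1000L)
})

test_that("nearby fragments are spacer-joined with the documented length", {
  fr <- data.frame(chrom = "ctg1",
                   start = c(0L, 1500L), end = c(1000L, 2500L),
                   sequence = c(random_dna(1000, seed = 4),
                                random_dna(1000)))
  ps <- chain_fragments(fr, spacer_ladder = c(100, 1000, 10000))
  expect_length(ps, 1L)
  expect_equal(ps[[1]]$total_len, 1000L + 10000L + 1000L)
  expect_equal(length(ps[[1]]$sequence), 12000L)
  # the spacer is a run of N excluded from members
  expect_equal(Biostrings::letterFrequency(ps[[1]]$sequence, "N")[[1]],
               10000L)
})

test_that("chaining matches the brute-force gap partition on random fixtures", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20L
    widths <- sample(200:2000, n, replace = TRUE)
    gaps <- sample(c(50:500, 5000:20000), n, replace = TRUE)
    starts <- cumsum(gaps + c(0L, widths[-n]))
    ends <- starts + widths
    fr <- data.frame(chrom = "ctg1", start = starts, end = ends,
                     sequence = vapply(ends - starts, random_dna, ""))
    ps <- chain_fragments(fr, spacer_ladder = c(100, 1000, 10000))
    oracle <- oracle_partition(starts, ends, 10000L)
    expect_length(ps, length(unique(oracle)))
    sizes_oracle <- sort(as.integer(table(oracle)))
    sizes_chain <- sort(vapply(ps, function(s) nrow(s$members), 1L))
    expect_equal(sizes_chain, sizes_oracle)

    # ladder equivalence: iterative ladder == one-shot final spacer
    ps1 <- chain_fragments(fr, spacer_ladder = 10000)
    expect_equal(vapply(ps, function(s) s$total_len, 1),
                 vapply(ps1, function(s) s$total_len, 1))

    # idempotence: chaining the emitted members changes nothing
    members <- do.call(rbind, lapply(ps, `[[`, "members"))
    ps2 <- chain_fragments(members, spacer_ladder = c(100, 1000, 10000))
    expect_equal(vapply(ps2, function(s) s$total_len, 1),
                 vapply(ps, function(s) s$total_len, 1))
  }
})

test_that("total_len holds against the re-parsed FASTA", {
  set.seed(9)
  starts <- cumsum(sample(2000:5000, 6))
  fr <- data.frame(chrom = "ctg1", start = starts, end = starts + 500L,
                   sequence = vapply(rep(500L, 6), random_dna, ""))
  ps <- chain_fragments(fr, spacer_ladder = c(100, 1000, 10000))
  dir <- withr::local_tempdir()
  write_pseudoscaffolds(ps, dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "pseudoscaffolds.fa"))
  expect_equal(unname(Biostrings::width(fa)),
               vapply(ps, function(s) s$total_len, 1))
  expect_equal(names(fa), vapply(ps, `[[`, "", "id"))
})

test_that("cross-contig chaining is forbidden", {
  fr <- data.frame(chrom = c("ctg1", "ctg2"),
                   start = c(0L, 100L), end = c(1000L, 1100L),
                   sequence = c(random_dna(1000, seed = 5),
                                random_dna(1000)))
  ps <- chain_fragments(fr)
  expect_length(ps, 2L)
})

test_that("annotation computes densities over member bases only", {
  fr <- data.frame(chrom = "ctg1",
                   start = c(0L, 5000L), end = c(1000L, 6000L),
                   sequence = c(random_dna(1000, seed = 6),
                                random_dna(1000)))
  ps <- chain_fragments(fr, spacer_ladder = c(100, 1000, 10000))
  expect_length(ps, 1L)   # gap 4000 <= 10000

  # no annotations at all -> zero counts, density 0
  ann0 <- annotate_pseudoscaffolds(ps)
  expect_equal(ann0$gene_count, c(0L, 0L))
  expect_equal(ann0$snv_per_kb, c(0, 0))

  # one member fully inside a repeat -> member-weighted fraction 0.5
  repeats <- data.frame(chrom = "ctg1", start = 4900L, end = 6100L)
  genes <- data.frame(chrom = "ctg1", start = c(100L, 2000L),
                      end = c(300L, 2500L), name = c("gA", "gB"))
  # 16 SNVs over the 2000 member bp -> 8 per kb; SNVs in the gap are
  # outside members and never counted
  snvs <- data.frame(chrom = "ctg1",
                     pos = c(seq(70L, 910L, by = 60L), 5010L,
                             seq(2000L, 4000L, by = 500L)))
  stopifnot(sum(snvs$pos <= 1000 | snvs$pos > 5000) == 16L)
  ann <- annotate_pseudoscaffolds(ps, genes = genes, repeats = repeats,
                                  variants = snvs)
  ov <- ann[ann$id == "overall", ]
  expect_equal(ov$member_bp, 2000L)
  expect_equal(ov$repeat_fraction, 0.5)
  expect_equal(ov$gene_count, 1L)        # gB sits in the spacer gap
  expect_equal(ov$snv_count, 16L)
  expect_equal(ov$snv_per_kb, 8)
})

test_that("variant positions can come from a VCF file", {
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=ctg1,length=10000>",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           "ctg1\t150\t.\tA\tG\t50\tPASS\t.",
           "ctg1\t900\t.\tC\tT\t50\tPASS\t.")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  v <- read_variant_positions(path)
  expect_equal(v$pos, c(150L, 900L))
  expect_equal(v$chrom, c("ctg1", "ctg1"))
})
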