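test_that("zero repeat fraction yields an empty mask", {
  ref <- build_reference(tiny_config(repeat_fraction = 0))
  expect_equal(nrow(ref$mask), 0L)
})

test_that("reference construction is deterministic and writes identical files", {
  cfg <- tiny_config(seed = 3)
  r1 <- build_reference(cfg)
  r2 <- build_reference(cfg)
  expect_identical(as.character(r1$seq), as.character(r2$seq))
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$fragments, r2$fragments)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_reference(r1, d1)
  write_reference(r2, d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})

test_that("masked fraction matches the configured repeat fraction", {
  cfg <- sim_config(seed = 5, genome_length = 2e6, repeat_fraction = 0.17,
                    populations = list(list(label = "p", n = 1L,
                                            cn_mean = 2, cn_sd = 0)))
  ref <- build_reference(cfg)
  frac <- sum(ref$mask$end - ref$mask$start) / cfg$genome_length
  expect_gte(frac, 0.16)
  expect_lte(frac, 0.18)
})

test_that("fragments, controls and mask are mutually disjoint", {
  ref <- build_reference(tiny_config(seed = 8))
  all_iv <- rbind(ref$fragments[c("chrom", "start", "end")],
                  ref$controls[c("chrom", "start", "end")],
                  ref$mask[c("chrom", "start", "end")])
  ir <- IRanges::IRanges(all_iv$start + 1L, all_iv$end)
  expect_equal(sum(IRanges::width(IRanges::reduce(ir))),
               sum(IRanges::width(ir)))
})

test_that("an unplaceable interval raises a placement error naming it", {
  cfg <- tiny_config(genome_length = 30000)  # control fragment cannot fit
  cfg$control_fragment_length <- 50000L
  expect_error(build_reference(cfg), "control_fragment")
})

test_that("null planting leaves every haplotype identical to the reference", {
  cfg <- tiny_config(populations = list(list(label = "p", n = 2L,
                                             cn_values = 2)))
  co <- simulate_cohort(cfg)
  for (g in co$truth$genomes) {
    expect_length(g, 2L)
    expect_identical(as.character(g[[1]]),
                     as.character(co$reference$seq[[1]]))
    expect_identical(as.character(g[[2]]),
                     as.character(co$reference$seq[[1]]))
  }
})

test_that("planted extra sequence length satisfies conservation", {
  cfg <- tiny_config(seed = 21,
                     b_fragment_length = 2000,
                     populations = list(list(label = "p", n = 3L,
                                             cn_values = c(0, 1, 4, 6))))
  co <- simulate_cohort(cfg)
  flen <- co$reference$fragments$end - co$reference$fragments$start
  for (id in co$truth$individuals$id) {
    cn <- co$truth$cn_matrix_true[id, ]
    expect_equal(sum(Biostrings::width(co$truth$genomes[[id]])),
                 2L * cfg$genome_length + sum((cn - 2) * flen))
  }
  # the planted copy count is physically realized in the genome
  id <- co$truth$individuals$id[1]
  for (i in seq_len(nrow(co$reference$fragments))) {
    fs <- Biostrings::subseq(co$reference$seq[[1]],
                             co$reference$fragments$start[i] + 1L,
                             co$reference$fragments$end[i])
    expect_equal(sum(Biostrings::vcountPattern(fs, co$truth$genomes[[id]])),
                 unname(co$truth$cn_matrix_true[id, i]))
  }
})

test_that("negative planted copy numbers are rejected", {
  cfg <- tiny_config()
  ref <- build_reference(cfg)
  bad <- matrix(-1, 2, cfg$n_b_fragments,
                dimnames = list(paste0("p1_", sprintf("%02d", 1:2)),
                                ref$fragments$name))
  expect_error(plant_copy_numbers(ref, cfg, cn_truth = bad),
               "non-negative")
})

test_that("population variance ordering is realized in the truth table", {
  ok <- 0L
  for (seed in 1:10) {
    cfg <- tiny_config(seed = seed, n_b_fragments = 6L,
                       populations = default_populations())
    ref <- build_reference(cfg)
    truth <- plant_copy_numbers(ref, cfg)
    v <- tapply(truth$cn$cn_true, truth$cn$population, stats::var)
    ok <- ok + (v[["pop1_india"]] > v[["pop2_seasia"]] &&
                  v[["pop2_seasia"]] > v[["pop3_australia"]])
  }
  expect_gte(ok, 9L)
})

test_that("truth table round-trips exactly through TSV", {
  co <- simulate_cohort(tiny_config(seed = 13))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(co$truth, path)
  back <- read_truth(path)
  expect_equal(back, co$truth$cn, ignore_attr = TRUE)
})

test_that("read simulation hits the configured coverage without GC bias", {
  cfg <- tiny_config(seed = 2, genome_length = 100000,
                     gc_bias_strength = 0, coverage = 7)
  ref <- build_reference(cfg)
  genome <- Biostrings::DNAStringSet(c(hap1 = as.character(ref$seq[[1]]),
                                       hap2 = as.character(ref$seq[[1]])))
  reads <- simulate_reads(genome, cfg, seed = 4)
  mean_depth <- length(reads) * cfg$read_length / cfg$genome_length
  expect_gte(mean_depth, 6.5)
  expect_lte(mean_depth, 7.5)
})

test_that("read simulation rejects impossible configurations", {
  cfg <- tiny_config()
  genome <- Biostrings::DNAStringSet(c(h = random_dna(500, seed = 1)))
  cfg0 <- cfg; cfg0$coverage <- 0
  expect_error(simulate_reads(genome, cfg0, seed = 1), "coverage")
  cfgL <- cfg; cfgL$read_length <- 501L
  expect_error(simulate_reads(genome, cfgL, seed = 1), "read_length")
})

test_that("identical seeds give byte-identical FASTQ", {
  cfg <- tiny_config(seed = 2, genome_length = 50000,
                     control_fragment_length = 10000)
  ref <- build_reference(cfg)
  genome <- Biostrings::DNAStringSet(c(hap1 = as.character(ref$seq[[1]]),
                                       hap2 = as.character(ref$seq[[1]])))
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq(simulate_reads(genome, cfg, seed = 9), f1)
  write_fastq(simulate_reads(genome, cfg, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_fastq(f1)
  expect_equal(length(back), length(simulate_reads(genome, cfg, seed = 9)))
})

test_that("configuration JSON round-trips", {
  cfg <- tiny_config(seed = 77)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back, cfg)
})

test_that("invalid configurations are rejected", {
  expect_error(tiny_config(repeat_fraction = 1), "repeat_fraction")
  expect_error(tiny_config(coverage = -1), "coverage")
  expect_error(tiny_config(gc_levels = c(0, 0.5)), "gc_levels")
  expect_error(tiny_config(populations = list(list(label = "p", n = 1L))),
               "cn_mean")
})
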