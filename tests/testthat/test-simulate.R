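test_that("simulated genomes honour GC, topology and the seed", {
  g <- simulate_genome(100000, 0.54, seed = 71)
  expect_equal(g$topology, "circular")
  gc <- sum(strsplit(g$seq, "")[[1]] %in% c("G", "C")) / g$length
  sigma <- sqrt(0.54 * 0.46 / g$length)
  expect_lt(abs(gc - 0.54), 3 * sigma)

  expect_false(grepl("[GC]", simulate_genome(5000, 0, seed = 72)$seq))
  expect_identical(simulate_genome(20000, 0.5, seed = 73)$seq,
                   simulate_genome(20000, 0.5, seed = 73)$seq)
})

test_that("insertion draws respect hard zeros in the weight matrix", {
  g <- simulate_genome(80000, 0.5, seed = 74)
  pwm <- matrix(0.25, 4, 8, dimnames = list(c("A", "C", "G", "T"), 1:8))
  pwm[c("G", "C"), 4] <- 0
  pwm["A", 4] <- 0.5
  pwm["T", 4] <- 0.5
  tr <- simulate_insertions(g, 500, pwm = pwm, seed = 75)
  expect_equal(nrow(tr), 500)
  expect_false(any(substr(tr$octamer, 4, 4) %in% c("G", "C")))
})

test_that("a degenerate one-octamer matrix draws exactly the planted site", {
  target <- "ACGTTCGA"
  set.seed(76)
  # backbone free of the target on either strand
  repeat {
    backbone <- rnd_dna(5000, 0.8)
    if (!grepl(target, backbone) && !grepl(revcomp(target), backbone) &&
        !grepl(target, revcomp(backbone)))
      break
  }
  gseq <- paste0(substr(backbone, 1, 2500), target,
                 substr(backbone, 2501, 5000))
  g <- genome_record("g", gseq, "circular")
  onehot <- vapply(1:8, function(i) {
    p <- setNames(numeric(4), c("A", "C", "G", "T"))
    p[substr(target, i, i)] <- 1
    p
  }, numeric(4))
  tr <- simulate_insertions(g, 1, pwm = onehot, seed = 77)
  expect_equal(tr$pos, 2500)
  expect_equal(tr$orientation, "+")
  expect_equal(tr$octamer, target)
  expect_error(simulate_insertions(g, 3, pwm = onehot, seed = 78),
               "positive target score")
})

test_that("uniform weights give a uniform site distribution", {
  g <- simulate_genome(100000, 0.5, seed = 79)
  uniform <- matrix(0.25, 4, 8, dimnames = list(c("A", "C", "G", "T"), 1:8))
  tr <- simulate_insertions(g, 2000, pwm = uniform, seed = 80)
  bins <- table(cut(tr$pos, breaks = seq(0, 100000, length.out = 51),
                    include.lowest = TRUE))
  expect_gt(stats::chisq.test(as.numeric(bins))$p.value, 0.01)
})

test_that("recorded octamers are re-extractable from the genome", {
  g <- simulate_genome(60000, 0.538, seed = 81)
  tr <- simulate_insertions(g, 150, seed = 82)
  sites <- data.frame(ref_id = g$id, pos = tr$pos,
                      orientation = tr$orientation, read_count = 2L,
                      stringsAsFactors = FALSE)
  expect_equal(extract_octamers(sites[order(sites$pos), ], g),
               tr$octamer[order(tr$pos)], ignore_attr = TRUE)
})

test_that("error-free reads are exact concatenations that close the loop", {
  g <- simulate_genome(30000, 0.5, seed = 83)
  tr <- simulate_insertions(g, 1, seed = 84)
  pl <- simulate_plasmid(seed = 85)
  cfg <- sim_config(error_rate = 0, reads_per_site = 1,
                    fragment_len_mean = 1200, seed = 86)
  reads <- simulate_enrichment_reads(g, pl, tr, cfg)
  expect_equal(nrow(reads), 1)
  seqr <- if (reads$flipped) revcomp(reads$seq) else reads$seq
  prefix <- substr(pl$record$seq, pl$marker$end - 173, pl$marker$end)
  expect_equal(substr(seqr, 1, 174), prefix)
  glen <- nchar(seqr) - 174
  expected_g <- if (tr$orientation == "+")
    seq_window(g$seq, tr$pos, tr$pos + glen, TRUE)
  else revcomp(seq_window(g$seq, tr$pos - glen, tr$pos, TRUE))
  expect_equal(substr(seqr, 175, nchar(seqr)), expected_g)

  aln <- naive_align(reads, list(pl$record, g))
  ev <- call_junctions(aln, pl$marker)
  expect_equal(ev$event_class, "transposition")
  expect_equal(ev$junction_pos, tr$pos)
  expect_equal(ev$orientation, tr$orientation)
})

test_that("single-read sites give the motif stage nothing at min_reads 2", {
  pp <- run_pipeline(genome_len = 40000, n_sites = 20, reads_per_site = 1,
                     error_rate = 0, fragment_len_mean = 1200, seed = 87)
  expect_true(all(pp$sites$read_count == 1))
  oct <- extract_octamers(pp$sites, pp$genome, min_reads = 2)
  expect_length(oct, 0)
})

test_that("simulation output files are byte-identical under one seed", {
  g <- simulate_genome(20000, 0.5, seed = 88)
  tr <- simulate_insertions(g, 10, seed = 89)
  pl <- simulate_plasmid(seed = 90)
  cfg <- sim_config(error_rate = 0.05, reads_per_site = 2,
                    fragment_len_mean = 1500, seed = 91)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  t1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  simulate_enrichment_reads(g, pl, tr, cfg, fastq = f1, truth_tsv = t1)
  simulate_enrichment_reads(g, pl, tr, cfg, fastq = f2, truth_tsv = t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
  back <- read_fastq(f1)
  expect_equal(nrow(back), 20)
})

test_that("the test aligner reports clean blocks and junction splits", {
  g <- simulate_genome(40000, 0.5, seed = 92)
  # plain genomic read
  plain <- data.frame(read_id = "p1",
                      seq = seq_window(g$seq, 5000, 7000, TRUE),
                      stringsAsFactors = FALSE)
  a <- naive_align(plain, g)
  expect_equal(nrow(a), 1)
  expect_equal(a$ref_start, 5000)
  expect_equal(a$ref_end, 7000)
  expect_equal(a$strand, "+")
  expect_equal(a$matches, 2000)

  # junction read: plasmid block + genome block, adjacent in read space
  pl <- simulate_plasmid(seed = 93)
  jread <- data.frame(
    read_id = "j1",
    seq = paste0(substr(pl$record$seq, pl$marker$end - 173, pl$marker$end),
                 seq_window(g$seq, 9000, 10500, TRUE)),
    stringsAsFactors = FALSE)
  aj <- naive_align(jread, list(pl$record, g))
  expect_equal(nrow(aj), 2)
  pb <- aj[aj$ref_id == "plasmid", ]
  gb <- aj[aj$ref_id == g$id, ]
  # blocks may over-run the junction by a few chance-matching bases, but
  # only gaplessly, so projecting the junction through either block is
  # exact
  expect_lte(abs(pb$read_end - 174), 8)
  expect_lte(abs(gb$read_start - 174), 8)
  expect_equal(pb$ref_end - (pb$read_end - 174), pl$marker$end)
  expect_equal(gb$ref_start - (gb$read_start - 174), 9000)

  # random read: no alignment
  set.seed(94)
  rand <- data.frame(read_id = "x", seq = rnd_dna(800),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(naive_align(rand, g)), 0)
})

test_that("reads crossing the origin of a circular genome still map", {
  g <- simulate_genome(30000, 0.5, seed = 95)
  wrap <- data.frame(read_id = "w",
                     seq = seq_window(g$seq, 29500, 30700, TRUE),
                     stringsAsFactors = FALSE)
  a <- naive_align(wrap, g)
  expect_equal(nrow(a), 1)
  expect_equal(a$ref_start, 29500)
  expect_equal(a$ref_end, 30700)
})
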