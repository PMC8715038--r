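# construct alignment rows in the read_alignments() contract
aln_row <- function(read_id, read_len, read_start, read_end, strand,
                    ref_id, ref_len, ref_start, ref_end) {
  data.frame(read_id = read_id, read_len = read_len,
             read_start = read_start, read_end = read_end, strand = strand,
             ref_id = ref_id, ref_len = ref_len, ref_start = ref_start,
             ref_end = ref_end, matches = read_end - read_start,
             block_len = read_end - read_start, mapq = 60L,
             stringsAsFactors = FALSE)
}

marker <- list(ref_id = "plasmid", start = 3900, end = 5148)

test_that("forward junction reads give pos/orientation by construction", {
  # read = 150 bp marker tail + 24 bp IR + genome[5000, 9000), forward
  aln <- rbind(
    aln_row("r1", 4174, 0, 174, "+", "plasmid", 6000, 4974, 5148),
    aln_row("r1", 4174, 174, 4174, "+", "genome", 50000, 5000, 9000))
  ev <- call_junctions(aln, marker)
  expect_equal(ev$event_class, "transposition")
  expect_equal(ev$junction_pos, 5000)
  expect_equal(ev$orientation, "+")
  expect_equal(ev$gap_on_read, 0)
})

test_that("minus-strand and flipped reads give the mirrored junction", {
  # genomic part reverse-complemented: block maps genome [5000, 9000) "-";
  # junction at the high end, pos = ref_end per the strand convention
  aln <- rbind(
    aln_row("r2", 4174, 0, 174, "+", "plasmid", 6000, 4974, 5148),
    aln_row("r2", 4174, 174, 4174, "-", "genome", 50000, 5000, 9000))
  ev <- call_junctions(aln, marker)
  expect_equal(ev$junction_pos, 9000)
  expect_equal(ev$orientation, "-")

  # whole read reverse-complemented by sequencing: marker block on "-",
  # read coordinates flipped; normalisation must recover the same event
  aln_f <- rbind(
    aln_row("r3", 4174, 4000, 4174, "-", "plasmid", 6000, 4974, 5148),
    aln_row("r3", 4174, 0, 4000, "+", "genome", 50000, 5000, 9000))
  ev_f <- call_junctions(aln_f, marker)
  expect_equal(ev_f$junction_pos, 9000)
  expect_equal(ev_f$orientation, "-")
})

test_that("plasmid pass-through beyond the IR is classed as integration", {
  aln <- rbind(
    aln_row("r4", 2000, 0, 374, "+", "plasmid", 6000, 4974, 5348),
    aln_row("r4", 2000, 374, 2000, "+", "genome", 50000, 7000, 8626))
  ev <- call_junctions(aln, marker)
  expect_equal(ev$event_class, "plasmid_integration")
})

test_that("reads without a marker anchor are skipped and counted", {
  aln <- aln_row("r5", 1000, 0, 1000, "+", "genome", 50000, 100, 1100)
  ev <- call_junctions(aln, marker)
  expect_equal(nrow(ev), 0)
  expect_equal(attr(ev, "n_skipped"), 1)
})

test_that("reads with a marker anchor but no adjacent genome block are ambiguous", {
  aln <- rbind(
    aln_row("r6", 4174, 0, 174, "+", "plasmid", 6000, 4974, 5148),
    aln_row("r6", 4174, 2000, 4174, "+", "genome", 50000, 5000, 7174))
  ev <- call_junctions(aln, marker)
  expect_equal(ev$event_class, "ambiguous")
})

test_that("collapse merges by tolerance, keeps strands apart, takes the mode", {
  mk_ev <- function(pos, orientation) {
    data.frame(read_id = paste0("r", seq_along(pos)), ref_id = "genome",
               junction_pos = pos, orientation = orientation,
               gap_on_read = 0L, event_class = "transposition",
               stringsAsFactors = FALSE)
  }
  s1 <- collapse_sites(mk_ev(c(5000, 5000, 5002), "+"))
  expect_equal(nrow(s1), 1)
  expect_equal(s1$pos, 5000)
  expect_equal(s1$read_count, 3)

  s2 <- collapse_sites(mk_ev(c(5000, 5000), c("+", "-")))
  expect_equal(nrow(s2), 2)
  expect_setequal(s2$orientation, c("+", "-"))

  # conservation: read counts sum to the number of transposition events
  set.seed(51)
  pos <- sample(1:100000, 400)
  ev <- mk_ev(rep(pos, each = 2), "+")
  s3 <- collapse_sites(ev)
  expect_equal(sum(s3$read_count), nrow(ev))
})

test_that("simulated sites with two clean reads each are recovered exactly", {
  pp <- run_pipeline(genome_len = 60000, n_sites = 100, reads_per_site = 2,
                     error_rate = 0, fragment_len_mean = 1500, seed = 52)
  expect_equal(nrow(pp$sites), 100)
  expect_equal(sum(pp$sites$read_count), 200)
  got <- pp$sites[order(pp$sites$pos), ]
  want <- pp$truth[order(pp$truth$pos), ]
  expect_equal(got$pos, want$pos)
  expect_equal(got$orientation, want$orientation)
})

test_that("replichore assignment follows the oriC/ter geometry", {
  sites <- data.frame(ref_id = "g", pos = c(25000, 25000, 75000, 75000),
                      orientation = c("+", "-", "+", "-"),
                      read_count = 2L, stringsAsFactors = FALSE)
  out <- assign_replichore(sites, oric_pos = 0, ter_pos = 50000,
                           genome_len = 100000)
  expect_equal(out$replichore_strand,
               c("leading", "lagging", "lagging", "leading"))
  expect_error(assign_replichore(sites, 100, 100, 100000), "coincide")

  # oriC > ter (origin-crossing replichore 1)
  out2 <- assign_replichore(sites, oric_pos = 90000, ter_pos = 40000,
                            genome_len = 100000)
  expect_equal(out2$replichore_strand[1], "leading")
  expect_equal(out2$replichore_strand[3], "lagging")
})

test_that("unbiased simulations split evenly between leading and lagging", {
  g <- simulate_genome(200000, 0.5, seed = 53)
  uniform_pwm <- matrix(0.25, 4, 8, dimnames = list(c("A", "C", "G", "T"),
                                                    1:8))
  tr <- simulate_insertions(g, 1000, pwm = uniform_pwm, seed = 54)
  sites <- data.frame(ref_id = "simchr", pos = tr$pos,
                      orientation = tr$orientation, read_count = 2L,
                      stringsAsFactors = FALSE)
  out <- assign_replichore(sites, 0, 100000, 200000)
  n_lead <- sum(out$replichore_strand == "leading")
  sigma <- sqrt(1000 * 0.25)
  expect_lt(abs(n_lead - 500), 3 * sigma)
})

test_that("positional summaries conserve counts and render a plot", {
  sites <- data.frame(ref_id = "g", pos = c(rep(0, 4), 25000, 99000),
                      orientation = "+", read_count = 2L,
                      stringsAsFactors = FALSE)
  s1 <- positional_summary(sites, 100000, 1)
  expect_equal(s1$total, 6)

  s2 <- positional_summary(sites[sites$pos == 0, ], 100000, 360)
  expect_equal(sum(s2$total > 0), 1)
  expect_equal(sum(s2$total), 4)

  expect_error(positional_summary(sites, 100000, 0), "n_bins")

  plot_file <- withr::local_tempfile(fileext = ".png")
  sites2 <- assign_replichore(sites, 0, 50000, 100000)
  positional_summary(sites2, 100000, 36, plot_file = plot_file)
  expect_true(file.exists(plot_file))
  expect_gt(file.size(plot_file), 0)
})

test_that("uniformly drawn sites look uniform across bins", {
  set.seed(55)
  sites <- data.frame(ref_id = "g", pos = sample(0:999999, 3000),
                      orientation = "+", read_count = 2L,
                      stringsAsFactors = FALSE)
  sm <- positional_summary(sites, 1000000, 50)
  expect_equal(sum(sm$total), 3000)
  p <- stats::chisq.test(sm$total)$p.value
  expect_gt(p, 0.01)
})
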