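ds_composition <- function(seq) {
  tab <- table(factor(strsplit(seq, "")[[1]], levels = c("A", "C", "G", "T")))
  c(AT = unname(tab["A"] + tab["T"]), GC = unname(tab["C"] + tab["G"]))
}

test_that("att_site computes the central dinucleotide and crossover", {
  s <- att_site("attB", 100, 148, paste0(strrep("A", 23), "GT",
                                         strrep("C", 23)), "+")
  expect_equal(s$central_dinucleotide, "GT")
  expect_equal(s$cut, 124)
  expect_error(att_site("attB", 0, 7, "ACGTACG", "+"), "even length")
})

test_that("the switch inverts the promoter and forms attL/attR", {
  sw <- make_switch_construct(seed = 41)
  res <- apply_switch(sw$construct, sw$attB, sw$attP,
                      promoter = sw$promoter)
  expect_equal(res$product$length, sw$construct$length)
  expect_equal(res$state$state, "ON")
  expect_equal(res$state$promoter_strand, "flipped")
  expect_equal(res$state$attL$kind, "attL")
  expect_equal(res$state$attR$kind, "attR")
  # hybrid structure: attL = attB left half + attP-derived right half
  len <- sw$attB$end - sw$attB$start
  expect_equal(substr(res$state$attL$seq, 1, len / 2),
               substr(sw$attB$seq, 1, len / 2))
  expect_equal(substr(res$state$attL$seq, len / 2 + 1, len),
               substr(sw$attP$seq, len / 2 + 1, len))
  # the promoter segment is reverse-complemented in place
  expect_equal(substr(res$product$seq, sw$promoter[1] + 1, sw$promoter[2]),
               revcomp(substr(sw$construct$seq, res$state$promoter[1] + 1,
                              res$state$promoter[2])))
})

test_that("switching conserves length and duplex base composition", {
  for (seed in 42:44) {
    sw <- make_switch_construct(seed = seed)
    res <- apply_switch(sw$construct, sw$attB, sw$attP)
    expect_equal(res$product$length, sw$construct$length)
    expect_equal(ds_composition(res$product$seq),
                 ds_composition(sw$construct$seq))
  }
})

test_that("the switch is unidirectional and validates its substrates", {
  sw <- make_switch_construct(seed = 45)
  res <- apply_switch(sw$construct, sw$attB, sw$attP)
  expect_error(apply_switch(res$product, sw$attB, sw$attP),
               "no attB/attP substrate")
  # attL/attR are never substrates
  expect_error(apply_switch(res$product, res$state$attL, res$state$attR),
               "no attB/attP substrate")
  # missing attP
  expect_error(apply_switch(sw$construct, sw$attB, NULL), "both attB and attP")
  # direct orientation is excision geometry, not modelled
  direct_p <- att_site("attP", sw$attP$start, sw$attP$end,
                       substr(sw$construct$seq, sw$attP$start + 1,
                              sw$attP$end), "+")
  expect_error(apply_switch(sw$construct, sw$attB, direct_p),
               "direct orientation")
})

test_that("plasmid integration conserves length and brackets with attL/attR", {
  att <- make_att_pair(seed = 46)
  set.seed(46)
  gseq <- rnd_dna(10000)
  gseq <- paste0(substr(gseq, 1, 5000), att$attB, substr(gseq, 5049, 10000))
  genome <- genome_record("gen", gseq, "circular")
  pseq <- rnd_dna(4000)
  pseq <- paste0(substr(pseq, 1, 2000), att$attP, substr(pseq, 2049, 4000))
  plasmid <- genome_record("plas", pseq, "circular")
  gb <- att_site("attB", 5000, 5048, att$attB, "+")
  pp <- att_site("attP", 2000, 2048, att$attP, "+")
  res <- integrate_plasmid(genome, gb, plasmid, pp)
  expect_equal(res$product$length, genome$length + plasmid$length)
  expect_equal(res$attL$kind, "attL")
  expect_equal(res$attR$kind, "attR")
  # attB consumed: re-running on the product errors
  expect_error(integrate_plasmid(res$product, gb, plasmid, pp),
               "no intact attB")
  # genome without the site
  expect_error(integrate_plasmid(genome_record("g0", rnd_dna(9000),
                                               "circular"),
                                 gb, plasmid, pp), "attB")
  lin <- genome_record("pl", pseq, "linear")
  expect_error(integrate_plasmid(genome, gb, lin, pp), "circular")
})

test_that("scan_attB scores sites by weighted positional identity", {
  att <- make_att_pair(seed = 47)
  set.seed(47)
  gseq <- rnd_dna(20000)
  gseq <- paste0(substr(gseq, 1, 8000), att$attB, substr(gseq, 8049, 20000))
  genome <- genome_record("g", gseq, "circular")
  w <- rep(1, 48)
  hits <- scan_attB(genome, att$attB, w, min_score = 40)
  expect_equal(hits$start[1], 8000)
  expect_equal(hits$score[1], 48)
  expect_equal(hits$strand[1], "+")
  expect_true(hits$central_match[1])

  # reverse-complemented planting: same score, minus strand
  g2 <- genome_record("g2", paste0(substr(gseq, 1, 14000),
                                   revcomp(att$attB),
                                   substr(gseq, 14001, 20000)), "linear")
  hits2 <- scan_attB(g2, att$attB, w, min_score = 48)
  expect_true(any(hits2$strand == "-" & hits2$start == 14000 &
                    hits2$score == 48))

  expect_error(scan_attB(genome, att$attB, rep(1, 10), 1), "length")
})

test_that("mismatches at zero-weight positions keep the maximal score", {
  att <- make_att_pair(seed = 48)
  set.seed(48)
  w <- runif(48)
  zero_pos <- c(3, 9, 20, 33, 41)
  w[zero_pos] <- 0
  mutated <- substitute_at(att$attB, zero_pos)
  gseq <- paste0(rnd_dna(5000), mutated, rnd_dna(5000))
  genome <- genome_record("g", gseq, "linear")
  hits <- scan_attB(genome, att$attB, w, min_score = 0)
  # oracle: exhaustive per-position weighted sum at the planted locus
  gch <- strsplit(gseq, "")[[1]]
  sch <- strsplit(att$attB, "")[[1]]
  expected <- sum(w * (gch[5001:5048] == sch))
  expect_equal(expected, sum(w) - sum(w[zero_pos]))
  top <- hits[hits$strand == "+", ][1, ]
  expect_equal(top$start, 5000)
  expect_equal(top$score, expected)
  expect_equal(top$score, sum(w))
})

test_that("scanning a genome and its reverse complement mirrors the hits", {
  att <- make_att_pair(seed = 49)
  set.seed(49)
  gseq <- paste0(rnd_dna(3000), att$attB, rnd_dna(3000))
  g1 <- genome_record("g", gseq, "linear")
  g2 <- genome_record("g", revcomp(gseq), "linear")
  w <- rep(1, 48)
  h1 <- scan_attB(g1, att$attB, w, min_score = 30)
  h2 <- scan_attB(g2, att$attB, w, min_score = 30)
  L <- nchar(gseq)
  expect_equal(nrow(h1), nrow(h2))
  key1 <- sort(paste(h1$start, h1$strand, h1$score))
  key2 <- sort(paste(L - h2$end, ifelse(h2$strand == "+", "-", "+"),
                     h2$score))
  expect_equal(key1, key2)
})
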