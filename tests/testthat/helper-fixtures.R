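# Shared fixture builders; everything is generated in code under fixed
# seeds.

rnd_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# substitute bases at the given 1-based positions (deterministic change)
substitute_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# a target genome with one planted IS element, plus the IS-free original
make_healing_pair <- function(genome_len = 40000, is_len = 1311,
                              is_pos = 20000, seed = 1) {
  set.seed(seed)
  base <- rnd_dna(genome_len, 0.54)
  is_seq <- rnd_dna(is_len, 0.6)
  target <- genome_record(
    "target",
    paste0(substr(base, 1, is_pos), is_seq,
           substr(base, is_pos + 1, genome_len)),
    "circular")
  list(target = target, clean = base, is_seq = is_seq,
       ann = is_annotation("IStoy", is_pos, is_pos + is_len))
}

# toy attB/attP pair (even length, GT central dinucleotide)
make_att_pair <- function(len = 48, seed = 5) {
  set.seed(seed)
  mk <- function() {
    s <- strsplit(rnd_dna(len), "")[[1]]
    s[len / 2] <- "G"; s[len / 2 + 1] <- "T"
    paste(s, collapse = "")
  }
  list(attB = mk(), attP = mk())
}

# an inverted-orientation switch construct around the att pair
make_switch_construct <- function(att = make_att_pair(), seed = 6) {
  set.seed(seed)
  left <- rnd_dna(120)
  sp1 <- rnd_dna(40)
  prom <- rnd_dna(30)
  sp2 <- rnd_dna(40)
  right <- rnd_dna(120)
  len <- nchar(att$attB)
  seqc <- paste0(left, att$attB, sp1, isforge::revcomp(prom), sp2,
                 isforge::revcomp(att$attP), right)
  b_start <- nchar(left)
  p_start <- b_start + len + nchar(sp1) + nchar(prom) + nchar(sp2)
  list(construct = genome_record("switch", seqc, "linear"),
       attB = att_site("attB", b_start, b_start + len, att$attB, "+"),
       attP = att_site("attP", p_start, p_start + len, att$attP, "-"),
       promoter = c(b_start + len + nchar(sp1),
                    b_start + len + nchar(sp1) + nchar(prom)))
}

# run the full simulated pipeline: genome -> insertions -> reads ->
# alignments -> junction events -> sites
run_pipeline <- function(genome_len = 100000, n_sites = 100,
                         reads_per_site = 3, error_rate = 0.05,
                         fragment_len_mean = 10000, gc = 0.538,
                         pwm = default_target_pwm(), seed = 1, k = 15) {
  g <- simulate_genome(genome_len, gc, seed = seed)
  tr <- simulate_insertions(g, n_sites, pwm = pwm, seed = seed + 1)
  pl <- simulate_plasmid(seed = seed + 2)
  cfg <- sim_config(error_rate = error_rate,
                    reads_per_site = reads_per_site,
                    fragment_len_mean = fragment_len_mean, seed = seed + 3)
  reads <- simulate_enrichment_reads(g, pl, tr, cfg)
  aln <- naive_align(reads, list(pl$record, g), k = k)
  events <- call_junctions(aln, pl$marker)
  sites <- collapse_sites(events)
  list(genome = g, truth = tr, plasmid = pl, reads = reads, aln = aln,
       events = events, sites = sites)
}

# site-level recovery against truth (match = same strand within tol)
recovery_stats <- function(sites, truth, tol = 3) {
  matched <- logical(nrow(truth))
  site_hit <- logical(nrow(sites))
  for (i in seq_len(nrow(truth))) {
    d <- abs(sites$pos - truth$pos[i]) <= tol &
      sites$orientation == truth$orientation[i]
    if (any(d)) {
      matched[i] <- TRUE
      site_hit[which(d)[1]] <- TRUE
    }
  }
  list(recall = mean(matched), precision = mean(site_hit),
       n_sites = nrow(sites))
}
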