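# Synthetic-data generator emulating the structure of an IS-element
# random-mutagenesis experiment read out by long-read sequencing of
# marker-anchored enrichment libraries: a circular genome, PWM-biased
# insertion positions with an 8-bp target-site duplication, ~10-kb
# fragmentation, and half-nested enrichment reads (150-bp marker tail +
# 24-bp inverted repeat + downstream genomic sequence) under a configurable
# substitution/indel error process. Everything is deterministic under a
# fixed seed. A small seeded aligner closes the loop for tests; it is a
# test utility, not a production long-read aligner.

#' Default target-site preference matrix
#'
#' A 4 x 8 column-stochastic matrix emulating the empirically observed
#' IS*Cg1*-type preference: T-biased positions 3-4, A-biased positions
#' 5-6, strong discrimination against G/C at positions 4-5, and a slight
#' G/C tendency at the outer positions.
#'
#' @return Numeric 4 x 8 matrix, rows `A,C,G,T`, columns summing to 1.
#' @export
default_target_pwm <- function() {
  outer_col <- c(A = 0.20, C = 0.30, G = 0.30, T = 0.20)
  pwm <- cbind(outer_col, outer_col,
               c(0.15, 0.10, 0.10, 0.65),   # pos 3: T-biased
               c(0.25, 0.025, 0.025, 0.70), # pos 4: T, G/C suppressed
               c(0.70, 0.025, 0.025, 0.25), # pos 5: A, G/C suppressed
               c(0.65, 0.10, 0.10, 0.15),   # pos 6: A-biased
               outer_col, outer_col)
  dimnames(pwm) <- list(DNA_BASES, 1:8)
  pwm
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a chromosome-scale
#' *C. glutamicum* mutagenesis library; tests and examples pass smaller
#' sizes explicitly.
#'
#' @param genome_len Genome length in bp (default 3,034,563, a
#'   *C. glutamicum* chassis chromosome).
#' @param gc GC fraction (default 0.538).
#' @param n_insertions Number of independent insertions (default 3,207).
#' @param pwm Target-site weight matrix (default [default_target_pwm()]).
#' @param tsd_len Target-site duplication / analysis window length
#'   (default 8).
#' @param fragment_len_mean Mean fragment (hence read) length in bp
#'   (default 10,000).
#' @param fragment_sdlog Log-normal sdlog for fragment lengths (default
#'   0.49, spanning roughly 4-20 kb between the 5th and 95th percentile).
#' @param reads_per_site Reads per insertion site: a single integer or a
#'   `function(n)` returning `n` counts.
#' @param error_rate Total per-base error rate in `[0, 0.2]`
#'   (substitution:insertion:deletion = 2:1:1).
#' @param marker_tail Marker bases upstream of the IR in each read
#'   (default 150, the nested-primer offset).
#' @param seed Integer seed fixing every downstream draw.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(genome_len = 3034563, gc = 0.538,
                       n_insertions = 3207, pwm = default_target_pwm(),
                       tsd_len = 8, fragment_len_mean = 10000,
                       fragment_sdlog = 0.49, reads_per_site = 3,
                       error_rate = 0.05, marker_tail = 150, seed = 1) {
  stopifnot(genome_len >= 1000, gc >= 0, gc <= 1,
            error_rate >= 0, error_rate <= 0.2)
  if (any(abs(colSums(pwm) - 1) > 1e-6)) stop("pwm columns must sum to 1")
  structure(list(genome_len = genome_len, gc = gc,
                 n_insertions = n_insertions, pwm = pwm, tsd_len = tsd_len,
                 fragment_len_mean = fragment_len_mean,
                 fragment_sdlog = fragment_sdlog,
                 reads_per_site = reads_per_site, error_rate = error_rate,
                 marker_tail = marker_tail, seed = seed),
            class = "sim_config")
}

#' Simulate a circular genome
#'
#' @param length Genome length.
#' @param gc GC fraction; bases are i.i.d.
#' @param seed Integer seed.
#' @param id Sequence name.
#' @return A circular [genome_record()].
#' @export
simulate_genome <- function(length, gc = 0.538, seed = 1, id = "simchr") {
  set.seed(seed)
  genome_record(id, random_dna(length, gc), "circular")
}

#' Simulate a transposon delivery plasmid
#'
#' Layout: backbone, transposase gene region, transposable element
#' (left IR, kanamycin-marker cassette, right IR), backbone. The right
#' IR's outer edge is where enrichment reads cross into genomic DNA.
#'
#' @param seed Integer seed.
#' @param backbone_len,tnp_len,marker_len Segment lengths.
#' @param ir_len Terminal inverted repeat length (default 24).
#' @param gc GC fraction of the simulated plasmid.
#' @return List: `record` (circular [genome_record()]), `marker`
#'   (interval `ref_id`,`start`,`end` with `end` = IR outer edge),
#'   `ir_seq`, `transposon` (interval of IR+marker+IR).
#' @export
simulate_plasmid <- function(seed = 1, backbone_len = 2700, tnp_len = 1200,
                             marker_len = 1200, ir_len = 24, gc = 0.5) {
  set.seed(seed + 101)
  ir <- random_dna(ir_len, gc)
  backbone_a <- random_dna(backbone_len, gc)
  tnp <- random_dna(tnp_len, gc)
  marker <- random_dna(marker_len, gc)
  backbone_b <- random_dna(1500, gc)
  seq <- paste0(backbone_a, tnp, revcomp(ir), marker, ir, backbone_b)
  tn_start <- backbone_len + tnp_len
  ir_r_end <- tn_start + ir_len + marker_len + ir_len
  rec <- genome_record("plasmid", seq, "circular")
  list(record = rec,
       marker = list(ref_id = "plasmid", start = tn_start + ir_len,
                     end = ir_r_end),
       ir_seq = ir,
       transposon = list(start = tn_start, end = ir_r_end))
}

# per-position insertion scores for one strand; idx is the genome as
# integers 1..4, pwm a 4 x w matrix. Returns a length-L numeric vector of
# products of pwm weights over the window in the junction convention.
pwm_position_scores <- function(idx, pwm, strand) {
  L <- length(idx)
  w <- ncol(pwm)
  score <- rep(1, L)
  comp <- c(4L, 3L, 2L, 1L) # A<->T, C<->G
  p0 <- 0:(L - 1)
  for (i in seq_len(w)) {
    if (strand == "+") {
      b <- idx[((p0 + i - 1) %% L) + 1]
    } else {
      b <- comp[idx[((p0 - i) %% L) + 1]]
    }
    score <- score * pwm[cbind(b, i)]
  }
  score
}

#' Draw PWM-biased insertion positions with target-site duplication
#'
#' Every genomic position and strand is scored as the product of PWM
#' weights over its target window (the window that is duplicated on
#' insertion); `n` sites are drawn without replacement proportional to
#' score, orientations uniform via the strand choice; sites closer than
#' `min_dist` on the same strand are rejected so positions stay distinct
#' after tolerance merging.
#'
#' @param genome Circular [genome_record()].
#' @param n Number of insertions.
#' @param pwm 4 x `tsd_len` column-stochastic matrix (rows `A,C,G,T`).
#' @param tsd_len Duplicated window length (default 8).
#' @param seed Integer seed.
#' @param min_dist Minimum same-strand distance between drawn sites
#'   (default 4, i.e. distinct under a 3-bp merge tolerance).
#' @return Data frame `pos, orientation, octamer` (the truth set); the
#'   octamer is the duplicated target in the strand-specific junction
#'   convention.
#' @export
simulate_insertions <- function(genome, n, pwm = default_target_pwm(),
                                tsd_len = 8, seed = 1, min_dist = 4) {
  stopifnot(ncol(pwm) == tsd_len)
  if (any(abs(colSums(pwm) - 1) > 1e-6)) stop("pwm columns must sum to 1")
  set.seed(seed + 202)
  L <- genome$length
  idx <- match(strsplit(genome$seq, "")[[1]], DNA_BASES)
  score <- c(pwm_position_scores(idx, pwm, "+"),
             pwm_position_scores(idx, pwm, "-"))
  n_positive <- sum(score > 0)
  if (n > n_positive)
    stop("requested ", n, " insertions but only ", n_positive,
         " positions have positive target score")
  occupied <- matrix(FALSE, nrow = L, ncol = 2)
  pos <- integer(n); strand <- integer(n)
  got <- 0L
  guard <- 0L
  while (got < n) {
    guard <- guard + 1L
    if (guard > 200L) stop("could not place all insertions (genome too ",
                           "dense for min_dist?)")
    draw <- sample.int(2L * L, size = max(2L * (n - got), 100L),
                       replace = TRUE, prob = score)
    for (d in draw) {
      if (got >= n) break
      s <- if (d <= L) 1L else 2L
      p <- if (d <= L) d else d - L # 1-based position
      win <- ((p - min_dist):(p + min_dist) - 1L) %% L + 1L
      if (any(occupied[win, s])) next
      occupied[p, s] <- TRUE
      got <- got + 1L
      pos[got] <- p - 1L # back to 0-based
      strand[got] <- s
    }
  }
  orientation <- c("+", "-")[strand]
  octamer <- vapply(seq_len(n), function(i) {
    if (orientation[i] == "+")
      seq_window(genome$seq, pos[i], pos[i] + tsd_len, TRUE)
    else
      revcomp(seq_window(genome$seq, pos[i] - tsd_len, pos[i], TRUE))
  }, "")
  out <- data.frame(pos = pos, orientation = orientation,
                    octamer = octamer, stringsAsFactors = FALSE)
  out[order(out$pos, out$orientation), , drop = FALSE]
}

# substitution:insertion:deletion = 2:1:1 at the given total rate
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hit <- runif(n) < rate
  if (!any(hit)) return(seq)
  type <- sample(c("sub", "ins", "del"), sum(hit), replace = TRUE,
                 prob = c(2, 1, 1))
  pieces <- chars
  w <- which(hit)
  for (k in seq_along(w)) {
    i <- w[k]
    if (type[k] == "sub") {
      pieces[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
    } else if (type[k] == "del") {
      pieces[i] <- ""
    } else {
      pieces[i] <- paste0(chars[i], sample(DNA_BASES, 1))
    }
  }
  paste(pieces, collapse = "")
}

#' Simulate marker-anchored enrichment reads
#'
#' Each read is `marker_tail` bp of marker + the IR + genomic sequence
#' from the junction outward (strand-specific), truncated by a log-normal
#' fragment-length draw; substitutions and indels are applied at the
#' configured rate, and each read is reverse-complemented with
#' probability 1/2 (sequencing strand). FASTQ qualities are constant.
#'
#' @param genome Circular [genome_record()].
#' @param plasmid A list from [simulate_plasmid()].
#' @param truth Truth set from [simulate_insertions()].
#' @param config A [sim_config()] (fields `reads_per_site`, `error_rate`,
#'   `fragment_len_mean`, `fragment_sdlog`, `marker_tail`, `seed` are
#'   used).
#' @param fastq,truth_tsv Optional output paths (FASTQ and the truth
#'   sidecar table).
#' @return Data frame `read_id, seq, true_pos, orientation, flipped`.
#' @export
simulate_enrichment_reads <- function(genome, plasmid, truth,
                                      config = sim_config(),
                                      fastq = NULL, truth_tsv = NULL) {
  set.seed(config$seed + 303)
  # prefix: marker tail plus the right IR, ending at the IR outer edge
  ir_len <- nchar(plasmid$ir_seq)
  prefix_len <- config$marker_tail + ir_len
  prefix <- substr(plasmid$record$seq, plasmid$marker$end - prefix_len + 1,
                   plasmid$marker$end)
  nsite <- nrow(truth)
  counts <- if (is.function(config$reads_per_site))
    config$reads_per_site(nsite) else rep(config$reads_per_site, nsite)
  rows <- vector("list", sum(counts))
  ridx <- 0L
  L <- genome$length
  for (i in seq_len(nsite)) {
    for (r in seq_len(counts[i])) {
      ridx <- ridx + 1L
      frag <- round(rlnorm(1, log(config$fragment_len_mean) -
                             config$fragment_sdlog^2 / 2,
                           config$fragment_sdlog))
      glen <- max(50L, min(as.integer(frag) - prefix_len, L - 10L))
      p <- truth$pos[i]
      gpart <- if (truth$orientation[i] == "+")
        seq_window(genome$seq, p, p + glen, TRUE)
      else
        revcomp(seq_window(genome$seq, p - glen, p, TRUE))
      read <- paste0(prefix, gpart)
      read <- mutate_seq(read, config$error_rate)
      flipped <- runif(1) < 0.5
      if (flipped) read <- revcomp(read)
      rows[[ridx]] <- data.frame(
        read_id = sprintf("read%05d_site%04d", ridx, i), seq = read,
        true_pos = p, orientation = truth$orientation[i],
        flipped = flipped, stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, rows)
  if (!is.null(fastq)) write_fastq(reads, fastq)
  if (!is.null(truth_tsv))
    write_tsv(reads[, c("read_id", "true_pos", "orientation", "flipped")],
              truth_tsv)
  reads
}

#' Write simulated reads as FASTQ (constant qualities)
#'
#' @param reads Data frame with `read_id` and `seq`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- reads$read_id
  quals <- Biostrings::BStringSet(vapply(nchar(reads$seq), function(n)
    strrep("I", n), ""))
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file.
#' @return Data frame with `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(set)),
             seq = as.character(set), stringsAsFactors = FALSE)
}

#' Seeded test aligner for simulated reads
#'
#' Exact k-mer seeding, co-linear seed chaining with banded alignment of
#' the inter-seed segments, and exact-match terminal extension, on both
#' strands against each reference, emitting records in the
#' [read_alignments()] PAF contract (read coordinates on the original
#' read strand). Circular references are handled by indexing the doubled
#' sequence, so blocks may cross the origin (`ref_end` can exceed the
#' reference length; downstream code normalises modulo length). This is a
#' closed-loop test utility, not a production long-read aligner.
#'
#' @param reads Data frame with `read_id`, `seq` (or named character
#'   vector).
#' @param references List of [genome_record()]s.
#' @param k Seed length (default 15).
#' @param band Extension band half-width (default 50).
#' @param min_score Minimum alignment score to report (default 40).
#' @param scoring From [aln_scoring()].
#' @return Alignment table (see [read_alignments()]).
#' @export
naive_align <- function(reads, references, k = 15, band = 50,
                        min_score = 40, scoring = aln_scoring()) {
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads), seq = unname(reads),
                        stringsAsFactors = FALSE)
  if (inherits(references, "genome_record")) references <- list(references)
  fwd <- toupper(reads$seq)
  rc <- revcomp(fwd)
  out <- list()
  for (ref in references) {
    L <- ref$length
    target <- if (is_circular(ref)) paste0(ref$seq, ref$seq) else ref$seq
    for (strand in c("+", "-")) {
      queries <- if (strand == "+") fwd else rc
      seed_list <- cpp_find_seeds_batch(queries, target, as.integer(k))
      for (ri in seq_along(queries)) {
        seeds <- seed_list[[ri]]
        if (nrow(seeds) == 0) next
        if (is_circular(ref)) seeds <- seeds[seeds[, 2] < L, , drop = FALSE]
        if (nrow(seeds) == 0) next
        q <- queries[ri]
        rlen <- nchar(q)
        for (cl in seed_clusters(seeds, band)) {
          a <- cpp_chain_extend(q, target, cl$qpos, cl$rpos, as.integer(k),
                                as.integer(band), scoring$match,
                                scoring$mismatch, scoring$gap_open,
                                scoring$gap_ext)
          if (!a$found || a$score < min_score) next
          rs <- a$q_start; re <- a$q_end
          if (strand == "-") { rs <- rlen - a$q_end; re <- rlen - a$q_start }
          out[[length(out) + 1L]] <- data.frame(
            read_id = reads$read_id[ri], read_len = rlen, read_start = rs,
            read_end = re, strand = strand, ref_id = ref$id, ref_len = L,
            ref_start = a$r_start, ref_end = a$r_end, matches = a$matches,
            block_len = a$block_len, mapq = 60L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) return(empty_alignments())
  aln <- do.call(rbind, out)
  prune_overlaps(aln)
}

# greedy per-read pruning: drop alignments whose read interval overlaps a
# higher-scoring kept alignment by more than half of their own span
prune_overlaps <- function(aln) {
  keep <- logical(nrow(aln))
  for (ids in split(seq_len(nrow(aln)), aln$read_id)) {
    ids <- ids[order(-aln$matches[ids])]
    kept <- integer(0)
    for (i in ids) {
      s <- aln$read_start[i]; e <- aln$read_end[i]
      ov <- FALSE
      for (j in kept) {
        o <- min(e, aln$read_end[j]) - max(s, aln$read_start[j])
        if (o > 0.5 * (e - s)) { ov <- TRUE; break }
      }
      if (!ov) { keep[i] <- TRUE; kept <- c(kept, i) }
    }
  }
  res <- aln[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}
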