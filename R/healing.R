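# "Genome healing": restore the ancestral, IS-free allele at an
# IS-disrupted locus by importing the syntenous region from a related donor
# genome. The procedure: search donors for the element's two 2,500-bp
# flanks, require a syntenous hit pair without the element in between,
# gate on >99% identity over the 750-bp windows abutting the healed
# junction, rank donors by combined identity, and emit a deletion
# construct with 500-600 bp homology arms amplifiable from the best donor.

#' Annotate an IS element on a target genome
#'
#' @param name Element name (e.g. `"ISCg1a"`).
#' @param start,end 0-based half-open locus on the target genome.
#' @param family IS family name.
#' @param ir_left,ir_right The two 24-bp imperfect terminal inverted
#'   repeats (optional, `NA` if not tracked).
#' @param max_ir_mismatch Maximum mismatches tolerated between `ir_left`
#'   and the reverse complement of `ir_right` ("imperfect" IRs).
#' @return An object of class `is_annotation`.
#' @export
is_annotation <- function(name, start, end, family = NA_character_,
                          ir_left = NA_character_, ir_right = NA_character_,
                          max_ir_mismatch = 8) {
  stopifnot(end > start)
  if (!is.na(ir_left) && !is.na(ir_right)) {
    if (nchar(ir_left) != 24 || nchar(ir_right) != 24)
      stop("terminal inverted repeats must be 24 bp")
    if (end - start < 48)
      stop("IS locus shorter than two terminal repeats")
    mm <- sum(strsplit(ir_left, "")[[1]] !=
                strsplit(revcomp(ir_right), "")[[1]])
    if (mm > max_ir_mismatch)
      stop("ir_left and reverse complement of ir_right differ at ", mm,
           " positions (> ", max_ir_mismatch, ")")
  }
  structure(list(name = name, start = as.integer(start),
                 end = as.integer(end), family = family,
                 ir_left = ir_left, ir_right = ir_right),
            class = "is_annotation")
}

#' Extract an IS element with its flanks as one query string
#'
#' Returns upstream flank + element + downstream flank; on circular
#' genomes the window may wrap the origin.
#'
#' @param target A [genome_record()].
#' @param is_ann An [is_annotation()].
#' @param flank Flank length on each side (default 2,500 bp).
#' @return DNA string of length `flank + (end - start) + flank`.
#' @export
extract_query <- function(target, is_ann, flank = 2500) {
  seq_window(target$seq, is_ann$start - flank, is_ann$end + flank,
             circular = is_circular(target))
}

# the two flank sequences, each `flank` bp, abutting the element
target_flanks <- function(target, is_ann, flank) {
  circ <- is_circular(target)
  list(up = seq_window(target$seq, is_ann$start - flank, is_ann$start, circ),
       down = seq_window(target$seq, is_ann$end, is_ann$end + flank, circ))
}

#' Find donor genomes that carry the syntenous region without the IS
#'
#' For each donor, both flanks are located by seeded local alignment; a
#' candidate requires co-linear same-strand hits whose junction gap is
#' smaller than `max_gap_frac` of the element length (the element is
#' absent), and identity above `min_identity` over the `window`-bp
#' stretches directly abutting the healed junction. Candidates are ranked
#' by combined identity (descending); ranking is a total order (ties break
#' on donor id, then coordinate), so donor input order never changes the
#' selection.
#'
#' @param target Target [genome_record()] carrying the element.
#' @param is_ann The [is_annotation()].
#' @param donors List of donor [genome_record()]s.
#' @param flank Search flank length (default 2,500 bp).
#' @param window Identity window length abutting the junction (default
#'   750 bp). Windows start exactly at the healed junction.
#' @param min_identity Identity gate, exclusive (default 0.99).
#' @param max_gap_frac Junction gap threshold as a fraction of the element
#'   length (default 0.1).
#' @param k,band,scoring Passed to [align_flank()].
#' @return Data frame of candidates (one row per passing donor) with
#'   columns `donor_id, donor_start, donor_end, strand, junction_up,
#'   junction_down, gap, up_identity, down_identity, combined_identity,
#'   is_absent`, ranked best first. Zero rows is a valid outcome
#'   (conventional design is then the fallback).
#' @export
find_donor_candidates <- function(target, is_ann, donors, flank = 2500,
                                  window = 750, min_identity = 0.99,
                                  max_gap_frac = 0.1, k = 15, band = 50,
                                  scoring = aln_scoring()) {
  if (inherits(donors, "genome_record")) donors <- list(donors)
  fl <- target_flanks(target, is_ann, flank)
  is_len <- is_ann$end - is_ann$start
  tgt_up <- seq_window(target$seq, is_ann$start - window, is_ann$start,
                       is_circular(target))
  tgt_down <- seq_window(target$seq, is_ann$end, is_ann$end + window,
                         is_circular(target))
  rows <- list()
  for (donor in donors) {
    hu <- align_flank(fl$up, donor, k = k, band = band, scoring = scoring)
    hd <- align_flank(fl$down, donor, k = k, band = band, scoring = scoring)
    if (!hu$found || !hd$found || hu$strand != hd$strand) next
    # work on the strand where target and donor are co-linear
    minus <- hu$strand == "-"
    L <- donor$length
    flip <- function(h) {
      if (!minus) return(h)
      tmp <- h$ref_start
      h$ref_start <- L - h$ref_end
      h$ref_end <- L - tmp
      h
    }
    du <- flip(hu); dd <- flip(hd)
    dseq <- if (minus) revcomp(donor$seq) else donor$seq
    if (dd$ref_start < du$ref_start) next # not co-linear
    gap <- dd$ref_start - du$ref_end
    absent <- abs(gap) < max_gap_frac * is_len
    if (!absent) {
      rows[[length(rows) + 1]] <- data.frame(
        donor_id = donor$id, donor_start = NA_integer_,
        donor_end = NA_integer_, strand = hu$strand,
        junction_up = NA_integer_, junction_down = NA_integer_, gap = gap,
        up_identity = NA_real_, down_identity = NA_real_,
        combined_identity = NA_real_, is_absent = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    j_up <- du$ref_end       # healed junction, donor coordinates (strand-local)
    j_down <- dd$ref_start
    if (j_up < window || j_down + window > nchar(dseq)) next
    wu <- substr(dseq, j_up - window + 1, j_up)
    wd <- substr(dseq, j_down + 1, j_down + window)
    iu <- ident_window(tgt_up, wu, band = band, scoring = scoring)
    id <- ident_window(tgt_down, wd, band = band, scoring = scoring)
    comb <- (iu$matches + id$matches) / (iu$columns + id$columns)
    rows[[length(rows) + 1]] <- data.frame(
      donor_id = donor$id, donor_start = du$ref_start,
      donor_end = dd$ref_end, strand = hu$strand, junction_up = j_up,
      junction_down = j_down, gap = gap, up_identity = iu$identity,
      down_identity = id$identity, combined_identity = comb,
      is_absent = TRUE, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_candidates())
  out <- do.call(rbind, rows)
  out <- out[out$is_absent & !is.na(out$up_identity) &
               out$up_identity > min_identity &
               out$down_identity > min_identity, , drop = FALSE]
  if (nrow(out) == 0) return(empty_candidates())
  out <- out[order(-out$combined_identity, out$donor_id, out$donor_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(donor_id = character(0), donor_start = integer(0),
             donor_end = integer(0), strand = character(0),
             junction_up = integer(0), junction_down = integer(0),
             gap = integer(0), up_identity = numeric(0),
             down_identity = numeric(0), combined_identity = numeric(0),
             is_absent = logical(0), stringsAsFactors = FALSE)
}

# pick an arm window of default length (midpoint of the range), shrinking
# away from ambiguous bases if possible. `get_seq(len)` must return the
# outermost-first window of the requested length.
shrink_arm <- function(get_seq, arm_min, arm_max, side) {
  len <- as.integer(floor((arm_min + arm_max) / 2))
  arm <- get_seq(len)
  while (grepl("N", arm, fixed = TRUE)) {
    # drop everything from the outer edge up to the innermost N
    npos <- gregexpr("N", arm, fixed = TRUE)[[1]]
    keep <- if (side == "left") len - max(npos) else min(npos) - 1L
    if (keep < arm_min)
      stop("ambiguous base leaves ", side, " arm shorter than ", arm_min,
           " bp")
    len <- as.integer(keep)
    arm <- get_seq(len)
  }
  arm
}

#' Design a healing construct from a donor candidate
#'
#' Homology arms are the donor sequence immediately up- and downstream of
#' the healed junction (default length the midpoint of `arm_range`);
#' an arm containing an ambiguous base is shortened within the range to
#' exclude it, or the design fails.
#'
#' @param candidate One row of [find_donor_candidates()] output.
#' @param donor The donor [genome_record()] named by the candidate.
#' @param target Target [genome_record()] (records the healed interval).
#' @param is_ann The [is_annotation()] being removed.
#' @param arm_range Allowed homology arm lengths, default `c(500, 600)`.
#' @return An object of class `deletion_construct` with fields `name`,
#'   `left_arm`, `right_arm`, `insert_source`, `healed_start`,
#'   `healed_end`.
#' @export
design_healing_construct <- function(candidate, donor, target, is_ann,
                                     arm_range = c(500, 600)) {
  stopifnot(nrow(candidate) == 1, candidate$is_absent)
  arm_min <- arm_range[1]; arm_max <- arm_range[2]
  dseq <- if (candidate$strand == "-") revcomp(donor$seq) else donor$seq
  ju <- candidate$junction_up; jd <- candidate$junction_down
  left <- shrink_arm(function(len) substr(dseq, ju - len + 1, ju),
                     arm_min, arm_max, "left")
  right <- shrink_arm(function(len) substr(dseq, jd + 1, jd + len),
                      arm_min, arm_max, "right")
  structure(list(name = paste0("heal_", is_ann$name),
                 left_arm = left, right_arm = right,
                 insert_source = paste0("donor:", candidate$donor_id),
                 healed_start = is_ann$start, healed_end = is_ann$end),
            class = "deletion_construct")
}

#' Design a conventional CDS + promoter deletion construct
#'
#' Fallback when no donor passes the identity gate: arms are taken from
#' the target genome itself, flanking a user-supplied feature interval
#' (CDS plus promoter; the promoter extent is an input, not computed).
#'
#' @param target Target [genome_record()].
#' @param feature_start,feature_end 0-based half-open feature interval.
#' @param name Construct name.
#' @param arm_range Allowed arm lengths, default `c(500, 600)`.
#' @return A `deletion_construct` with `insert_source = "conventional"`.
#' @export
design_conventional_deletion <- function(target, feature_start, feature_end,
                                         name = "deletion",
                                         arm_range = c(500, 600)) {
  if (feature_end <= feature_start) stop("feature interval is empty")
  arm_min <- arm_range[1]; arm_max <- arm_range[2]
  len0 <- as.integer(floor((arm_min + arm_max) / 2))
  circ <- is_circular(target)
  if (!circ && (feature_start - arm_min < 0 ||
                feature_end + arm_min > target$length))
    stop("feature too close to the end of a linear genome for ", arm_min,
         " bp arms")
  grab_left <- function(len) {
    lo <- feature_start - len
    if (!circ && lo < 0) stop("left arm overruns the linear genome start")
    seq_window(target$seq, lo, feature_start, circ)
  }
  grab_right <- function(len) {
    hi <- feature_end + len
    if (!circ && hi > target$length)
      stop("right arm overruns the linear genome end")
    seq_window(target$seq, feature_end, hi, circ)
  }
  # clamp default length on linear genomes
  if (!circ) len0 <- min(len0, feature_start, target$length - feature_end)
  left <- shrink_arm(function(len) grab_left(len), arm_min, arm_max, "left")
  right <- shrink_arm(function(len) grab_right(len), arm_min, arm_max, "right")
  structure(list(name = name, left_arm = left, right_arm = right,
                 insert_source = "conventional",
                 healed_start = as.integer(feature_start),
                 healed_end = as.integer(feature_end)),
            class = "deletion_construct")
}

#' @export
print.deletion_construct <- function(x, ...) {
  cat(sprintf(paste0("<deletion_construct> %s\n  arms: %d + %d bp",
                     "  source: %s\n  removes [%d, %d) (0-based)\n"),
              x$name, nchar(x$left_arm), nchar(x$right_arm),
              x$insert_source, x$healed_start, x$healed_end))
  invisible(x)
}

#' Apply a deletion construct to a genome in silico
#'
#' Excises the interval the construct removes and joins the flanks; used
#' to verify healing closure (re-running [find_donor_candidates()] on the
#' healed genome against the donor gives identity 1 over both windows).
#'
#' @param target Target [genome_record()].
#' @param construct A `deletion_construct`.
#' @return A new [genome_record()] with the interval excised.
#' @export
apply_construct <- function(target, construct) {
  s <- construct$healed_start; e <- construct$healed_end
  n <- target$length
  stopifnot(s >= 0, e <= n, e > s)
  healed <- paste0(substr(target$seq, 1, s), substr(target$seq, e + 1, n))
  genome_record(paste0(target$id, "_healed"), healed, target$topology)
}
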