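# Seeded local alignment: exact k-mer seeds anchoring a banded affine-gap
# Smith-Waterman extension. BLAST-like defaults at desk scale; every knob
# is an argument. Identity is matches / alignment columns, gap columns
# counting as mismatch (the conservative reading of "percent identity").

#' Alignment scoring parameters
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Cost of the first column of a gap (positive).
#' @param gap_ext Cost of each further gap column (positive). Setting
#'   `gap_ext == gap_open` gives a linear gap penalty.
#' @return A list of scoring parameters.
#' @export
aln_scoring <- function(match = 1, mismatch = -1, gap_open = 2, gap_ext = 1) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_ext >= 0)
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_ext = gap_ext)
}

# cluster seed hits into diagonal bands; returns list of (diag, rmin, rmax)
seed_clusters <- function(seeds, band) {
  if (nrow(seeds) == 0) return(list())
  diag <- seeds[, 2] - seeds[, 1]
  o <- order(diag)
  diag <- diag[o]
  rpos <- seeds[o, 2]
  qpos <- seeds[o, 1]
  brk <- c(0L, which(diff(diag) > band), length(diag))
  lapply(seq_len(length(brk) - 1), function(i) {
    sel <- (brk[i] + 1):brk[i + 1]
    list(diag = as.integer(stats::median(diag[sel])),
         rmin = min(rpos[sel]), rmax = max(rpos[sel]),
         qpos = qpos[sel], rpos = rpos[sel])
  })
}

# one banded local alignment of query against ref around a cluster
extend_cluster <- function(query, ref, cl, band, k, scoring) {
  qlen <- nchar(query)
  win_lo <- max(0L, cl$rmin - qlen - band)
  win_hi <- min(nchar(ref), cl$rmax + k + qlen + band)
  sub <- substr(ref, win_lo + 1, win_hi)
  a <- cpp_align_banded(query, sub, cl$diag - win_lo, band, TRUE,
                        scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_ext)
  if (!a$found || a$block_len == 0) return(NULL)
  a$r_start <- a$r_start + win_lo
  a$r_end <- a$r_end + win_lo
  a
}

#' Find the best local hit of a query flank in a donor genome
#'
#' Exact k-mer seeding plus banded affine-gap local extension on both
#' strands. Ties are broken towards the lowest donor coordinate. A query
#' with no seed hit returns `found = FALSE` ("absent"), not an error.
#'
#' @param query_flank DNA string (e.g. a 2,500-bp IS flank).
#' @param donor A [genome_record()].
#' @param k Seed k-mer length (default 15).
#' @param band Half-width of the extension band around the seed diagonal
#'   (default 50).
#' @param scoring From [aln_scoring()].
#' @return A list with `found`, and when found: `ref_start`, `ref_end`,
#'   `q_start`, `q_end` (0-based half-open), `strand`, `score`, `matches`,
#'   `block_len`, `identity`.
#' @export
align_flank <- function(query_flank, donor, k = 15, band = 50,
                        scoring = aln_scoring()) {
  query_flank <- toupper(query_flank)
  if (nchar(query_flank) < k)
    stop("query shorter than the seed length k = ", k)
  L <- donor$length
  best <- NULL
  for (strand in c("+", "-")) {
    ref <- if (strand == "+") donor$seq else revcomp(donor$seq)
    seeds <- cpp_find_seeds(query_flank, ref, as.integer(k))
    for (cl in seed_clusters(seeds, band)) {
      a <- extend_cluster(query_flank, ref, cl, band, k, scoring)
      if (is.null(a)) next
      if (strand == "-") {
        tmp <- a$r_start
        a$r_start <- L - a$r_end
        a$r_end <- L - tmp
      }
      a$strand <- strand
      better <- is.null(best) || a$score > best$score ||
        (a$score == best$score && a$r_start < best$r_start)
      if (better) best <- a
    }
  }
  if (is.null(best)) return(list(found = FALSE))
  list(found = TRUE, ref_start = best$r_start, ref_end = best$r_end,
       q_start = best$q_start, q_end = best$q_end, strand = best$strand,
       score = best$score, matches = best$matches,
       block_len = best$block_len,
       identity = best$matches / best$block_len)
}

#' Identity of two syntenous windows by banded global alignment
#'
#' Global (end-to-end) affine-gap alignment inside a band; identity is
#' matches over alignment columns with gap columns counted as mismatches,
#' so two 750-bp windows differing by 7 substitutions score 743/750.
#'
#' @param a,b DNA strings of comparable length.
#' @param band Band half-width (default 50); must cover the length
#'   difference.
#' @param scoring From [aln_scoring()].
#' @return List with `identity`, `matches`, `columns`, `score`.
#' @export
ident_window <- function(a, b, band = 50, scoring = aln_scoring()) {
  band <- max(band, abs(nchar(a) - nchar(b)) + 5)
  r <- cpp_align_banded(toupper(a), toupper(b), 0L, as.integer(band), FALSE,
                        scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_ext)
  if (!r$found) stop("global alignment failed (band too narrow?)")
  list(identity = r$matches / r$block_len, matches = r$matches,
       columns = r$block_len, score = r$score)
}
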