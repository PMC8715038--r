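# seqio: readers/writers and the shared coordinate contract.
#
# Internal convention: every coordinate is 0-based half-open, on both reads
# and references, for PAF and SAM input alike. BED is emitted natively in
# that convention; 1-based positions appear only in human-readable
# summaries and are labelled as such.

#' Construct a genome record
#'
#' A named nucleotide sequence with topology. The workhorse container for
#' chromosomes, plasmids and simulated replicons.
#'
#' @param id Non-empty sequence name.
#' @param seq DNA string over `A,C,G,T,N` (lower case is folded to upper).
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `genome_record` with fields `id`, `seq`,
#'   `topology` and `length`.
#' @export
genome_record <- function(id, seq, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop("id must be a non-empty string")
  seq <- toupper(seq)
  if (nchar(seq) < 1) stop("sequence must have length >= 1")
  check_dna(seq, what = paste0("sequence '", id, "'"))
  structure(list(id = id, seq = seq, topology = topology,
                 length = nchar(seq)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s  %s bp  (%s)\n", x$id,
              format(x$length, big.mark = ","), x$topology))
  invisible(x)
}

is_circular <- function(g) g$topology == "circular"

#' Read a FASTA file into genome records
#'
#' Wraps [Biostrings::readDNAStringSet()]; sequences are upper-cased, ids
#' are the first whitespace-delimited token of each header, and characters
#' outside `A,C,G,T,N` are rejected.
#'
#' @param path FASTA file.
#' @param topology Topology applied to every record (FASTA does not carry
#'   one); default `"linear"`.
#' @return Named list of [genome_record()]s in file order.
#' @export
read_fasta <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  recs <- lapply(seq_along(set), function(i)
    genome_record(ids[i], as.character(set[[i]]), topology))
  names(recs) <- ids
  recs
}

#' Write genome records to FASTA
#'
#' @param records A `genome_record` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

empty_alignments <- function() {
  data.frame(read_id = character(0), read_len = integer(0),
             read_start = integer(0), read_end = integer(0),
             strand = character(0), ref_id = character(0),
             ref_len = integer(0), ref_start = integer(0),
             ref_end = integer(0), matches = integer(0),
             block_len = integer(0), mapq = integer(0),
             stringsAsFactors = FALSE)
}

#' Read long-read alignments (PAF or SAM) into a common record table
#'
#' Both dialects are normalised to one contract: 0-based half-open
#' coordinates on read and reference, read coordinates always on the
#' original read strand, `strand` giving the mapping orientation.
#' Unmapped and secondary SAM records are dropped; supplementary records
#' are kept (they carry the junction halves of split reads). Hard and soft
#' clips are both treated as unaligned read sequence.
#'
#' @param path Alignment file.
#' @param dialect `"paf"` or `"sam"`.
#' @return A data frame with columns `read_id, read_len, read_start,
#'   read_end, strand, ref_id, ref_len, ref_start, ref_end, matches,
#'   block_len, mapq`.
#' @export
read_alignments <- function(path, dialect = c("paf", "sam")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (dialect == "paf") parse_paf(lines) else parse_sam(lines)
}

parse_paf <- function(lines) {
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 12)
      stop("malformed PAF line ", i, ": expected >= 12 columns, got ",
           length(f))
    num <- suppressWarnings(as.integer(f[c(2:4, 7:12)]))
    if (anyNA(num) || !f[5] %in% c("+", "-"))
      stop("malformed PAF line ", i, ": non-numeric coordinate field")
    data.frame(read_id = f[1], read_len = num[1], read_start = num[2],
               read_end = num[3], strand = f[5], ref_id = f[6],
               ref_len = num[4], ref_start = num[5], ref_end = num[6],
               matches = num[7], block_len = num[8], mapq = num[9],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  validate_alignments(out)
  out
}

parse_sam <- function(lines) {
  # reference lengths from @SQ headers, if present
  sq <- lines[startsWith(lines, "@SQ")]
  ref_lens <- integer(0)
  if (length(sq)) {
    nm <- sub("^.*\tSN:([^\t]+).*$", "\\1", sq)
    ln <- as.integer(sub("^.*\tLN:([0-9]+).*$", "\\1", sq))
    ref_lens <- setNames(ln, nm)
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 11)
      stop("malformed SAM line ", i, ": expected >= 11 columns")
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    mapq <- suppressWarnings(as.integer(f[5]))
    if (is.na(flag) || is.na(pos))
      stop("malformed SAM line ", i, ": bad FLAG/POS")
    if (bitwAnd(flag, 4L) > 0L || bitwAnd(flag, 256L) > 0L) next
    cigar <- f[6]
    if (cigar == "*")
      stop("malformed SAM line ", i, ": mapped record without CIGAR")
    ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
    clip5 <- if (length(ops) && ops[1] %in% c("S", "H")) lens[1] else 0L
    clip3 <- if (length(ops) > 1 && ops[length(ops)] %in% c("S", "H"))
      lens[length(ops)] else 0L
    qlen_aln <- sum(lens[ops %in% c("M", "I", "=", "X")])
    rlen_aln <- sum(lens[ops %in% c("M", "D", "N", "=", "X")])
    read_len <- clip5 + clip3 + qlen_aln
    rev <- bitwAnd(flag, 16L) > 0L
    # CIGAR is written in reference orientation; map back to original read
    rs <- if (rev) clip3 else clip5
    re <- rs + qlen_aln
    matches <- if (any(ops == "=")) sum(lens[ops == "="]) else qlen_aln
    block <- sum(lens[ops %in% c("M", "I", "D", "=", "X")])
    rows[[i]] <- data.frame(
      read_id = f[1], read_len = read_len, read_start = rs, read_end = re,
      strand = if (rev) "-" else "+", ref_id = f[3],
      ref_len = if (f[3] %in% names(ref_lens)) ref_lens[[f[3]]] else NA_integer_,
      ref_start = pos - 1L, ref_end = pos - 1L + rlen_aln,
      matches = matches, block_len = block, mapq = mapq,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_alignments())
  validate_alignments(out)
  out
}

validate_alignments <- function(aln) {
  bad <- aln$read_start >= aln$read_end | aln$ref_start >= aln$ref_end |
    aln$matches > aln$block_len
  if (any(bad))
    stop("invalid alignment record(s) at row(s) ",
         paste(which(bad), collapse = ", "))
  invisible(TRUE)
}

#' Write insertion sites (or any scored intervals) as BED6
#'
#' 0-based half-open, deterministically ordered by reference, start, then
#' strand (`+` before `-`).
#'
#' @param sites Data frame with columns `ref_id, start, end, name, score,
#'   strand` (a site table from [collapse_sites()] is accepted and
#'   converted).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  if (nrow(sites) > 0 && !"start" %in% names(sites) && "pos" %in% names(sites))
    sites <- data.frame(ref_id = sites$ref_id, start = sites$pos,
                        end = sites$pos + 1L, name = "site",
                        score = sites$read_count,
                        strand = sites$orientation,
                        stringsAsFactors = FALSE)
  need <- c("ref_id", "start", "end", "name", "score", "strand")
  if (!all(need %in% names(sites)))
    stop("sites must carry columns: ", paste(need, collapse = ", "))
  o <- order(sites$ref_id, sites$start, match(sites$strand, c("+", "-", ".")))
  sites <- sites[o, need, drop = FALSE]
  write.table(sites, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED file written by [write_bed()] or compatible.
#' @return Data frame with columns `ref_id, start, end, name, score,
#'   strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(data.frame(ref_id = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:6] <- c("ref_id", "start", "end", "name", "score", "strand")
  df[, 1:6]
}

#' Write a table as TSV with a header row
#'
#' @param table Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write alignment records as PAF
#'
#' @param aln Alignment table in the [read_alignments()] contract.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  df <- aln[, c("read_id", "read_len", "read_start", "read_end", "strand",
                "ref_id", "ref_len", "ref_start", "ref_end", "matches",
                "block_len", "mapq")]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
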