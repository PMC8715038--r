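# Sequence-level model of a Bxb1-type serine-integrase genetic switch:
# attB x attP recombination inverts the segment between the two crossover
# points (flipping a promoter), leaving the hybrid sites attL and attR,
# which are not substrates without a recombination directionality factor -
# hence the switch is one-way. The same crossover geometry models
# integration of an attP plasmid at a genomic attB. A separate scanner
# finds degenerate, partially conserved attB-like sites (the kind of
# cryptic site a groEL gene can harbour).

#' Describe an attachment site on a sequence
#'
#' The crossover is placed at the centre of the site, between the two
#' bases of the central dinucleotide, so the site length must be even.
#'
#' @param kind One of `"attB"`, `"attP"`, `"attL"`, `"attR"`.
#' @param start,end 0-based half-open locus on the carrier sequence.
#' @param seq Site sequence *on its own strand* (for `strand = "-"` the
#'   carrier holds its reverse complement).
#' @param strand `"+"` or `"-"`.
#' @return An object of class `att_site` with the central dinucleotide
#'   and crossover point precomputed.
#' @export
att_site <- function(kind = c("attB", "attP", "attL", "attR"),
                     start, end, seq, strand = c("+", "-")) {
  kind <- match.arg(kind)
  strand <- match.arg(strand)
  seq <- toupper(seq)
  len <- nchar(seq)
  if (end - start != len) stop("locus span and sequence length differ")
  if (len %% 2 != 0 || len < 4)
    stop("attachment site must have even length >= 4 ",
         "(central dinucleotide at the midpoint)")
  structure(list(kind = kind, start = as.integer(start),
                 end = as.integer(end), seq = seq, strand = strand,
                 central_dinucleotide = substr(seq, len / 2, len / 2 + 1),
                 cut = as.integer(start + len / 2)),
            class = "att_site")
}

#' @export
print.att_site <- function(x, ...) {
  cat(sprintf("<att_site> %s [%d,%d) %s  central %s\n", x$kind, x$start,
              x$end, x$strand, x$central_dinucleotide))
  invisible(x)
}

# carrier sequence at the site locus, as it should read if the site is
# intact (strand-aware)
site_on_carrier <- function(seq, site) {
  obs <- substr(seq, site$start + 1, site$end)
  want <- if (site$strand == "-") revcomp(site$seq) else site$seq
  list(observed = obs, expected = want, intact = identical(obs, want))
}

check_substrate <- function(construct, attB, attP) {
  if (is.null(attB) || is.null(attP))
    stop("both attB and attP must be supplied")
  if (attB$kind != "attB" || attP$kind != "attP")
    stop("no attB/attP substrate: need one attB and one attP site, got ",
         attB$kind, " and ", attP$kind)
  for (s in list(attB, attP)) {
    chk <- site_on_carrier(construct$seq, s)
    if (!chk$intact)
      stop("no attB/attP substrate: sequence at the ", s$kind,
           " locus does not match the site (already recombined?)")
  }
  invisible(TRUE)
}

#' Fire the genetic switch: invert the segment between attB and attP
#'
#' The two sites must be in inverted orientation (opposite strands) on the
#' same construct; the segment between the crossover points is
#' reverse-complemented in place, forming the hybrid sites attL and attR
#' and flipping everything between them (including the promoter). Total
#' length is conserved. The product carries no attB/attP, so a second
#' application errors - the switch is unidirectional.
#'
#' @param construct A [genome_record()] carrying both sites.
#' @param attB,attP [att_site()]s on `construct`.
#' @param promoter Optional 0-based half-open `c(start, end)` interval of
#'   the promoter; if it lies between the crossovers its strand flip is
#'   reported.
#' @return List with `product` (a [genome_record()]), and `state` (list
#'   with `state = "ON"`, the `attL`/`attR` [att_site()]s, and
#'   `promoter_strand` if a promoter was given).
#' @export
apply_switch <- function(construct, attB, attP, promoter = NULL) {
  check_substrate(construct, attB, attP)
  if (attB$strand == attP$strand)
    stop("sites are in direct orientation (excision geometry); ",
         "only the inversion switch is modelled")
  lo <- min(attB$cut, attP$cut)
  hi <- max(attB$cut, attP$cut)
  seq <- construct$seq
  product <- paste0(substr(seq, 1, lo),
                    revcomp(substr(seq, lo + 1, hi)),
                    substr(seq, hi + 1, nchar(seq)))
  stopifnot(nchar(product) == nchar(seq))
  first <- if (attB$cut < attP$cut) attB else attP
  second <- if (attB$cut < attP$cut) attP else attB
  # hybrid sites read off the product at the former loci
  mk_hybrid <- function(kind, tmpl) {
    s <- substr(product, tmpl$start + 1, tmpl$end)
    str <- tmpl$strand
    att_site(kind, tmpl$start, tmpl$end,
             if (str == "-") revcomp(s) else s, str)
  }
  attL <- mk_hybrid("attL", first)
  attR <- mk_hybrid("attR", second)
  state <- list(state = "ON", attL = attL, attR = attR)
  if (!is.null(promoter)) {
    inside <- promoter[1] >= lo && promoter[2] <= hi
    state$promoter_strand <- if (inside) "flipped" else "unchanged"
    if (inside)
      state$promoter <- c(lo + hi - promoter[2], lo + hi - promoter[1])
  }
  list(product = genome_record(construct$id, product, construct$topology),
       state = state)
}

#' Integrate an attP plasmid at a genomic attB site
#'
#' The circular plasmid is opened at its attP crossover and inserted at
#' the genomic attB crossover, with orientation fixed by the relative site
#' polarity; the product carries attL and attR at the insertion borders
#' and its length is the sum of the two inputs. The genomic attB is
#' consumed, so re-running on the product errors.
#'
#' @param genome [genome_record()] with one attB.
#' @param genomic_attB [att_site()] of kind `"attB"` on `genome`.
#' @param plasmid Circular [genome_record()].
#' @param plasmid_attP [att_site()] of kind `"attP"` on `plasmid`.
#' @return List with `product` ([genome_record()]) and `attL`, `attR`
#'   ([att_site()]s at the insertion borders).
#' @export
integrate_plasmid <- function(genome, genomic_attB, plasmid, plasmid_attP) {
  if (!is_circular(plasmid)) stop("plasmid must be circular")
  if (genomic_attB$kind != "attB" || plasmid_attP$kind != "attP")
    stop("need a genomic attB and a plasmid attP")
  chkB <- site_on_carrier(genome$seq, genomic_attB)
  if (!chkB$intact)
    stop("genome carries no intact attB at the given locus ",
         "(site consumed by a previous integration?)")
  chkP <- site_on_carrier(plasmid$seq, plasmid_attP)
  if (!chkP$intact) stop("plasmid carries no intact attP at the given locus")
  cb <- genomic_attB$cut
  cp <- plasmid_attP$cut
  Lp <- plasmid$length
  ins <- paste0(substr(plasmid$seq, cp + 1, Lp), substr(plasmid$seq, 1, cp))
  if (genomic_attB$strand != plasmid_attP$strand) ins <- revcomp(ins)
  product <- paste0(substr(genome$seq, 1, cb), ins,
                    substr(genome$seq, cb + 1, genome$length))
  stopifnot(nchar(product) == genome$length + Lp)
  lenB <- genomic_attB$end - genomic_attB$start
  lenP <- plasmid_attP$end - plasmid_attP$start
  attL_start <- genomic_attB$start
  attL_end <- cb + lenP / 2
  attR_start <- cb + Lp - lenP / 2
  attR_end <- genomic_attB$end + Lp
  g <- function(a, b) substr(product, a + 1, b)
  mk <- function(kind, s, e) {
    str <- genomic_attB$strand
    sq <- g(s, e)
    att_site(kind, s, e, if (str == "-") revcomp(sq) else sq, str)
  }
  list(product = genome_record(paste0(genome$id, "::", plasmid$id), product,
                               genome$topology),
       attL = mk("attL", attL_start, attL_end),
       attR = mk("attR", attR_start, attR_end))
}

#' Scan a genome for degenerate attB-like sites
#'
#' Every position on both strands is scored as the sum of per-position
#' weights at positions matching the reference site; weights encode which
#' positions define attB identity. A match at the central dinucleotide is
#' reported separately but not required (cryptic sites can lack it).
#'
#' @param genome [genome_record()].
#' @param reference_site DNA string of the reference attB (even length).
#' @param weights Numeric vector, one weight per site position.
#' @param min_score Minimum reported score.
#' @return Data frame of hits sorted by score (descending, ties by
#'   coordinate): `start, end, strand, score, central_match`.
#' @export
scan_attB <- function(genome, reference_site, weights, min_score) {
  reference_site <- toupper(reference_site)
  w <- nchar(reference_site)
  if (length(weights) != w)
    stop("weights length (", length(weights),
         ") does not match reference site length (", w, ")")
  hits <- rbind(scan_one_strand(genome$seq, reference_site, weights, "+"),
                scan_one_strand(genome$seq, revcomp(reference_site),
                                rev(weights), "-"))
  # central dinucleotide comparison, strand-aware
  cen <- substr(reference_site, w / 2, w / 2 + 1)
  if (nrow(hits)) {
    obs <- substr(rep(genome$seq, nrow(hits)), hits$start + w / 2,
                  hits$start + w / 2 + 1)
    obs[hits$strand == "-"] <- revcomp(obs[hits$strand == "-"])
    hits$central_match <- obs == cen
  } else hits$central_match <- logical(0)
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  hits <- hits[order(-hits$score, hits$start,
                     match(hits$strand, c("+", "-"))), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

scan_one_strand <- function(seq, site, weights, strand) {
  n <- nchar(seq)
  w <- nchar(site)
  if (n < w)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  gchars <- strsplit(seq, "")[[1]]
  schars <- strsplit(site, "")[[1]]
  npos <- n - w + 1
  score <- numeric(npos)
  for (i in seq_len(w))
    score <- score + weights[i] * (gchars[i:(i + npos - 1)] == schars[i])
  data.frame(start = 0:(npos - 1), end = w:(n), strand = strand,
             score = score, stringsAsFactors = FALSE)
}
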