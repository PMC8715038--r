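# tnseq: turn alignments of marker-anchored enrichment reads into
# transposition sites. Each informative read runs from inside the
# selection marker, across the element's terminal inverted repeat, into
# flanking genomic DNA; the marker-side alignment anchors the IR's outer
# edge in read space and the genomic alignment is projected through that
# anchor to give the junction coordinate.
#
# Junction coordinate convention (0-based): for a "+" event the 8-bp
# target window is [pos, pos + 8); for a "-" event it is the reverse
# complement of [pos - 8, pos). The simulator records truth in the same
# convention.

#' Call marker-genome junctions from read alignments
#'
#' A junction event is emitted for every read with (a) a marker-side
#' alignment to the delivery plasmid ending within `tolerance` of the IR
#' outer edge (the end of `plasmid_marker`) and (b) a genomic alignment
#' beginning within `max_read_gap` of that end in read space. Reads whose
#' plasmid alignment continues more than `backbone_threshold` bp beyond
#' the IR into vector backbone are classed `plasmid_integration` (whole
#' construct co-integrated, e.g. at a cryptic attB); reads failing (b)
#' are `ambiguous`. Reads with only genomic alignments are skipped and
#' counted (no marker anchor).
#'
#' Read orientation is normalised per read from the marker alignment
#' strand, so flipped (reverse-sequenced) reads are handled
#' transparently. The junction coordinate is obtained by projecting the
#' IR outer edge through the genomic alignment, which keeps it exact even
#' when a local alignment over- or under-runs the junction by a few
#' coincidentally matching bases.
#'
#' @param alignments Alignment table from [read_alignments()] or
#'   [naive_align()].
#' @param plasmid_marker List `(ref_id, start, end)`: the marker interval
#'   on the plasmid, oriented so `end` coincides with the IR outer edge.
#' @param max_read_gap Maximum overlap in read space between the genomic
#'   block and the marker block (junk over-extension bound, default 20).
#' @param tolerance Maximum over-extension (bp) of the marker alignment
#'   beyond the IR outer edge into backbone before the read stops looking
#'   like a clean junction (default 10).
#' @param backbone_threshold Plasmid alignment overrun beyond the IR that
#'   flags plasmid integration (default 50).
#' @param end_slack Maximum under-extension (bp) of either block away
#'   from the junction (default 150): local aligners trim noisy block
#'   ends back to the last cleanly matching stretch, and the junction is
#'   recovered by colinear extrapolation through the trimmed stub.
#' @return Data frame of events: `read_id, ref_id, junction_pos,
#'   orientation, gap_on_read, event_class`; attribute `n_skipped` counts
#'   reads without a marker anchor.
#' @export
call_junctions <- function(alignments, plasmid_marker, max_read_gap = 20,
                           tolerance = 10, backbone_threshold = 50,
                           end_slack = 150) {
  stopifnot(all(c("ref_id", "start", "end") %in% names(plasmid_marker)))
  pid <- plasmid_marker$ref_id
  ir_edge <- plasmid_marker$end
  events <- list()
  n_skipped <- 0L
  for (aln in split(alignments, alignments$read_id)) {
    pl <- aln[aln$ref_id == pid, , drop = FALSE]
    gn <- aln[aln$ref_id != pid, , drop = FALSE]
    if (nrow(pl) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    # normalise read orientation by the (best) marker alignment strand
    m <- pl[which.max(pl$matches), , drop = FALSE]
    if (m$strand == "-") {
      L <- aln$read_len[1]
      rs <- aln$read_start
      aln$read_start <- L - aln$read_end
      aln$read_end <- L - rs
      aln$strand <- ifelse(aln$strand == "+", "-", "+")
      pl <- aln[aln$ref_id == pid, , drop = FALSE]
      gn <- aln[aln$ref_id != pid, , drop = FALSE]
      m <- pl[which.max(pl$matches), , drop = FALSE]
    }
    over <- m$ref_end - ir_edge
    # read-space position of the IR outer edge, via the marker alignment
    ir_read_pos <- m$read_end - over
    if (over > backbone_threshold) {
      g <- best_adjacent(gn, ir_read_pos, Inf, Inf)
      ev <- junction_row(m, g, ir_read_pos, "plasmid_integration")
      events[[length(events) + 1L]] <- ev
      next
    }
    if (over > tolerance || over < -end_slack) {
      events[[length(events) + 1L]] <-
        junction_row(m, NULL, ir_read_pos, "ambiguous")
      next
    }
    g <- best_adjacent(gn, ir_read_pos, max_read_gap, end_slack)
    cls <- if (is.null(g)) "ambiguous" else "transposition"
    events[[length(events) + 1L]] <- junction_row(m, g, ir_read_pos, cls)
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(read_id = character(0), ref_id = character(0),
               junction_pos = integer(0), orientation = character(0),
               gap_on_read = integer(0), event_class = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

# the genomic alignment whose read start is closest to the IR edge;
# overlap into the marker block bounded by max_overlap, trimmed-end
# under-extension bounded by max_under
best_adjacent <- function(gn, ir_read_pos, max_overlap, max_under) {
  if (nrow(gn) == 0) return(NULL)
  gap <- gn$read_start - ir_read_pos
  ok <- gap >= -max_overlap & gap <= max_under
  if (!any(ok)) return(NULL)
  gn <- gn[ok, , drop = FALSE]
  gn[which.min(abs(gn$read_start - ir_read_pos)), , drop = FALSE]
}

junction_row <- function(m, g, ir_read_pos, cls) {
  if (is.null(g)) {
    return(data.frame(read_id = m$read_id, ref_id = NA_character_,
                      junction_pos = NA_integer_,
                      orientation = NA_character_,
                      gap_on_read = NA_integer_, event_class = cls,
                      stringsAsFactors = FALSE))
  }
  delta <- ir_read_pos - g$read_start
  if (g$strand == "+") {
    pos <- g$ref_start + delta
    orient <- "+"
  } else {
    pos <- g$ref_end - delta
    orient <- "-"
  }
  if (!is.na(g$ref_len) && g$ref_len > 0) pos <- pos %% g$ref_len
  data.frame(read_id = m$read_id, ref_id = g$ref_id,
             junction_pos = as.integer(pos), orientation = orient,
             gap_on_read = as.integer(g$read_start - ir_read_pos),
             event_class = cls, stringsAsFactors = FALSE)
}

#' Collapse junction events into deduplicated insertion sites
#'
#' Transposition-class events on the same reference and strand within
#' `position_tolerance` of each other are merged; the site coordinate is
#' the modal junction position (ties towards the smallest), the read
#' count is the number of merged events. Events at the same coordinate on
#' opposite strands stay distinct sites.
#'
#' @param events Output of [call_junctions()].
#' @param position_tolerance Merge radius in bp (default 3).
#' @param min_reads_for_motif Read-count threshold marking sites eligible
#'   for target-site (octamer) analysis (default 2); singletons stay in
#'   the site list.
#' @return Data frame of sites: `ref_id, pos, orientation, read_count,
#'   for_motif`, ordered by coordinate then strand.
#' @details The site coordinate is the modal junction position of the
#'   merged events; ties break towards the event with the most reliable
#'   junction anchoring (smallest `|gap_on_read|`, i.e. the shortest
#'   extrapolation through aligner-trimmed stub sequence), then towards
#'   the smallest coordinate. After clustering, a single-read site lying
#'   within twice the tolerance of a multi-read site on the same strand
#'   is absorbed into it (residual junction jitter).
#' @export
collapse_sites <- function(events, position_tolerance = 3,
                           min_reads_for_motif = 2) {
  ev <- events[events$event_class == "transposition", , drop = FALSE]
  if (!"gap_on_read" %in% names(ev)) ev$gap_on_read <- 0L
  ev$gap_on_read[is.na(ev$gap_on_read)] <- 0L
  out <- list()
  for (grp in split(ev, list(ev$ref_id, ev$orientation), drop = TRUE)) {
    o <- order(grp$junction_pos)
    pos <- grp$junction_pos[o]
    gap <- abs(grp$gap_on_read[o])
    brk <- c(0L, which(diff(pos) > position_tolerance), length(pos))
    for (i in seq_len(length(brk) - 1)) {
      sel <- (brk[i] + 1):brk[i + 1]
      cl <- pos[sel]
      tab <- table(cl)
      best <- as.integer(names(tab)[tab == max(tab)])
      site_pos <- if (length(best) == 1) best[1] else {
        # tie: most reliably anchored event, then smallest position
        cand_gap <- vapply(best, function(p) min(gap[sel][cl == p]), 0)
        best[order(cand_gap, best)][1]
      }
      out[[length(out) + 1L]] <- data.frame(
        ref_id = grp$ref_id[1], pos = site_pos,
        orientation = grp$orientation[1], read_count = length(cl),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(ref_id = character(0), pos = integer(0),
                      orientation = character(0), read_count = integer(0),
                      for_motif = logical(0), stringsAsFactors = FALSE))
  sites <- do.call(rbind, out)
  # absorb jittered singletons into adjacent multi-read sites
  repeat {
    drop <- integer(0)
    for (i in which(sites$read_count == 1)) {
      near <- which(sites$ref_id == sites$ref_id[i] &
                      sites$orientation == sites$orientation[i] &
                      sites$read_count >= 2 &
                      abs(sites$pos - sites$pos[i]) <= 2 * position_tolerance)
      if (length(near)) {
        j <- near[which.max(sites$read_count[near])]
        sites$read_count[j] <- sites$read_count[j] + 1L
        drop <- c(drop, i)
      }
    }
    if (length(drop) == 0) break
    sites <- sites[-drop, , drop = FALSE]
  }
  sites$for_motif <- sites$read_count >= min_reads_for_motif
  sites <- sites[order(sites$ref_id, sites$pos,
                       match(sites$orientation, c("+", "-"))), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Assign insertion sites to leading or lagging replichore strands
#'
#' The circular chromosome is split at `oric_pos` and `ter_pos` into two
#' replichores (replichore 1 runs clockwise oriC -> ter). On replichore 1
#' an insertion on `+` lies on the leading strand and `-` on the lagging
#' strand; on replichore 2 the assignment is inverted.
#'
#' @param sites Site table from [collapse_sites()].
#' @param oric_pos,ter_pos 0-based positions of the replication origin
#'   and terminus.
#' @param genome_len Chromosome length.
#' @return `sites` with an added `replichore_strand` column
#'   (`"leading"`/`"lagging"`).
#' @export
assign_replichore <- function(sites, oric_pos, ter_pos, genome_len) {
  if (oric_pos == ter_pos) stop("oriC and terminus positions coincide")
  pos <- sites$pos %% genome_len
  if (oric_pos < ter_pos) {
    rep1 <- pos >= oric_pos & pos < ter_pos
  } else {
    rep1 <- pos >= oric_pos | pos < ter_pos
  }
  plus <- sites$orientation == "+"
  sites$replichore_strand <- ifelse(rep1 == plus, "leading", "lagging")
  sites
}

#' Per-bin positional summary of insertion sites (polar-plot style)
#'
#' Bins the chromosome into `n_bins` half-open windows and counts sites
#' per bin, split into a leading (outer ring) and lagging (inner ring)
#' series; total counts are conserved. Optionally renders a polar genome
#' plot.
#'
#' @param sites Site table with `replichore_strand` (from
#'   [assign_replichore()]); without that column all sites are counted in
#'   a single series.
#' @param genome_len Chromosome length.
#' @param n_bins Number of bins (>= 1).
#' @param plot_file Optional image path (`.png` or `.pdf`); written with
#'   ggplot2 in polar coordinates.
#' @return Data frame `bin, bin_start, bin_end, leading, lagging, total`.
#' @export
positional_summary <- function(sites, genome_len, n_bins, plot_file = NULL) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  width <- genome_len / n_bins
  bin <- pmin(floor((sites$pos %% genome_len) / width), n_bins - 1)
  has_rep <- "replichore_strand" %in% names(sites)
  lead <- if (has_rep) sites$replichore_strand == "leading" else
    rep(TRUE, nrow(sites))
  tab_l <- tabulate(bin[lead] + 1L, nbins = n_bins)
  tab_g <- tabulate(bin[!lead] + 1L, nbins = n_bins)
  out <- data.frame(bin = seq_len(n_bins) - 1L,
                    bin_start = round((seq_len(n_bins) - 1L) * width),
                    bin_end = round(seq_len(n_bins) * width),
                    leading = tab_l, lagging = tab_g,
                    total = tab_l + tab_g)
  if (!is.null(plot_file)) render_polar_plot(out, genome_len, plot_file)
  out
}

render_polar_plot <- function(summary, genome_len, path) {
  df <- rbind(
    data.frame(mid = (summary$bin_start + summary$bin_end) / 2,
               count = summary$leading, ring = "leading (outer)"),
    data.frame(mid = (summary$bin_start + summary$bin_end) / 2,
               count = -summary$lagging, ring = "lagging (inner)"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count,
                                        fill = .data$ring)) +
    ggplot2::geom_col(width = genome_len / nrow(summary),
                      position = "identity") +
    ggplot2::coord_polar() +
    ggplot2::labs(x = "genome position (bp)", y = "sites per bin",
                  title = "Transposition sites around the chromosome") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 6, height = 6, dpi = 120)
  invisible(path)
}
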