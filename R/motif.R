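# Target-site preference analysis over the strand-specific 8-bp window
# downstream of the terminal inverted repeat at each insertion site:
# position frequency/information matrices (logo letter heights use
# 2 - H bits, optionally with the WebLogo small-sample correction) and
# central tetranucleotide frequencies.

#' Extract the strand-specific 8-bp target windows at insertion sites
#'
#' For a `+` site at `pos` the window is `[pos, pos + 8)`; for a `-` site
#' it is the reverse complement of `[pos - 8, pos)`. Windows containing
#' `N` are dropped (and counted); on a linear genome, windows overrunning
#' a contig end drop the site with a warning. Circular genomes wrap.
#'
#' @param sites Site table from [collapse_sites()] (needs `pos`,
#'   `orientation`, `read_count`).
#' @param genome [genome_record()] the sites live on.
#' @param min_reads Minimum read count for a site to contribute
#'   (default 2).
#' @param width Window width (default 8).
#' @return Character vector of octamers; attribute `n_dropped_n` counts
#'   windows lost to ambiguous bases.
#' @export
extract_octamers <- function(sites, genome, min_reads = 2, width = 8) {
  keep <- sites$read_count >= min_reads
  sites <- sites[keep, , drop = FALSE]
  circ <- is_circular(genome)
  n <- genome$length
  out <- character(0)
  n_edge <- 0L
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i]
    rng <- if (sites$orientation[i] == "+") c(p, p + width) else
      c(p - width, p)
    if (!circ && (rng[1] < 0 || rng[2] > n)) {
      n_edge <- n_edge + 1L
      next
    }
    w <- seq_window(genome$seq, rng[1], rng[2], circ)
    if (sites$orientation[i] == "-") w <- revcomp(w)
    out <- c(out, w)
  }
  if (n_edge > 0)
    warning(n_edge, " site(s) dropped: window beyond a linear contig end")
  has_n <- grepl("N", out, fixed = TRUE)
  res <- out[!has_n]
  attr(res, "n_dropped_n") <- sum(has_n)
  res
}

#' Position frequency matrix and information content of target windows
#'
#' Information content per column is `2 - H` bits with
#' `H = -sum_b p_b log2 p_b`; with `small_sample_correction` the standard
#' WebLogo term `e(n) = 3 / (2 ln(2) n)` is subtracted (and the result
#' floored at 0).
#'
#' @param octamers Character vector of equal-length windows (from
#'   [extract_octamers()]).
#' @param small_sample_correction Apply the WebLogo small-sample
#'   correction (default `FALSE`).
#' @return Object of class `position_matrix`: `counts` (4 x width,
#'   rows A,C,G,T), `freqs`, `n_sites`, `info_bits`,
#'   `small_sample_correction`.
#' @export
position_matrix <- function(octamers, small_sample_correction = FALSE) {
  if (length(octamers) == 0) stop("no target windows supplied")
  width <- nchar(octamers[1])
  stopifnot(all(nchar(octamers) == width))
  mat <- do.call(rbind, strsplit(octamers, ""))
  counts <- vapply(seq_len(width), function(j)
    tabulate(match(mat[, j], DNA_BASES), nbins = 4), integer(4))
  dimnames(counts) <- list(DNA_BASES, seq_len(width))
  n <- length(octamers)
  freqs <- counts / n
  H <- apply(freqs, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  info <- 2 - H
  if (small_sample_correction) info <- pmax(0, info - 3 / (2 * log(2) * n))
  structure(list(counts = counts, freqs = freqs, n_sites = n,
                 info_bits = unname(info),
                 small_sample_correction = small_sample_correction),
            class = "position_matrix")
}

#' @export
print.position_matrix <- function(x, ...) {
  cat(sprintf("<position_matrix> %d sites, %d positions%s\n", x$n_sites,
              ncol(x$counts),
              if (x$small_sample_correction) " (small-sample corrected)"
              else ""))
  print(round(x$freqs, 3))
  cat("info (bits):", paste(sprintf("%.2f", x$info_bits), collapse = " "),
      "\n")
  invisible(x)
}

#' Frequencies of the central tetranucleotide of each target window
#'
#' @param octamers Character vector of 8-bp windows.
#' @param central_span 1-based positions of the central tetramer within
#'   the window (default 3:6).
#' @param ceiling Flagging threshold: is any single tetramer above this
#'   fraction of all insertions (default 0.20)?
#' @return Object of class `tetramer_table`: `freqs` (named, sorted
#'   descending), `counts`, `n_sites`, `ceiling`, `any_exceeds_ceiling`,
#'   `top_tetramer`.
#' @export
tetramer_frequencies <- function(octamers, central_span = 3:6,
                                 ceiling = 0.20) {
  if (length(octamers) == 0) stop("no target windows supplied")
  tet <- substr(octamers, min(central_span), max(central_span))
  counts <- sort(table(tet), decreasing = TRUE)
  freqs <- as.numeric(counts) / length(octamers)
  names(freqs) <- names(counts)
  structure(list(freqs = freqs, counts = as.integer(counts),
                 n_sites = length(octamers), ceiling = ceiling,
                 any_exceeds_ceiling = any(freqs > ceiling),
                 top_tetramer = names(freqs)[1]),
            class = "tetramer_table")
}

#' @export
print.tetramer_table <- function(x, n = 10, ...) {
  cat(sprintf("<tetramer_table> %d sites; top central 4-mers:\n",
              x$n_sites))
  show <- head(x$freqs, n)
  for (i in seq_along(show))
    cat(sprintf("  %s  %5.1f%%\n", names(show)[i], 100 * show[i]))
  cat(sprintf("  any > %.0f%% ceiling: %s\n", 100 * x$ceiling,
              x$any_exceeds_ceiling))
  invisible(x)
}

#' Render a sequence logo from a position matrix
#'
#' Letters at each position are stacked by frequency, total stack height
#' equal to the column's information content in bits (0-2).
#'
#' @param matrix A [position_matrix()].
#' @param path Output image path (`.png` or `.pdf`).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_logo <- function(matrix, path, width = 7, height = 3.2) {
  base_cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  open_dev <- if (grepl("\\.pdf$", path)) {
    function() grDevices::pdf(path, width = width, height = height)
  } else {
    function() grDevices::png(path, width = width * 120,
                              height = height * 120, res = 120)
  }
  open_dev()
  on.exit(grDevices::dev.off())
  npos <- ncol(matrix$counts)
  graphics::plot(NA, xlim = c(0.5, npos + 0.5), ylim = c(0, 2.05),
                 xlab = "position in target window", ylab = "bits",
                 xaxt = "n", bty = "n")
  graphics::axis(1, at = seq_len(npos))
  for (j in seq_len(npos)) {
    h <- matrix$freqs[, j] * matrix$info_bits[j]
    ord <- order(h) # smallest first, tallest on top
    y <- 0
    for (b in DNA_BASES[ord]) {
      hb <- h[b]
      if (hb <= 1e-9) next
      cex <- hb / max(graphics::strheight("A", units = "user"), 1e-9)
      graphics::text(j, y + hb / 2, b, col = base_cols[b], cex = cex,
                     font = 2)
      y <- y + hb
    }
  }
  invisible(path)
}
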