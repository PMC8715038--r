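# Shared sequence helpers. All coordinates in the package are 0-based
# half-open unless a function explicitly says otherwise.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring on a possibly circular sequence; start/end 0-based half-open,
# end may exceed nchar(seq) (wraps) and start may be negative.
seq_window <- function(seq, start, end, circular = TRUE) {
  n <- nchar(seq)
  stopifnot(end > start)
  if (!circular) {
    if (start < 0 || end > n)
      stop("window [", start, ",", end, ") overruns a linear sequence of length ", n)
    return(substr(seq, start + 1, end))
  }
  width <- end - start
  if (width > n) stop("window longer than the circular sequence")
  start <- ((start %% n) + n) %% n
  if (start + width <= n) {
    substr(seq, start + 1, start + width)
  } else {
    paste0(substr(seq, start + 1, n), substr(seq, 1, start + width - n))
  }
}

# modal value of an integer vector; ties broken by the smallest value
modal_min <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)]) # which.max takes first = smallest name
}

check_dna <- function(seq, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, seq)
  if (any(bad))
    stop(what, " contains characters outside ",
         if (allow_n) "A/C/G/T/N" else "A/C/G/T")
  invisible(TRUE)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}
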