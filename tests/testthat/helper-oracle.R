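# Independent full-matrix Smith-Waterman oracle in plain R (affine gaps:
# first gap column costs `open`, each further column `ext`; linear gaps via
# open == ext). Used to cross-check the package's seeded banded kernel.
# Tie preferences mirror the production kernel so optimal intervals are
# comparable: diagonal state preferred over gap states, best cell is the
# first strictly-greater one in row-major order.

sw_oracle <- function(q, r, match = 1, mismatch = -1, open = 2, ext = 2) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  IX <- matrix(NEG, n + 1, m + 1)
  IY <- matrix(NEG, n + 1, m + 1)
  PM <- matrix(0L, n + 1, m + 1) # 0 none, 1 M, 2 IX, 3 IY
  PX <- matrix(0L, n + 1, m + 1)
  PY <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- -1; bj <- -1
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (qc[i - 1] == rc[j - 1]) match else mismatch
      base <- max(M[i - 1, j - 1], IX[i - 1, j - 1], IY[i - 1, j - 1])
      from <- if (base <= NEG / 2) 0L
        else if (base == M[i - 1, j - 1]) 1L
        else if (base == IX[i - 1, j - 1]) 2L else 3L
      if (base <= 0) { M[i, j] <- s; PM[i, j] <- 0L }
      else { M[i, j] <- base + s; PM[i, j] <- from }
      xo <- if (M[i, j - 1] > NEG / 2) M[i, j - 1] - open else NEG
      xe <- if (IX[i, j - 1] > NEG / 2) IX[i, j - 1] - ext else NEG
      if (xo >= xe) { IX[i, j] <- xo; PX[i, j] <- 1L }
      else { IX[i, j] <- xe; PX[i, j] <- 2L }
      yo <- if (M[i - 1, j] > NEG / 2) M[i - 1, j] - open else NEG
      ye <- if (IY[i - 1, j] > NEG / 2) IY[i - 1, j] - ext else NEG
      if (yo >= ye) { IY[i, j] <- yo; PY[i, j] <- 1L }
      else { IY[i, j] <- ye; PY[i, j] <- 3L }
      if (M[i, j] > best) { best <- M[i, j]; bi <- i; bj <- j }
    }
  }
  if (bi < 0)
    return(list(score = 0, found = FALSE))
  i <- bi; j <- bj; st <- 1L
  matches <- 0L; cols <- 0L
  repeat {
    if (st == 1L) {
      from <- PM[i, j]
      cols <- cols + 1L
      if (qc[i - 1] == rc[j - 1]) matches <- matches + 1L
      i <- i - 1; j <- j - 1
      if (from == 0L) break
      st <- from
    } else if (st == 2L) {
      from <- PX[i, j]
      cols <- cols + 1L
      j <- j - 1
      st <- from
    } else {
      from <- PY[i, j]
      cols <- cols + 1L
      i <- i - 1
      st <- from
    }
  }
  list(score = best, q_start = i - 1, q_end = bi - 1, r_start = j - 1,
       r_end = bj - 1, matches = matches, block_len = cols, found = TRUE)
}
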