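# Independent oracles used across the suite. These deliberately use
# brute-force enumeration / textbook dynamic programming, not the package's
# own code paths.

# all deletion start positions producing the same edited string
oracleDeletionPlacements <- function(ref, start, len) {
  target <- paste0(substr(ref, 1, start), substr(ref, start + len + 1, nchar(ref)))
  starts <- integer()
  for (s in 0:(nchar(ref) - len)) {
    edited <- paste0(substr(ref, 1, s), substr(ref, s + len + 1, nchar(ref)))
    if (edited == target) starts <- c(starts, s)
  }
  starts
}

# microhomology as the placement-ambiguity span of the deletion
oracleMH <- function(ref, start, len) {
  st <- oracleDeletionPlacements(ref, start, len)
  max(st) - min(st)
}

# Gotoh affine-gap global alignment score (gap cost = open + extend * len)
oracleAlignScore <- function(read, ref, match = 2, mismatch = -3,
                             gapOpen = 8, gapExtend = 1) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in ref (read insertion)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in read (deletion)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gapOpen - gapExtend * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gapOpen - gapExtend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gapOpen - gapExtend,
                     X[i - 1, j] - gapExtend)
      Y[i, j] <- max(M[i, j - 1] - gapOpen - gapExtend,
                     Y[i, j - 1] - gapExtend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# score implied by an event table (global alignment identity elsewhere)
impliedEventScore <- function(events, refLen, match = 2, mismatch = -3,
                              gapOpen = 8, gapExtend = 1) {
  nSub <- sum(events$kind == "substitution")
  nDel <- sum(events$length[events$kind == "deletion"])
  nIns <- sum(events$length[events$kind == "insertion"])
  nIndel <- sum(events$kind != "substitution")
  nMatch <- refLen - nDel - nSub
  nMatch * match + nSub * mismatch -
    nIndel * gapOpen - (nDel + nIns) * gapExtend
}

# hypergeometric tail p-values by direct pmf enumeration (lchoose)
oracleFisherTails <- function(a, b, c, d) {
  n1 <- a + b; K <- a + c; N <- a + b + c + d
  support <- max(0, n1 - (N - K)):min(n1, K)
  logp <- lchoose(K, support) + lchoose(N - K, n1 - support) - lchoose(N, n1)
  pmf <- exp(logp)
  list(p_left = sum(pmf[support <= a]), p_right = sum(pmf[support >= a]))
}

# a small spectrum used by several generator tests
fullSpectrum <- function(unedited = 0.17) {
  edited <- c("1bp Ins" = 0.15, "Large Ins" = 0.05, "MH Small Del" = 0.20,
              "NonMH Small Del" = 0.15, "MH Large Del" = 0.10,
              "NonMH Large Del" = 0.10, "Mut" = 0.08)
  spectrumSpec(c(edited / sum(edited) * (1 - unedited),
                 "Unedited" = unedited))
}

mhTestLocus <- function(seed = 7) {
  genTargetLocus(mhDesign = data.frame(offset = c(-4, -6), len = c(4, 9),
                                       mh = c(2, 3)), seed = seed)
}

randomRef <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
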