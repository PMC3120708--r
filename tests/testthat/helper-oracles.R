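# Shared fixtures and independent oracles.

aa20 <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]], "X")

randomSeq <- function(len) paste(sample(aa20, len, replace = TRUE),
                                 collapse = "")

# Build a Landscape object directly from a numeric matrix (for unit tests of
# the peak/walk machinery, which only reads the matrix).
mkLandscape <- function(H, w = 1L, idA = "A", idB = "B") {
  H <- as.matrix(H)
  new("Landscape", idA = idA, idB = idB, w = as.integer(w),
      H = matrix(as.integer(H), nrow(H), ncol(H)))
}

# Independent brute-force landscape oracle: enumerate every oriented pair and
# every window-index pair, testing substring occurrence directly.
bruteLandscape <- function(seqA, seqB, pairs, seqs, w,
                           excludeIds = NULL) {
  nA <- nchar(seqA) - w + 1L
  nB <- nchar(seqB) - w + 1L
  H <- matrix(0L, max(nA, 0L), max(nB, 0L))
  if (nA < 1L || nB < 1L) return(H)
  lo <- pmin(pairs[[1L]], pairs[[2L]])
  hi <- pmax(pairs[[1L]], pairs[[2L]])
  pairs <- unique(data.frame(idA = lo, idB = hi, stringsAsFactors = FALSE))
  oriented <- list()
  for (r in seq_len(nrow(pairs))) {
    x <- pairs[r, 1L]; y <- pairs[r, 2L]
    if (!is.null(excludeIds) &&
        setequal(c(x, y), excludeIds)) next
    oriented[[length(oriented) + 1L]] <- c(x, y)
    if (x != y) oriented[[length(oriented) + 1L]] <- c(y, x)
  }
  for (o in oriented) {
    for (i in seq_len(nA)) {
      winA <- substr(seqA, i, i + w - 1L)
      if (!grepl(winA, seqs[[o[1L]]], fixed = TRUE)) next
      for (j in seq_len(nB)) {
        winB <- substr(seqB, j, j + w - 1L)
        if (grepl(winB, seqs[[o[2L]]], fixed = TRUE))
          H[i, j] <- H[i, j] + 1L
      }
    }
  }
  H
}

# Random toy interaction instance for oracle-equivalence checks.
randomToyInstance <- function(maxProteins = 8L, maxLen = 30L, maxW = 4L) {
  n <- sample(2:maxProteins, 1L)
  ids <- paste0("T", seq_len(n))
  lens <- sample(5:maxLen, n, replace = TRUE)
  seqs <- vapply(lens, randomSeq, character(1L))
  names(seqs) <- ids
  npairs <- sample(1:6, 1L)
  pairs <- data.frame(idA = sample(ids, npairs, replace = TRUE),
                      idB = sample(ids, npairs, replace = TRUE),
                      stringsAsFactors = FALSE)
  qs <- sample(ids, 2L, replace = FALSE)
  list(ids = ids, seqs = seqs, pairs = pairs,
       A = qs[1L], B = qs[2L], w = sample(1:maxW, 1L))
}

# Small planted-motif study used by recovery checks (package defaults).
recoveryDataset <- function(seed) {
  generateDataset(synthParams(seed = seed))
}
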