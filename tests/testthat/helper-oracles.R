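## Independent oracles used to validate the package's computations.
## These deliberately re-derive results by brute force or closed form and
## never call the code paths they check.

## Exhaustive affine-gap global alignment score (Gotoh three-state DP,
## score only). A gap of length L costs open + L * ext; end gaps are
## penalized. Written independently of the alignment engine.
gotoh_global_score <- function(a, b, mat, open, ext) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -open - i * ext
  for (j in seq_len(m)) Y[1L, j + 1L] <- -open - j * ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[ca[i], cb[j]]
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                               X[i, j + 1L] - ext,
                               Y[i, j + 1L] - open - ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                               Y[i + 1L, j] - ext,
                               X[i + 1L, j] - open - ext)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

## Brute-force cherry enumeration: a leaf pair is a cherry iff its MRCA
## has exactly those two leaves as descendants. Uses ape utilities only.
brute_force_cherries <- function(tree) {
  tips <- tree$tip.label
  out <- list()
  if (length(tips) < 2L) return(out)
  for (i in seq_along(tips)) for (j in seq_along(tips)) {
    if (i >= j) next
    mrca <- ape::getMRCA(tree, c(tips[i], tips[j]))
    desc <- ape::extract.clade(tree, mrca)$tip.label
    if (length(desc) == 2L && setequal(desc, c(tips[i], tips[j])))
      out[[length(out) + 1L]] <- sort(c(tips[i], tips[j]))
  }
  out
}

random_protein <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]], n, replace = TRUE),
        collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Matrix exponential by scaling-and-squaring on the series (independent
## of the package's eigendecomposition path).
expm_series <- function(A, k = 20L, squarings = 12L) {
  A <- A / 2^squarings
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (i in seq_len(k)) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(squarings)) P <- P %*% P
  P
}
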