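# Independent oracles used across the suite. These deliberately re-derive
# results with naive algorithms (loops, direct series, full DP matrices) and
# never share code with the implementation they check.

# exhaustive per-residue hotspot scan with explicit window loops
naive_hotspot_scan <- function(counts, params = hotspot_params()) {
  L <- length(counts)
  out <- data.frame(residue = integer(0), k = integer(0), passed = logical(0))
  for (r in seq_len(L)) {
    k <- counts[r]
    if (k < params$min_count) next
    ok <- TRUE
    for (W in params$windows) {
      lo <- max(1, r - W %/% 2)
      hi <- min(L, r + W %/% 2)
      n_w <- 0
      for (j in lo:hi) n_w <- n_w + counts[j]
      if (params$mode == "fraction") {
        if (k / n_w < params$min_fraction) ok <- FALSE
      } else {
        if (k < params$overrep_factor * n_w / (hi - lo + 1)) ok <- FALSE
      }
    }
    out <- rbind(out, data.frame(residue = r, k = k, passed = ok))
  }
  out
}

# upper Poisson tail by direct series summation of the lower tail
poisson_tail_series <- function(k, lambda) {
  if (k == 0) return(1)
  i <- 0:(k - 1)
  1 - sum(exp(-lambda + i * log(lambda) - lgamma(i + 1)))
}

# Smith-Waterman score by full Gotoh dynamic programming; a gap of length
# ell costs open + ell * ext (the same affine convention as local_align)
sw_score_oracle <- function(a, b, open = 10, ext = 0.5) {
  submat <- get_blosum62()
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consumes b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consumes a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + submat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

get_blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

random_peptide <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
}
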