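## Small utilities for matching fitted components to a known truth.

allPermutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in allPermutations(k - 1L))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

## Best one-to-one matching (over all permutations) minimizing the mean
## per-column total-variation distance; returns the matched per-column TV
## values and the permutation.
bestMatchTV <- function(fittedPwms, truePwms) {
  k <- length(truePwms)
  best <- NULL
  bestMean <- Inf
  for (perm in allPermutations(k)) {
    tv <- unlist(lapply(seq_len(k), function(i) {
      0.5 * colSums(abs(probMatrix(fittedPwms[[perm[i]]]) -
                          probMatrix(truePwms[[i]])))
    }))
    if (mean(tv) < bestMean) {
      bestMean <- mean(tv)
      best <- list(tv = tv, perm = unlist(perm))
    }
  }
  best
}
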