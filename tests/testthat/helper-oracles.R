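## Independent brute-force oracles: plain arithmetic, no log space, no
## vectorized shortcuts shared with the implementation.

.oracleBases <- c("A", "C", "G", "U")

oracleHamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

oracleSeqProb <- function(seed, pwm) {
  ch <- strsplit(seed, "", fixed = TRUE)[[1]]
  p <- 1
  for (v in seq_along(ch))
    p <- p * unname(probMatrix(pwm)[match(ch[v], .oracleBases), v])
  p
}

## Plain-arithmetic posterior: numerator / denominator per sequence.
oracleEStep <- function(seeds, lambdas, pwms) {
  k <- length(lambdas)
  z <- matrix(NA_real_, length(seeds), k)
  for (m in seq_along(seeds)) {
    num <- numeric(k)
    for (i in seq_len(k))
      num[i] <- lambdas[i] * oracleSeqProb(seeds[m], pwms[[i]])
    z[m, ] <- num / sum(num)
  }
  z
}

oracleMarginal <- function(seeds, lambdas, pwms) {
  total <- 0
  for (m in seq_along(seeds)) {
    s <- 0
    for (i in seq_along(lambdas))
      s <- s + lambdas[i] * oracleSeqProb(seeds[m], pwms[[i]])
    total <- total + log(s)
  }
  total
}

## Explicit per-column evaluation of the information-weighted match score.
oracleMatchScore <- function(seed, groupSeeds) {
  L <- nchar(seed)
  n <- length(groupSeeds)
  chars <- t(vapply(groupSeeds,
                    function(s) strsplit(s, "", fixed = TRUE)[[1]],
                    character(L)))
  f <- matrix(0, 4, L)
  for (v in seq_len(L))
    for (b in 1:4)
      f[b, v] <- sum(chars[, v] == .oracleBases[b]) / n
  info <- numeric(L)
  for (v in seq_len(L))
    for (b in 1:4)
      if (f[b, v] > 0)
        info[v] <- info[v] + f[b, v] * log(4 * f[b, v])
  sc <- strsplit(seed, "", fixed = TRUE)[[1]]
  num <- 0; lo <- 0; hi <- 0
  for (v in seq_len(L)) {
    num <- num + info[v] * f[match(sc[v], .oracleBases), v]
    lo <- lo + info[v] * min(f[, v])
    hi <- hi + info[v] * max(f[, v])
  }
  if (hi - lo <= 0) return(0)
  (num - lo) / (hi - lo)
}

## O(N^2) silhouette with the singleton -> 0 and 0/0 -> 0 conventions.
oracleSilhouette <- function(seeds, labels) {
  n <- length(seeds)
  D <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      D[i, j] <- oracleHamming(seeds[i], seeds[j])
  out <- numeric(n)
  for (m in seq_len(n)) {
    own <- setdiff(which(labels == labels[m]), m)
    if (length(own) == 0) { out[m] <- 0; next }
    a <- mean(D[m, own])
    b <- Inf
    for (g in setdiff(unique(labels), labels[m]))
      b <- min(b, mean(D[m, which(labels == g)]))
    mx <- max(a, b)
    out[m] <- if (mx == 0) 0 else (b - a) / mx
  }
  out
}

## Random test-case generators (always called under a caller-set seed).
randomSeedStrings <- function(n, L = 6L) {
  vapply(seq_len(n), function(i)
    paste(sample(.oracleBases, L, replace = TRUE), collapse = ""),
    character(1))
}

randomPWM <- function(L = 6L) {
  g <- matrix(rgamma(4 * L, 1), 4, L)
  PWM(sweep(g, 2, colSums(g), "/"))
}

randomModelParams <- function(k, L = 6L) {
  lam <- rgamma(k, 1) + 0.05
  list(lambdas = lam / sum(lam),
       pwms = replicate(k, randomPWM(L), simplify = FALSE))
}
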