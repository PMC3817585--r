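## Seeded simulator: seed sets drawn from a known PWM mixture, for
## parameter-recovery tests and demo fixtures.

## k distinct consensus strings with pairwise Hamming >= minHamming, drawn
## by seeded rejection (cheap at L = 6 and small k).
.drawConsensus <- function(k, L, minHamming) {
  out <- character(0)
  tries <- 0L
  while (length(out) < k) {
    tries <- tries + 1L
    if (tries > 10000L)
      stop("could not place ", k, " consensus strings at pairwise ",
           "Hamming >= ", minHamming, " with L = ", L)
    cand <- paste(sample(.BASES, L, replace = TRUE), collapse = "")
    if (length(out) == 0 ||
        all(hammingDistance(rep(cand, length(out)), out) >= minHamming))
      out <- c(out, cand)
  }
  out
}

#' Simulate a seed set from a known PWM mixture
#'
#' Draws true component PWMs, then for each record draws a component from
#' the mixing weights and bases independently per column — exactly the
#' generative model the EM engine fits. \code{separation = "random"} draws
#' every PWM column from a symmetric Dirichlet(\code{columnConcentration});
#' \code{"planted_consensus"} builds each PWM from a distinct consensus
#' string (pairwise Hamming >= \code{minConsensusHamming}, which keeps the
#' components identifiable) with probability \code{matchProb} on the
#' consensus base at every position. Deterministic per \code{rngSeed}.
#'
#' @param k number of components; must satisfy k <= 4^L for
#'   planted_consensus.
#' @param n number of records (>= 1).
#' @param L seed length (default 6).
#' @param lambdas mixing weights (default uniform).
#' @param separation \code{"planted_consensus"} (default) or
#'   \code{"random"}.
#' @param columnConcentration Dirichlet concentration for random PWMs.
#' @param matchProb consensus-base probability for planted PWMs.
#' @param minConsensusHamming minimum pairwise Hamming distance between
#'   planted consensus strings.
#' @param rngSeed integer seed.
#' @return a \linkS4class{SimulationTruth} with record ids
#'   \code{sim_<component>_<index>}.
#' @examples
#' truth <- sampleMixture(k = 2, n = 50, rngSeed = 11)
#' table(truth@labels)
#' @export
sampleMixture <- function(k, n, L = 6L, lambdas = NULL,
                          separation = c("planted_consensus", "random"),
                          columnConcentration = 1, matchProb = 0.85,
                          minConsensusHamming = 3L, rngSeed = 1L) {
  separation <- match.arg(separation)
  if (n < 1) stop("n must be >= 1")
  if (k < 1) stop("k must be >= 1")
  if (is.null(lambdas)) lambdas <- rep(1 / k, k)
  if (length(lambdas) != k || abs(sum(lambdas) - 1) > 1e-9)
    stop("lambdas must be a k-vector summing to 1")
  if (separation == "planted_consensus" && k > 4^L)
    stop("cannot plant ", k, " distinct consensus strings with L = ", L)
  if (columnConcentration <= 0) stop("columnConcentration must be > 0")
  .withSeed(rngSeed, {
    pwms <- if (separation == "planted_consensus") {
      lapply(.drawConsensus(k, L, minConsensusHamming), .windowToPwm,
             matchWeight = matchProb)
    } else {
      lapply(seq_len(k), function(i) {
        g <- matrix(stats::rgamma(4L * L, shape = columnConcentration), 4, L)
        PWM(sweep(g, 2L, colSums(g), "/"))
      })
    }
    labels <- sample.int(k, n, replace = TRUE, prob = lambdas)
    enc <- matrix(0L, n, L)
    for (i in seq_len(k)) {
      idx <- which(labels == i)
      if (length(idx) == 0) next
      p <- pwms[[i]]@probs
      for (v in seq_len(L))
        enc[idx, v] <- sample.int(4L, length(idx), replace = TRUE,
                                  prob = p[, v])
    }
    seeds <- apply(enc, 1L, function(r) paste(.BASES[r], collapse = ""))
    ids <- sprintf("sim_%d_%d", labels, seq_len(n))
    new("SimulationTruth", pwms = pwms, lambdas = lambdas,
        labels = as.integer(labels), seeds = SeedSet(ids, seeds),
        rngSeed = as.integer(rngSeed))
  })
}

#' Write a simulated truth as a mature-miRNA-like FASTA fixture
#'
#' Each simulated seed is planted at positions 2-7 of a 22-mer with
#' uniform-random flanking bases, so the fixture exercises the full
#' pipeline including seed extraction. Byte-identical per \code{rngSeed}.
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param path output FASTA path.
#' @param totalLength length of the padded sequence (default 22, a typical
#'   mature miRNA length).
#' @param rngSeed integer seed for the flanking bases.
#' @return the path, invisibly.
#' @export
writeFixtureFasta <- function(truth, path, totalLength = 22L, rngSeed = 1L) {
  L <- seedWidth(truth@seeds)
  if (totalLength < L + 1L)
    stop("totalLength must be at least L + 1 = ", L + 1L)
  seeds <- unname(seedStrings(truth@seeds))
  n <- length(seeds)
  .withSeed(rngSeed, {
    pre <- sample(.BASES, n, replace = TRUE)
    postLen <- totalLength - L - 1L
    post <- vapply(seq_len(n), function(i) {
      paste(sample(.BASES, postLen, replace = TRUE), collapse = "")
    }, character(1))
    lines <- character(2L * n)
    lines[c(TRUE, FALSE)] <- paste0(">", seqIds(truth@seeds))
    lines[c(FALSE, TRUE)] <- paste0(pre, seeds, post)
    writeLines(lines, path)
  })
  invisible(path)
}

#' Write the simulation truth sidecar JSON
#'
#' Same schema as the model file (\code{\link{writeMixtureModel}}) plus a
#' \code{labels} array of true component indices (0-based, matching file
#' conventions).
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeSimulationTruth <- function(truth, path) {
  obj <- list(
    schema_version = 1L,
    L = seedWidth(truth@seeds),
    k = length(truth@pwms),
    base_order = as.list(.BASES),
    lambdas = truth@lambdas,
    pwms = lapply(truth@pwms, function(p) unname(p@probs)),
    rng_seed = truth@rngSeed,
    labels = truth@labels - 1L)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
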