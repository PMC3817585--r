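## PWM operations: per-sequence likelihood, consensus, information content,
## and initialization of the mixture components.

#' Log-likelihood of a seed under one PWM
#'
#' Natural-log probability of a sequence under the column-independent PWM
#' model: sum over positions v of log W[base at v, v]. If an unsmoothed
#' zero entry is touched the result is \code{-Inf} (a documented sentinel,
#' never an error).
#'
#' @param seeds character vector of seed strings of length L.
#' @param pwm a \linkS4class{PWM} with L columns.
#' @return numeric vector of log-likelihoods.
#' @examples
#' seedLogLikelihood("ACGUAC", PWM(matrix(0.25, 4, 6)))  # log(0.25^6)
#' @export
seedLogLikelihood <- function(seeds, pwm) {
  L <- ncol(pwm@probs)
  if (any(nchar(seeds) != L))
    stop("seed length must equal the PWM width L = ", L)
  enc <- .encodeSeeds(seeds)
  lp <- log(pwm@probs)
  vals <- lp[cbind(as.vector(enc), rep(seq_len(L), each = nrow(enc)))]
  rowSums(matrix(vals, nrow = nrow(enc)))
}

#' @describeIn PWM per-column maximal-probability base, ties broken by the
#'   fixed base order A < C < G < U.
#' @param x a PWM.
#' @export
setMethod("consensusString", "PWM", function(x) {
  paste(.BASES[apply(x@probs, 2L, which.max)], collapse = "")
})

#' @describeIn GroupProfile consensus of the group's frequency matrix (ties
#'   to the lowest base in A < C < G < U order).
#' @param x a GroupProfile.
#' @export
setMethod("consensusString", "GroupProfile", function(x) {
  paste(.BASES[apply(x@freqs, 2L, which.max)], collapse = "")
})

.colInfo <- function(freqs) {
  if (any(freqs < -1e-12)) stop("negative frequency in information content")
  freqs <- pmax(freqs, 0)
  apply(as.matrix(freqs), 2L, function(f) {
    nz <- f > 0
    sum(f[nz] * log(4 * f[nz]))  # 0 log 0 = 0 convention
  })
}

#' @rdname columnInformation
#' @export
setMethod("columnInformation", "numeric", function(x) {
  if (length(x) != 4) stop("a frequency vector must have 4 entries")
  if (abs(sum(x) - 1) > 1e-9) stop("frequencies must sum to 1")
  unname(.colInfo(matrix(x, 4, 1)))
})

#' @rdname columnInformation
#' @export
setMethod("columnInformation", "matrix", function(x) .colInfo(x))

#' @rdname columnInformation
#' @export
setMethod("columnInformation", "PWM", function(x) .colInfo(x@probs))

#' @rdname columnInformation
#' @export
setMethod("columnInformation", "GroupProfile", function(x) .colInfo(x@freqs))

## One length-L window -> PWM with matchWeight on the observed base.
.windowToPwm <- function(window, matchWeight) {
  enc <- .encodeSeeds(window)[1L, ]
  L <- length(enc)
  p <- matrix((1 - matchWeight) / 3, 4, L)
  p[cbind(enc, seq_len(L))] <- matchWeight
  PWM(p)
}

#' Initialize k PWMs for an EM run
#'
#' \code{mode = "from_sequences"} draws k length-L windows uniformly (with
#' replacement) from a background pool of sequences and converts each into
#' a PWM that puts \code{matchWeight} on the observed base at each position
#' and \code{(1 - matchWeight)/3} on the others. The default pool is the
#' input seed set itself; a user-supplied \code{background} of longer
#' sequences (e.g. genomic fragments) can stand in, with a uniform random
#' window taken per draw. \code{mode = "dirichlet"} draws each column
#' independently from a symmetric Dirichlet(1). Deterministic given
#' \code{rngSeed}.
#'
#' @param seeds a \linkS4class{SeedSet} or character vector of seed strings.
#' @param k number of components (>= 1).
#' @param mode \code{"from_sequences"} (default) or \code{"dirichlet"}.
#' @param matchWeight probability mass on the observed base, in (0.25, 1).
#' @param rngSeed integer seed.
#' @param background optional character vector of background sequences, each
#'   of length >= L.
#' @param L seed length; inferred from \code{seeds} when omitted.
#' @return list of k \linkS4class{PWM} objects.
#' @export
initPWMs <- function(seeds, k, mode = c("from_sequences", "dirichlet"),
                     matchWeight = 0.7, rngSeed = 1L, background = NULL,
                     L = NULL) {
  mode <- match.arg(mode)
  if (k < 1) stop("k must be >= 1")
  pool <- if (is(seeds, "SeedSet")) seeds@seeds else as.character(seeds)
  if (is.null(L)) {
    if (length(pool) == 0) stop("cannot infer L from an empty seed set")
    L <- nchar(pool[[1]])
  }
  if (mode == "from_sequences") {
    if (!is.null(background)) pool <- toupper(chartr("T", "U", background))
    if (length(pool) == 0)
      stop("from_sequences initialization needs a non-empty pool")
    if (any(nchar(pool) < L))
      stop("background sequences must be at least L = ", L, " long")
    if (matchWeight <= 0.25 || matchWeight >= 1)
      stop("matchWeight must lie in (0.25, 1)")
    .withSeed(rngSeed, {
      lapply(seq_len(k), function(i) {
        s <- pool[[sample.int(length(pool), 1L)]]
        start <- sample.int(nchar(s) - L + 1L, 1L)
        .windowToPwm(substr(s, start, start + L - 1L), matchWeight)
      })
    })
  } else {
    .withSeed(rngSeed, {
      lapply(seq_len(k), function(i) {
        g <- matrix(stats::rgamma(4L * L, shape = 1), 4, L)
        PWM(sweep(g, 2L, colSums(g), "/"))
      })
    })
  }
}
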