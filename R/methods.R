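## Accessors, show methods, and internal encoding helpers.

#' @rdname seqIds
#' @export
setMethod("seqIds", "SeedSet", function(x) x@ids)

#' @rdname seqIds
#' @export
setMethod("seqIds", "Grouping", function(x) names(x@labels))

#' @rdname seedStrings
#' @export
setMethod("seedStrings", "SeedSet", function(x) {
  stats::setNames(x@seeds, x@ids)
})

#' @rdname seedStrings
#' @export
setMethod("seedStrings", "SimulationTruth", function(x) seedStrings(x@seeds))

#' @describeIn SeedSet number of records.
#' @param x a SeedSet.
#' @export
setMethod("length", "SeedSet", function(x) length(x@ids))

#' @rdname seedWidth
#' @export
setMethod("seedWidth", "SeedSet", function(x) {
  if (length(x@seeds) == 0) return(NA_integer_)
  nchar(x@seeds[[1]])
})

#' @rdname seedWidth
#' @export
setMethod("seedWidth", "PWM", function(x) ncol(x@probs))

#' @rdname seedWidth
#' @export
setMethod("seedWidth", "PWMixture", function(x) ncol(x@pwms[[1]]@probs))

#' @rdname seedWidth
#' @export
setMethod("seedWidth", "GroupProfile", function(x) ncol(x@freqs))

#' @rdname probMatrix
#' @export
setMethod("probMatrix", "PWM", function(x) x@probs)

#' @rdname probMatrix
#' @export
setMethod("probMatrix", "GroupProfile", function(x) x@freqs)

#' @rdname mixingWeights
#' @export
setMethod("mixingWeights", "PWMixture", function(x) x@lambdas)

#' @rdname pwmList
#' @export
setMethod("pwmList", "PWMixture", function(x) x@pwms)

#' @rdname responsibilities
#' @export
setMethod("responsibilities", "PWMixture", function(x) x@responsibilities)

#' @rdname logLikTrajectory
#' @export
setMethod("logLikTrajectory", "PWMixture", function(x) x@loglikTrajectory)

#' @rdname groupLabels
#' @export
setMethod("groupLabels", "Grouping", function(x) x@labels)

#' @rdname nGroups
#' @export
setMethod("nGroups", "Grouping", function(x) x@k)

#' @rdname nGroups
#' @export
setMethod("nGroups", "PWMixture", function(x) x@k)

#' @rdname familyList
#' @export
setMethod("familyList", "FamilyTable", function(x) x@families)

setMethod("show", "SeedSet", function(object) {
  cat("SeedSet with", length(object@ids), "records, seed length",
      seedWidth(object), "\n")
  n <- min(3L, length(object@ids))
  if (n > 0)
    for (i in seq_len(n))
      cat(" ", object@ids[i], object@seeds[i], "\n")
  if (length(object@ids) > n) cat("  ...\n")
})

setMethod("show", "PWM", function(object) {
  cat("PWM (4 x", ncol(object@probs), "), consensus",
      consensusString(object), "\n")
  print(round(object@probs, 3))
})

setMethod("show", "PWMixture", function(object) {
  cat("PWMixture with k =", object@k, "components, L =",
      seedWidth(object), "\n")
  cat("  lambdas:", paste(sprintf("%.3f", object@lambdas), collapse = " "),
      "\n")
  cat("  consensus:",
      paste(vapply(object@pwms, consensusString, character(1)),
            collapse = " "), "\n")
  if (length(object@loglikTrajectory))
    cat("  final loglik:",
        format(utils::tail(object@loglikTrajectory, 1)), "after",
        object@nIter, "iterations (converged:", object@converged, ")\n")
})

setMethod("show", "Grouping", function(object) {
  sizes <- tabulate(object@labels, nbins = object@k)
  cat("Grouping of", length(object@labels), "records into", object@k,
      "groups (", sum(sizes == 0), "empty )\n")
})

setMethod("show", "FamilyTable", function(object) {
  cat("FamilyTable with", length(object@families), "families,",
      length(unlist(object@families, use.names = FALSE)), "members\n")
})

setMethod("show", "GroupProfile", function(object) {
  cat("GroupProfile from", object@nMembers, "seeds",
      if (isDegenerate(object)) "(degenerate: all columns uniform)" else "",
      "\n")
  print(round(object@freqs, 3))
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth: k =", length(object@pwms), "components,",
      length(object@labels), "records\n")
})

## ---- internal helpers -----------------------------------------------------

## Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
## state afterwards so no hidden global state leaks between calls.
.withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## SeedSet -> N x L integer matrix of base codes in 1..4 (A,C,G,U order).
.encodeSeeds <- function(x) {
  seeds <- if (is(x, "SeedSet")) x@seeds else as.character(x)
  if (length(seeds) == 0) return(matrix(integer(), 0, 0))
  L <- nchar(seeds[[1]])
  chars <- matrix(unlist(strsplit(seeds, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seeds), ncol = L, byrow = TRUE)
  enc <- match(chars, .BASES)
  dim(enc) <- dim(chars)
  enc
}

## N x L integer codes -> N x 4L one-hot matrix, column block order
## (base 1..4) within position 1..L: column index = 4*(v-1) + u.
.oneHot <- function(enc) {
  n <- nrow(enc); L <- ncol(enc)
  oh <- matrix(0, n, 4L * L)
  if (n == 0) return(oh)
  idx <- cbind(rep(seq_len(n), L),
               4L * rep(seq_len(L) - 1L, each = n) + as.vector(enc))
  oh[idx] <- 1
  oh
}

## Stack a list of PWMs into a k x 4L matrix of log-probabilities, matching
## the .oneHot column order. log(0) = -Inf is deliberate (documented
## sentinel for unsmoothed zero entries).
.logPwmMatrix <- function(pwms) {
  t(vapply(pwms, function(p) as.vector(log(p@probs)),
           numeric(4L * ncol(pwms[[1]]@probs))))
}

## Row-wise log-sum-exp, guarding all -Inf rows.
.logSumExpRows <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}
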