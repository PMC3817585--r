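#' @import methods
NULL

## Fixed base ordering used everywhere, including serialization.
.BASES <- c("A", "C", "G", "U")

#' SeedSet: a set of fixed-length miRNA seed sequences
#'
#' Holds one identifier and one seed string per record. All seeds in a set
#' share the same length L and are over the RNA alphabet \{A, C, G, U\}.
#' Duplicate seed strings under distinct ids are permitted (many miRNAs
#' share a seed); duplicate ids are not.
#'
#' @slot ids character vector of unique record identifiers.
#' @slot seeds character vector of seed strings, same length as \code{ids}.
#' @export
setClass("SeedSet", slots = c(ids = "character", seeds = "character"))

setValidity("SeedSet", function(object) {
  msgs <- character()
  if (length(object@ids) != length(object@seeds))
    msgs <- c(msgs, "ids and seeds must have equal length")
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, paste0("duplicate ids: ",
      paste(unique(object@ids[duplicated(object@ids)]), collapse = ", ")))
  if (length(object@seeds) > 0) {
    w <- nchar(object@seeds)
    if (length(unique(w)) > 1)
      msgs <- c(msgs, "all seeds must share a single length L")
    bad <- grepl("[^ACGU]", object@seeds)
    if (any(bad))
      msgs <- c(msgs, paste0("seeds with characters outside {A,C,G,U}: ",
        paste(utils::head(object@ids[bad], 5), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SeedSet
#'
#' @param ids character vector of unique identifiers.
#' @param seeds character vector of equal-length seed strings over
#'   \{A, C, G, U\}.
#' @return A \linkS4class{SeedSet}.
#' @examples
#' SeedSet(c("a", "b"), c("GAGGUA", "AUACAA"))
#' @export
SeedSet <- function(ids, seeds) {
  new("SeedSet", ids = as.character(ids), seeds = as.character(seeds))
}

#' PWM: a column-stochastic position weight matrix
#'
#' A 4 x L matrix of per-position base probabilities, rows fixed in the
#' order A, C, G, U.
#'
#' @slot probs numeric 4 x L matrix; every column sums to 1.
#' @export
setClass("PWM", slots = c(probs = "matrix"))

setValidity("PWM", function(object) {
  p <- object@probs
  if (!is.numeric(p) || nrow(p) != 4)
    return("probs must be a numeric matrix with 4 rows (A, C, G, U)")
  if (ncol(p) < 1) return("probs must have at least one column")
  if (any(p < 0)) return("probs must be non-negative")
  cs <- colSums(p)
  if (any(abs(cs - 1) > 1e-9))
    return("every PWM column must sum to 1 (within 1e-9)")
  TRUE
})

#' Construct a PWM
#'
#' @param probs numeric 4 x L column-stochastic matrix (rows A, C, G, U).
#' @return A \linkS4class{PWM}.
#' @examples
#' PWM(matrix(0.25, 4, 6))
#' @export
PWM <- function(probs) {
  probs <- as.matrix(probs)
  dimnames(probs) <- list(.BASES, NULL)
  new("PWM", probs = probs)
}

#' PWMixture: a fitted mixture of position weight matrices
#'
#' The result of \code{\link{fitMixture}}: k mixing weights, k PWMs sharing
#' one seed length, the posterior responsibility matrix for the training
#' seeds, and fit metadata (marginal log-likelihood trajectory, RNG seed,
#' convergence state).
#'
#' @slot k integer number of components.
#' @slot lambdas numeric k-vector of mixing weights summing to 1.
#' @slot pwms list of k \linkS4class{PWM} objects sharing L.
#' @slot responsibilities numeric N x k row-stochastic posterior matrix
#'   (may have zero rows for a model not paired with data).
#' @slot loglikTrajectory numeric per-iteration marginal log-likelihood.
#' @slot rngSeed integer seed the fit was started from.
#' @slot converged logical convergence flag.
#' @slot nIter integer number of EM iterations run.
#' @export
setClass("PWMixture", slots = c(
  k = "integer", lambdas = "numeric", pwms = "list",
  responsibilities = "matrix", loglikTrajectory = "numeric",
  rngSeed = "integer", converged = "logical", nIter = "integer"))

setValidity("PWMixture", function(object) {
  msgs <- character()
  if (length(object@lambdas) != object@k)
    msgs <- c(msgs, "lambdas must have length k")
  if (any(object@lambdas < -1e-12))
    msgs <- c(msgs, "lambdas must be non-negative")
  if (abs(sum(object@lambdas) - 1) > 1e-9)
    msgs <- c(msgs, "lambdas must sum to 1 (within 1e-9)")
  if (length(object@pwms) != object@k)
    msgs <- c(msgs, "pwms must be a list of length k")
  if (!all(vapply(object@pwms, is, logical(1), class2 = "PWM")))
    msgs <- c(msgs, "all pwms must be PWM objects")
  else {
    Ls <- vapply(object@pwms, function(p) ncol(p@probs), integer(1))
    if (length(unique(Ls)) > 1)
      msgs <- c(msgs, "all PWMs must share the same number of columns L")
  }
  if (nrow(object@responsibilities) > 0) {
    if (ncol(object@responsibilities) != object@k)
      msgs <- c(msgs, "responsibilities must have k columns")
    else if (any(abs(rowSums(object@responsibilities) - 1) > 1e-9))
      msgs <- c(msgs, "responsibility rows must sum to 1 (within 1e-9)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PWMixture
#'
#' Mostly used internally and by the model JSON reader; end users normally
#' obtain fitted models from \code{\link{fitMixture}} or \code{\link{scanK}}.
#'
#' @param lambdas numeric mixing weights (must sum to 1).
#' @param pwms list of \linkS4class{PWM} objects sharing L.
#' @param responsibilities optional N x k row-stochastic matrix.
#' @param loglikTrajectory optional numeric trajectory.
#' @param rngSeed integer seed recorded on the model.
#' @param converged logical flag.
#' @param nIter integer iteration count.
#' @return A \linkS4class{PWMixture}.
#' @export
PWMixture <- function(lambdas, pwms,
                      responsibilities = matrix(numeric(), 0, length(lambdas)),
                      loglikTrajectory = numeric(), rngSeed = NA_integer_,
                      converged = NA, nIter = length(loglikTrajectory)) {
  new("PWMixture", k = length(lambdas), lambdas = as.numeric(lambdas),
      pwms = pwms, responsibilities = responsibilities,
      loglikTrajectory = as.numeric(loglikTrajectory),
      rngSeed = as.integer(rngSeed), converged = as.logical(converged),
      nIter = as.integer(nIter))
}

#' Grouping: a hard assignment of records to groups
#'
#' Labels are stored 1-based (R convention) and written 0-based to files.
#' Empty groups are permitted: \code{k} can exceed the number of distinct
#' labels present.
#'
#' @slot labels named integer vector, one entry per record id, values in
#'   1..k.
#' @slot k integer number of groups.
#' @export
setClass("Grouping", slots = c(labels = "integer", k = "integer"))

setValidity("Grouping", function(object) {
  msgs <- character()
  if (is.null(names(object@labels)) && length(object@labels) > 0)
    msgs <- c(msgs, "labels must be named by record id")
  if (anyDuplicated(names(object@labels)))
    msgs <- c(msgs, "each record id must appear exactly once")
  if (length(object@labels) > 0 &&
      (min(object@labels) < 1L || max(object@labels) > object@k))
    msgs <- c(msgs, "labels must lie in 1..k")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Grouping
#'
#' @param labels named integer vector of group labels in 1..k (names are
#'   record ids).
#' @param k integer number of groups (defaults to \code{max(labels)}).
#' @return A \linkS4class{Grouping}.
#' @export
Grouping <- function(labels, k = max(labels)) {
  lab <- as.integer(labels)
  names(lab) <- names(labels)
  new("Grouping", labels = lab, k = as.integer(k))
}

#' FamilyTable: reference family membership
#'
#' A mapping family id -> set of member ids, miRBase-family style. A member
#' id may belong to at most one family.
#'
#' @slot families named list; each element a non-empty character vector of
#'   member ids.
#' @slot accessions named character vector of optional per-family accessions
#'   (may be empty).
#' @export
setClass("FamilyTable",
         slots = c(families = "list", accessions = "character"))

setValidity("FamilyTable", function(object) {
  msgs <- character()
  if (length(object@families) > 0 && is.null(names(object@families)))
    msgs <- c(msgs, "families must be named by family id")
  if (any(lengths(object@families) == 0))
    msgs <- c(msgs, "family member sets must be non-empty")
  all_members <- unlist(object@families, use.names = FALSE)
  dup <- unique(all_members[duplicated(all_members)])
  if (length(dup))
    msgs <- c(msgs, paste0("member ids in more than one family: ",
                           paste(dup, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' GroupProfile: empirical base frequencies of a group of seeds
#'
#' Raw (unsmoothed) per-column base frequencies of the member seeds; the
#' frequency matrix that the match score Score_M is evaluated against. A
#' profile is degenerate when every column is exactly uniform, in which case
#' the match-score denominator vanishes.
#'
#' @slot freqs numeric 4 x L matrix of base frequencies (rows A, C, G, U).
#' @slot nMembers integer number of seeds the profile was built from.
#' @export
setClass("GroupProfile", slots = c(freqs = "matrix", nMembers = "integer"))

setValidity("GroupProfile", function(object) {
  if (nrow(object@freqs) != 4) return("freqs must have 4 rows")
  if (object@nMembers >= 1L &&
      any(abs(colSums(object@freqs) - 1) > 1e-9))
    return("freqs columns must sum to 1 (within 1e-9)")
  TRUE
})

#' SimulationTruth: a simulated seed set with its generating model
#'
#' @slot pwms list of k true \linkS4class{PWM} objects.
#' @slot lambdas numeric true mixing weights.
#' @slot labels integer per-record true component index (1-based).
#' @slot seeds the simulated \linkS4class{SeedSet}.
#' @slot rngSeed integer seed the simulation was drawn with.
#' @export
setClass("SimulationTruth", slots = c(
  pwms = "list", lambdas = "numeric", labels = "integer",
  seeds = "SeedSet", rngSeed = "integer"))

setValidity("SimulationTruth", function(object) {
  msgs <- character()
  if (length(object@labels) != length(object@seeds@ids))
    msgs <- c(msgs, "labels must have one entry per seed record")
  if (length(object@lambdas) != length(object@pwms))
    msgs <- c(msgs, "lambdas and pwms must have equal length")
  if (length(msgs)) msgs else TRUE
})
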