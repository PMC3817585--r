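#' @importFrom Biostrings consensusString
NULL

#' Record identifiers
#' @param x a SeedSet, Grouping or SimulationTruth.
#' @return character vector of record ids.
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' Seed strings
#' @param x a SeedSet or SimulationTruth.
#' @return character vector of seed strings.
#' @export
setGeneric("seedStrings", function(x) standardGeneric("seedStrings"))

#' Shared seed length L
#' @param x a SeedSet, PWM, PWMixture or GroupProfile.
#' @return integer seed length.
#' @export
setGeneric("seedWidth", function(x) standardGeneric("seedWidth"))

#' Probability / frequency matrix
#' @param x a PWM or GroupProfile.
#' @return numeric 4 x L matrix with rows A, C, G, U.
#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))

#' Mixing weights of a mixture model
#' @param x a PWMixture.
#' @return numeric vector of mixing weights.
#' @export
setGeneric("mixingWeights", function(x) standardGeneric("mixingWeights"))

#' Component PWMs of a mixture model
#' @param x a PWMixture.
#' @return list of PWM objects.
#' @export
setGeneric("pwmList", function(x) standardGeneric("pwmList"))

#' Posterior responsibility matrix
#' @param x a PWMixture.
#' @return numeric N x k row-stochastic matrix.
#' @export
setGeneric("responsibilities", function(x) standardGeneric("responsibilities"))

#' Marginal log-likelihood trajectory of a fit
#' @param x a PWMixture.
#' @return numeric vector, one value per EM iteration.
#' @export
setGeneric("logLikTrajectory", function(x) standardGeneric("logLikTrajectory"))

#' Group labels of a hard assignment
#' @param x a Grouping.
#' @return named integer vector of labels in 1..k.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Number of groups
#' @param x a Grouping or PWMixture.
#' @return integer.
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' Family membership list
#' @param x a FamilyTable.
#' @return named list of character vectors of member ids.
#' @export
setGeneric("familyList", function(x) standardGeneric("familyList"))

#' Per-column information content
#'
#' I(v) = sum_b f_b log(4 f_b) in natural log, with the convention
#' 0 log 0 = 0. Zero for a uniform column, log 4 for a fully conserved one.
#'
#' @param x a frequency 4-vector, a 4 x L matrix, a PWM or a GroupProfile.
#' @return numeric: one value per column (a scalar for a single 4-vector).
#' @export
setGeneric("columnInformation",
           function(x) standardGeneric("columnInformation"))

#' Hard group assignment from posterior responsibilities
#'
#' Each record goes to the component with maximal posterior responsibility;
#' ties break to the lowest component index. Empty groups are permitted.
#'
#' @param x a PWMixture or a row-stochastic responsibility matrix with row
#'   names giving record ids.
#' @return a \linkS4class{Grouping}.
#' @export
setGeneric("assignGroups", function(x) standardGeneric("assignGroups"))

#' Degeneracy flag of a frequency profile
#'
#' TRUE when every column of the profile is exactly uniform, so the match
#' score denominator is 0 and \code{\link{matchScore}} returns 0 by
#' convention.
#'
#' @param x a GroupProfile.
#' @return logical.
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))
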