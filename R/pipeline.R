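## High-level pipeline runs: each writes its tabular/JSON outputs plus a
## config echo capturing all effective parameters, so a run can be
## reproduced exactly from its output directory. These functions are also
## the surface the command-line front end (inst/scripts/seedmix.R) calls.

.configEcho <- function(outDir, command, params) {
  cfg <- c(list(tool = "seedmix",
                version = as.character(utils::packageVersion("seedmix")),
                command = command), params)
  jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(cfg)
}

.ensureDir <- function(outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  outDir
}

## Shared post-fit output writing for runFit / runScan.
.writeFitOutputs <- function(model, seedSet, outDir, groupPrefix) {
  grouping <- assignGroups(model)
  writeMixtureModel(model, file.path(outDir, "model.json"))
  writeAssignments(grouping, seedSet, responsibilities(model),
                   file.path(outDir, "assignments.tsv"),
                   groupPrefix = groupPrefix)
  writeGroupScores(groupSummaries(grouping, seedSet),
                   file.path(outDir, "group_scores.tsv"))
  grouping
}

#' Fit a mixture at one k and write all outputs
#'
#' Runs seed extraction, restarted EM at a single k, hard assignment and
#' per-group scoring; writes model.json, assignments.tsv, group_scores.tsv
#' and config.json into \code{outDir}.
#'
#' @param input path to a FASTA file of mature sequences.
#' @param k number of mixture components.
#' @param outDir output directory (created if needed).
#' @param seedStart,seedLength 1-based seed window (defaults: positions
#'   2-7).
#' @param alphabet,skipAmbiguous,prefixFilter see
#'   \code{\link{seedSetFromFasta}}.
#' @param restarts random restarts (best-likelihood fit kept).
#' @param rngSeed master seed; all randomness derives from it.
#' @param pseudocount,tol,maxIter,initMode,mStepVariant see
#'   \code{\link{fitMixture}}.
#' @param groupPrefix optional display prefix rendering group labels as
#'   e.g. "c10" in the assignments table.
#' @return (invisibly) list with the fitted model, the grouping and the
#'   output directory.
#' @export
runFit <- function(input, k, outDir, seedStart = 2L, seedLength = 6L,
                   alphabet = "dna_to_rna", skipAmbiguous = FALSE,
                   prefixFilter = NULL, restarts = 1L, rngSeed = 1L,
                   pseudocount = 1e-4, tol = 1e-8, maxIter = 500L,
                   initMode = "from_sequences", mStepVariant = "standard",
                   groupPrefix = NULL) {
  .ensureDir(outDir)
  ss <- seedSetFromFasta(input, start = seedStart, width = seedLength,
                         alphabet = alphabet, skipAmbiguous = skipAmbiguous,
                         prefixFilter = prefixFilter)
  res <- scanK(ss, kValues = k, restarts = restarts, rngSeed = rngSeed,
               pseudocount = pseudocount, tol = tol, maxIter = maxIter,
               initMode = initMode, mStepVariant = mStepVariant)
  grouping <- .writeFitOutputs(res$model, ss, outDir, groupPrefix)
  .configEcho(outDir, "fit",
              list(input = input, k = k, seedStart = seedStart,
                   seedLength = seedLength, alphabet = alphabet,
                   skipAmbiguous = skipAmbiguous,
                   prefixFilter = prefixFilter, restarts = restarts,
                   rngSeed = rngSeed, pseudocount = pseudocount, tol = tol,
                   maxIter = maxIter, initMode = initMode,
                   mStepVariant = mStepVariant, outDir = outDir))
  invisible(list(model = res$model, grouping = grouping, outDir = outDir))
}

#' Scan k with restarts and write the winner's outputs
#'
#' Runs \code{\link{scanK}} over \code{kValues}, writes the per-k
#' best-likelihood table to scan.tsv, and the winning model's outputs as
#' in \code{\link{runFit}}.
#'
#' @inheritParams runFit
#' @param kValues integer vector of component counts to scan.
#' @return (invisibly) list with the best model, its grouping, the scan
#'   table and the output directory.
#' @export
runScan <- function(input, kValues, outDir, seedStart = 2L, seedLength = 6L,
                    alphabet = "dna_to_rna", skipAmbiguous = FALSE,
                    prefixFilter = NULL, restarts = 10L, rngSeed = 1L,
                    pseudocount = 1e-4, tol = 1e-8, maxIter = 500L,
                    initMode = "from_sequences", mStepVariant = "standard",
                    groupPrefix = NULL) {
  .ensureDir(outDir)
  ss <- seedSetFromFasta(input, start = seedStart, width = seedLength,
                         alphabet = alphabet, skipAmbiguous = skipAmbiguous,
                         prefixFilter = prefixFilter)
  res <- scanK(ss, kValues = kValues, restarts = restarts, rngSeed = rngSeed,
               pseudocount = pseudocount, tol = tol, maxIter = maxIter,
               initMode = initMode, mStepVariant = mStepVariant)
  utils::write.table(res$table, file.path(outDir, "scan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  grouping <- .writeFitOutputs(res$model, ss, outDir, groupPrefix)
  .configEcho(outDir, "scan",
              list(input = input, kValues = kValues, bestK = res$bestK,
                   seedStart = seedStart, seedLength = seedLength,
                   alphabet = alphabet, skipAmbiguous = skipAmbiguous,
                   prefixFilter = prefixFilter, restarts = restarts,
                   rngSeed = rngSeed, pseudocount = pseudocount, tol = tol,
                   maxIter = maxIter, initMode = initMode,
                   mStepVariant = mStepVariant, outDir = outDir))
  invisible(list(model = res$model, grouping = grouping, table = res$table,
                 outDir = outDir))
}

## Build a Grouping from a family table: one group per family, in sorted
## family-id order. Used to score reference families Table-1 style.
.familyGrouping <- function(families) {
  fam <- familyList(families)
  fids <- sort(names(fam))
  labels <- integer(0)
  for (i in seq_along(fids))
    labels <- c(labels, stats::setNames(rep(i, length(fam[[fids[i]]])),
                                        fam[[fids[i]]]))
  Grouping(labels, k = length(fids))
}

#' Score an externally supplied grouping
#'
#' Computes Score_S / Score_M summaries for any grouping of the input
#' sequences — a fitted assignment table, a reference family table, or a
#' baseline — enabling side-by-side comparisons of groupings. Writes
#' group_scores.tsv, overall_scores.tsv and config.json.
#'
#' @inheritParams runFit
#' @param assignments path to an assignments TSV
#'   (\code{\link{writeAssignments}} format); exactly one of
#'   \code{assignments} / \code{familyTable} must be given.
#' @param familyTable path to a reference family TSV; each family becomes
#'   one group. Input records not covered by any family are dropped with a
#'   warning; grouping ids absent from the FASTA are an error.
#' @return (invisibly) list with the grouping, the summaries data.frame
#'   and the overall score vector.
#' @export
runScore <- function(input, outDir, assignments = NULL, familyTable = NULL,
                     seedStart = 2L, seedLength = 6L,
                     alphabet = "dna_to_rna", skipAmbiguous = FALSE) {
  if (is.null(assignments) == is.null(familyTable))
    stop("give exactly one of 'assignments' or 'familyTable'")
  .ensureDir(outDir)
  ss <- seedSetFromFasta(input, start = seedStart, width = seedLength,
                         alphabet = alphabet, skipAmbiguous = skipAmbiguous)
  grouping <- if (!is.null(assignments)) readAssignments(assignments)$grouping
              else .familyGrouping(readFamilyTable(familyTable))
  orphans <- setdiff(seqIds(grouping), seqIds(ss))
  if (length(orphans))
    stop("grouping ids absent from the FASTA: ",
         paste(utils::head(orphans, 10), collapse = ", "))
  uncovered <- setdiff(seqIds(ss), seqIds(grouping))
  if (length(uncovered)) {
    warning("dropping ", length(uncovered),
            " input record(s) not covered by the grouping")
    keep <- seqIds(ss) %in% seqIds(grouping)
    ss <- SeedSet(seqIds(ss)[keep], unname(seedStrings(ss))[keep])
  }
  summaries <- groupSummaries(grouping, ss)
  overall <- overallScores(grouping, ss)
  writeGroupScores(summaries, file.path(outDir, "group_scores.tsv"))
  utils::write.table(
    data.frame(score_S = overall[["score_S"]],
               score_M = overall[["score_M"]]),
    file.path(outDir, "overall_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  .configEcho(outDir, "score",
              list(input = input, assignments = assignments,
                   familyTable = familyTable, seedStart = seedStart,
                   seedLength = seedLength, alphabet = alphabet,
                   skipAmbiguous = skipAmbiguous, outDir = outDir))
  invisible(list(grouping = grouping, summaries = summaries,
                 overall = overall))
}

#' Compare a fitted grouping against reference families
#'
#' Writes the family-enrichment table ("overlap/family_size" per family)
#' for an assignments TSV against a reference family TSV.
#'
#' @param assignments path to an assignments TSV.
#' @param familyTable path to a reference family TSV.
#' @param outDir output directory.
#' @param groupPrefix optional display prefix for group labels (e.g. "c").
#' @return (invisibly) the enrichment data.frame.
#' @export
runCompare <- function(assignments, familyTable, outDir,
                       groupPrefix = NULL) {
  .ensureDir(outDir)
  grouping <- readAssignments(assignments)$grouping
  enrich <- familyEnrichment(grouping, readFamilyTable(familyTable))
  writeEnrichment(enrich, file.path(outDir, "enrichment.tsv"),
                  groupPrefix = groupPrefix)
  .configEcho(outDir, "compare",
              list(assignments = assignments, familyTable = familyTable,
                   outDir = outDir))
  invisible(enrich)
}

#' Simulate a fixture FASTA with its truth sidecar
#'
#' Thin wrapper over \code{\link{sampleMixture}} /
#' \code{\link{writeFixtureFasta}}: writes fixture.fasta, truth.json and
#' config.json into \code{outDir}.
#'
#' @param outDir output directory.
#' @param k,n,L,lambdas,separation,matchProb,rngSeed see
#'   \code{\link{sampleMixture}}.
#' @return (invisibly) the \linkS4class{SimulationTruth}.
#' @export
runSimulate <- function(outDir, k, n, L = 6L, lambdas = NULL,
                        separation = "planted_consensus", matchProb = 0.85,
                        rngSeed = 1L) {
  .ensureDir(outDir)
  truth <- sampleMixture(k = k, n = n, L = L, lambdas = lambdas,
                         separation = separation, matchProb = matchProb,
                         rngSeed = rngSeed)
  writeFixtureFasta(truth, file.path(outDir, "fixture.fasta"),
                    rngSeed = .deriveSeed(rngSeed, k, 0L))
  writeSimulationTruth(truth, file.path(outDir, "truth.json"))
  .configEcho(outDir, "simulate",
              list(k = k, n = n, L = L, lambdas = lambdas,
                   separation = separation, matchProb = matchProb,
                   rngSeed = rngSeed, outDir = outDir))
  invisible(truth)
}
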