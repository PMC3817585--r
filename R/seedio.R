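## Sequence and table I/O: FASTA reading with alphabet normalization, seed
## extraction, reference family tables, and the tabular outputs.

#' Read mature miRNA sequences from FASTA
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file, takes the first
#' whitespace-delimited token of each header as the record id, uppercases
#' the sequence, and normalizes the alphabet. With
#' \code{alphabet = "dna_to_rna"} every T is mapped to U; with
#' \code{"strict"} the sequence must already be over \{A, C, G, U\}.
#' Ambiguity codes (N, R, Y, ...) have no slot in a 4-row PWM: by default
#' they raise an error naming the record; with \code{skipAmbiguous = TRUE}
#' the offending record is dropped with a warning instead.
#'
#' @param path path to a FASTA file.
#' @param alphabet \code{"dna_to_rna"} (default) or \code{"strict"}.
#' @param skipAmbiguous drop records containing letters outside the allowed
#'   alphabet instead of erroring.
#' @return data.frame with columns \code{id} and \code{sequence}, in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT"), fa)
#' readMatureFasta(fa)
#' @export
readMatureFasta <- function(path, alphabet = c("dna_to_rna", "strict"),
                            skipAmbiguous = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (alphabet == "dna_to_rna") seqs <- chartr("T", "U", seqs)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    offending <- vapply(seqs[bad], function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      paste(unique(ch[!ch %in% c("A", "C", "G", "U")]), collapse = ",")
    }, character(1))
    msg <- paste0(ids[bad], " (", offending, ")", collapse = "; ")
    if (skipAmbiguous) {
      warning("skipping ", sum(bad),
              " record(s) with disallowed characters: ", msg)
      ids <- ids[!bad]; seqs <- seqs[!bad]
    } else {
      stop("records with characters outside the allowed alphabet: ", msg)
    }
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Extract the seed window from mature sequences
#'
#' Returns the substring covering 1-based positions
#' \code{start .. start + width - 1} inclusive of each sequence. The
#' default window, positions 2-7, is the canonical miRNA seed region.
#'
#' @param sequences character vector of full sequences.
#' @param start 1-based start position (default 2).
#' @param width window length (default 6).
#' @param ids optional ids used in error messages.
#' @return character vector of seed strings.
#' @examples
#' extractSeed("UGAGGUAGUAGGUUGUAUAGUU")  # "GAGGUA"
#' @export
extractSeed <- function(sequences, start = 2L, width = 6L, ids = NULL) {
  end <- start + width - 1L
  short <- nchar(sequences) < end
  if (any(short)) {
    who <- if (is.null(ids)) which(short) else ids[short]
    stop("sequence(s) too short for seed window [", start, ", ", end, "]: ",
         paste(utils::head(who, 5), collapse = ", "),
         " (lengths ", paste(utils::head(nchar(sequences)[short], 5),
                             collapse = ", "), ")")
  }
  substr(sequences, start, end)
}

#' Build a SeedSet straight from a FASTA file
#'
#' Convenience chain: \code{\link{readMatureFasta}} then
#' \code{\link{extractSeed}}, with an optional id-prefix whitelist (e.g.
#' \code{c("hsa-", "mmu-")}) standing in for taxonomy-based species
#' filtering.
#'
#' @inheritParams readMatureFasta
#' @inheritParams extractSeed
#' @param prefixFilter optional character vector of id prefixes to keep.
#' @return a \linkS4class{SeedSet}.
#' @export
seedSetFromFasta <- function(path, start = 2L, width = 6L,
                             alphabet = c("dna_to_rna", "strict"),
                             skipAmbiguous = FALSE, prefixFilter = NULL) {
  recs <- readMatureFasta(path, alphabet = alphabet,
                          skipAmbiguous = skipAmbiguous)
  if (!is.null(prefixFilter) && nrow(recs) > 0) {
    pat <- paste0("^(", paste(prefixFilter, collapse = "|"), ")")
    recs <- recs[grepl(pat, recs$id), , drop = FALSE]
  }
  SeedSet(recs$id, extractSeed(recs$sequence, start, width, ids = recs$id))
}

#' Read a reference family table
#'
#' Tab-separated file with columns family_id, member_id and an optional
#' third accession column; lines starting with \code{#} are ignored. A
#' member id may appear in at most one family.
#'
#' @param path path to the TSV file.
#' @return a \linkS4class{FamilyTable}.
#' @export
readFamilyTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(nzchar(raw) & !startsWith(raw, "#")))
    stop("empty family table: ", path)
  tab <- tryCatch(
    utils::read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse family table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(tab) < 2) stop("family table needs >= 2 columns: ", path)
  fam <- split(tab[[2]], tab[[1]])
  acc <- character()
  if (ncol(tab) >= 3) {
    acc <- vapply(split(tab[[3]], tab[[1]]), `[[`, character(1), 1L)
  }
  new("FamilyTable", families = fam, accessions = acc)
}

#' Write a hard assignment with posterior confidences to TSV
#'
#' Columns: id, seed, group_index (0-based), max_responsibility (6 decimal
#' places); one row per record in input order.
#'
#' @param grouping a \linkS4class{Grouping}.
#' @param seedSet the \linkS4class{SeedSet} that was grouped.
#' @param responsibilities N x k row-stochastic posterior matrix in the
#'   same record order (may be NULL; then max_responsibility is 1).
#' @param path output file path.
#' @param groupPrefix optional display prefix; when given, an extra
#'   group_label column renders 1-based names such as "c10".
#' @return the path, invisibly.
#' @export
writeAssignments <- function(grouping, seedSet, responsibilities = NULL,
                             path, groupPrefix = NULL) {
  labels <- groupLabels(grouping)[seqIds(seedSet)]
  maxresp <- if (is.null(responsibilities)) rep(1, length(labels))
             else apply(responsibilities, 1L, max)
  df <- data.frame(id = seqIds(seedSet), seed = unname(seedStrings(seedSet)),
                   group_index = unname(labels) - 1L,
                   max_responsibility = sprintf("%.6f", maxresp))
  if (!is.null(groupPrefix))
    df$group_label <- paste0(groupPrefix, unname(labels))
  if (length(labels) == 0)
    df <- df[0, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an assignments TSV back into a Grouping and SeedSet
#'
#' Inverse of \code{\link{writeAssignments}} on (id, seed, group_index).
#'
#' @param path path to an assignments TSV.
#' @param k number of groups; defaults to the largest index present plus 1.
#' @return list with elements \code{grouping} and \code{seedSet}.
#' @export
readAssignments <- function(path, k = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  labels <- stats::setNames(df$group_index + 1L, df$id)
  if (is.null(k)) k <- if (length(labels)) max(labels) else 1L
  list(grouping = Grouping(labels, k = k),
       seedSet = SeedSet(df$id, df$seed))
}

#' Write per-group score summaries to TSV
#'
#' Columns: group_index (0-based), n_members, mean_score_S, mean_score_M.
#'
#' @param summaries data.frame from \code{\link{groupSummaries}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGroupScores <- function(summaries, path) {
  out <- data.frame(group_index = summaries$group - 1L,
                    n_members = summaries$n_members,
                    mean_score_S = summaries$mean_score_S,
                    mean_score_M = summaries$mean_score_M)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a family-enrichment table to TSV
#'
#' Columns: family_id, best_group (0-based), overlap, family_size,
#' enrichment ("overlap/family_size"); sorted by family_id.
#'
#' @param enrich data.frame from \code{\link{familyEnrichment}}.
#' @param path output file path.
#' @param groupPrefix optional display prefix; adds a 1-based group_label
#'   column such as "c10".
#' @return the path, invisibly.
#' @export
writeEnrichment <- function(enrich, path, groupPrefix = NULL) {
  out <- enrich
  if (!is.null(groupPrefix))
    out$group_label <- paste0(groupPrefix, out$best_group)
  out$best_group <- out$best_group - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
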