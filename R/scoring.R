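## Cluster-validation scores (silhouette over Hamming distances, the
## information-weighted matrix match score), per-group summaries, baseline
## groupings, and reference-family enrichment.

#' Hamming distance between equal-length sequences
#'
#' @param a,b character vectors of equal-length strings (recycled
#'   pairwise).
#' @return integer vector of per-pair mismatch counts, in [0, L].
#' @examples
#' hammingDistance("AUACAA", "AUACAC")  # 1
#' @export
hammingDistance <- function(a, b) {
  if (any(nchar(a) != nchar(b)))
    stop("Hamming distance needs equal-length strings")
  mapply(function(x, y) {
    sum(strsplit(x, "", fixed = TRUE)[[1]] !=
          strsplit(y, "", fixed = TRUE)[[1]])
  }, a, b, USE.NAMES = FALSE)
}

#' Pairwise Hamming distance matrix of a seed set
#'
#' Computed as half the Manhattan distance between one-hot encodings
#' (every mismatching position contributes 2 there).
#'
#' @param seedSet a \linkS4class{SeedSet} or character vector of
#'   equal-length seeds.
#' @return symmetric integer N x N matrix with record ids as dimnames.
#' @export
hammingDistanceMatrix <- function(seedSet) {
  oh <- .oneHot(.encodeSeeds(seedSet))
  D <- as.matrix(stats::dist(oh, method = "manhattan")) / 2
  if (is(seedSet, "SeedSet"))
    dimnames(D) <- list(seqIds(seedSet), seqIds(seedSet))
  D
}

#' Empirical base-frequency profile of a group of seeds
#'
#' Raw per-column base frequencies (no pseudocounts), the matrix the match
#' score is evaluated against. Built from counts, so a perfectly conserved
#' group reaches frequency 1 exactly.
#'
#' @param seeds a \linkS4class{SeedSet} or character vector of seeds.
#' @return a \linkS4class{GroupProfile}.
#' @export
groupProfile <- function(seeds) {
  enc <- .encodeSeeds(seeds)
  if (nrow(enc) == 0) stop("cannot profile an empty group")
  f <- apply(enc, 2L, tabulate, nbins = 4L) / nrow(enc)
  dimnames(f) <- list(.BASES, NULL)
  new("GroupProfile", freqs = f, nMembers = nrow(enc))
}

#' @rdname isDegenerate
#' @export
setMethod("isDegenerate", "GroupProfile", function(x) {
  all(abs(x@freqs - 0.25) < 1e-12)
})

#' Match score of seeds against a frequency profile
#'
#' The TRANSFAC-style matrix similarity
#' \deqn{Score_M = \frac{\sum_v I(v) f_{v,b(v)} - \sum_v I(v) f_v^{min}}
#'                      {\sum_v I(v) f_v^{max} - \sum_v I(v) f_v^{min}}}
#' where b(v) is the seed's base at position v, f are the profile's
#' empirical frequencies and I(v) is the per-column information content
#' (natural log). Weighting by I(v) suppresses mismatches at highly
#' conserved positions relative to unconserved ones. The value lies in
#' [0, 1]; a profile whose columns are all uniform has a zero denominator
#' and scores 0 by convention (see \code{\link{isDegenerate}}).
#'
#' @param seeds a \linkS4class{SeedSet} or character vector of seeds of
#'   length L.
#' @param profile a \linkS4class{GroupProfile} with L columns.
#' @return numeric vector of scores in [0, 1].
#' @export
matchScore <- function(seeds, profile) {
  enc <- .encodeSeeds(seeds)
  if (nrow(enc) == 0) return(numeric(0))
  L <- ncol(profile@freqs)
  if (ncol(enc) != L)
    stop("seed length must equal the profile width L = ", L)
  info <- columnInformation(profile)
  fmin <- apply(profile@freqs, 2L, min)
  fmax <- apply(profile@freqs, 2L, max)
  denom <- sum(info * fmax) - sum(info * fmin)
  if (denom <= 0) return(rep(0, nrow(enc)))
  fb <- matrix(profile@freqs[cbind(as.vector(enc),
                                   rep(seq_len(L), each = nrow(enc)))],
               nrow = nrow(enc))
  num <- as.vector(fb %*% info) - sum(info * fmin)
  num / denom
}

## Align a grouping's labels to a seed set's record order; error on
## records missing from the grouping.
.alignedLabels <- function(grouping, seedSet) {
  labels <- groupLabels(grouping)[seqIds(seedSet)]
  if (anyNA(labels))
    stop("records absent from the grouping: ",
         paste(utils::head(seqIds(seedSet)[is.na(labels)], 5),
               collapse = ", "))
  unname(labels)
}

#' Per-record silhouette scores over Hamming distances
#'
#' Score_S(X_m) = (beta - alpha) / max(alpha, beta), where alpha is the
#' mean Hamming distance of X_m to the other members of its own group
#' (excluding itself) and beta is the minimum over other non-empty groups
#' of the mean distance to that group's members. Values lie in [-1, 1]. A
#' record alone in its group scores 0 (alpha undefined), as does a record
#' with alpha = beta = 0.
#'
#' @param grouping a \linkS4class{Grouping} with at least 2 non-empty
#'   groups.
#' @param seedSet the \linkS4class{SeedSet} that was grouped.
#' @return named numeric vector, one score per record.
#' @export
silhouetteScores <- function(grouping, seedSet) {
  labels <- .alignedLabels(grouping, seedSet)
  present <- sort(unique(labels))
  if (length(present) < 2)
    stop("silhouette needs at least 2 non-empty groups")
  D <- hammingDistanceMatrix(seedSet)
  n <- length(labels)
  idxByGroup <- split(seq_len(n), labels)
  scores <- numeric(n)
  for (m in seq_len(n)) {
    own <- setdiff(idxByGroup[[as.character(labels[m])]], m)
    if (length(own) == 0) {
      scores[m] <- 0
      next
    }
    alpha <- mean(D[m, own])
    beta <- min(vapply(idxByGroup[names(idxByGroup) !=
                                    as.character(labels[m])],
                       function(idx) mean(D[m, idx]), numeric(1)))
    mx <- max(alpha, beta)
    scores[m] <- if (mx == 0) 0 else (beta - alpha) / mx
  }
  stats::setNames(scores, seqIds(seedSet))
}

#' Per-group score summaries
#'
#' For every non-empty group: member count, mean silhouette score of its
#' members, and mean match score of its members against the group's own
#' empirical frequency profile. With fewer than 2 non-empty groups the
#' silhouette is undefined and reported as NA.
#'
#' @param grouping a \linkS4class{Grouping}.
#' @param seedSet the grouped \linkS4class{SeedSet}.
#' @return data.frame with columns group (1-based), n_members,
#'   mean_score_S, mean_score_M.
#' @export
groupSummaries <- function(grouping, seedSet) {
  labels <- .alignedLabels(grouping, seedSet)
  present <- sort(unique(labels))
  sil <- if (length(present) >= 2) silhouetteScores(grouping, seedSet)
         else NULL
  seeds <- unname(seedStrings(seedSet))
  rows <- lapply(present, function(g) {
    idx <- which(labels == g)
    prof <- groupProfile(seeds[idx])
    data.frame(group = g, n_members = length(idx),
               mean_score_S = if (is.null(sil)) NA_real_
                              else mean(sil[idx]),
               mean_score_M = mean(matchScore(seeds[idx], prof)))
  })
  do.call(rbind, rows)
}

#' Global mean scores over all sequences
#'
#' Means over all records (not means of group means) of the silhouette
#' score and of the match score against each record's own group profile.
#'
#' @inheritParams groupSummaries
#' @return named numeric vector with elements score_S and score_M (score_S
#'   is NA when fewer than 2 groups are non-empty).
#' @export
overallScores <- function(grouping, seedSet) {
  labels <- .alignedLabels(grouping, seedSet)
  present <- sort(unique(labels))
  seeds <- unname(seedStrings(seedSet))
  mScores <- numeric(length(labels))
  for (g in present) {
    idx <- which(labels == g)
    mScores[idx] <- matchScore(seeds[idx], groupProfile(seeds[idx]))
  }
  sS <- if (length(present) >= 2)
    mean(silhouetteScores(grouping, seedSet)) else NA_real_
  c(score_S = sS, score_M = mean(mScores))
}

#' Uniform random baseline grouping
#'
#' Each record is assigned independently and uniformly among k groups;
#' deterministic per seed.
#'
#' @param ids character vector of record ids.
#' @param k number of groups (>= 1).
#' @param rngSeed integer seed.
#' @return a \linkS4class{Grouping}.
#' @export
randomGrouping <- function(ids, k, rngSeed = 1L) {
  if (k < 1) stop("k must be >= 1")
  labels <- .withSeed(rngSeed, sample.int(k, length(ids), replace = TRUE))
  Grouping(stats::setNames(labels, ids), k = as.integer(k))
}

#' Average-linkage hierarchical baseline grouping
#'
#' Agglomerative clustering (UPGMA) on pairwise Hamming distances, cut to
#' exactly k clusters. Deterministic; ties follow \code{\link[stats]{hclust}}
#' merge order.
#'
#' @param seedSet a \linkS4class{SeedSet} with at least k records.
#' @param k number of clusters.
#' @return a \linkS4class{Grouping}.
#' @export
hierarchicalGrouping <- function(seedSet, k) {
  n <- length(seedSet)
  if (n < k) stop("need at least k = ", k, " records, got ", n)
  oh <- .oneHot(.encodeSeeds(seedSet))
  d <- stats::dist(oh, method = "manhattan") / 2
  labels <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  Grouping(stats::setNames(as.integer(labels), seqIds(seedSet)),
           k = as.integer(k))
}

#' Enrichment of reference families within fitted groups
#'
#' For every reference family, the group containing the largest number of
#' its members, the overlap count, and the family size, with the
#' "overlap/family_size" display string used in enrichment tables. Members
#' absent from the grouping still count toward family_size and are
#' reported in n_missing; a family with no member present at all is an
#' error.
#'
#' @param grouping a \linkS4class{Grouping}.
#' @param families a \linkS4class{FamilyTable}.
#' @return data.frame sorted by family_id with columns family_id,
#'   best_group (1-based; ties to the lowest index), overlap, family_size,
#'   enrichment, n_missing.
#' @export
familyEnrichment <- function(grouping, families) {
  labels <- groupLabels(grouping)
  fam <- familyList(families)
  rows <- lapply(sort(names(fam)), function(fid) {
    members <- fam[[fid]]
    present <- members[members %in% names(labels)]
    if (length(present) == 0)
      stop("family ", fid, " has no member in the grouping; missing: ",
           paste(members, collapse = ", "))
    counts <- tabulate(labels[present], nbins = nGroups(grouping))
    best <- which.max(counts)                    # ties -> lowest index
    data.frame(family_id = fid, best_group = as.integer(best),
               overlap = counts[best], family_size = length(members),
               enrichment = paste0(counts[best], "/", length(members)),
               n_missing = length(members) - length(present))
  })
  do.call(rbind, rows)
}
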