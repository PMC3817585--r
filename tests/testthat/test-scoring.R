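test_that("Hamming distance counts mismatching positions", {
  expect_equal(hammingDistance("AUACAA", "AUACAA"), 0L)
  expect_equal(hammingDistance("AUACAA", "AUACAC"), 1L)
  expect_equal(hammingDistance("AAAAAA", "UUUUUU"), 6L)
  expect_error(hammingDistance("AAA", "AAAA"), "equal-length")

  set.seed(5)
  a <- randomSeedStrings(20); b <- randomSeedStrings(20)
  expect_equal(hammingDistance(a, b),
               mapply(oracleHamming, a, b, USE.NAMES = FALSE))
  ss <- SeedSet(paste0("s", 1:8), randomSeedStrings(8))
  D <- hammingDistanceMatrix(ss)
  expect_equal(unname(D[3, 7]),
               oracleHamming(seedStrings(ss)[[3]], seedStrings(ss)[[7]]))
})

test_that("silhouette hits its exact extremes and conventions", {
  ss <- SeedSet(paste0("s", 1:4),
                c("AAAAAA", "AAAAAA", "CCCCCC", "CCCCCC"))
  g <- Grouping(setNames(c(1L, 1L, 2L, 2L), seqIds(ss)), k = 2L)
  expect_equal(unname(silhouetteScores(g, ss)), rep(1, 4))

  # singleton cluster scores 0 by convention
  g2 <- Grouping(setNames(c(1L, 1L, 1L, 2L), seqIds(ss)), k = 2L)
  expect_equal(unname(silhouetteScores(g2, ss))[4], 0)

  # fewer than 2 non-empty groups is an error
  g3 <- Grouping(setNames(rep(1L, 4), seqIds(ss)), k = 3L)
  expect_error(silhouetteScores(g3, ss), "2 non-empty")
})

test_that("silhouette matches the O(N^2) brute force and cluster::silhouette", {
  set.seed(9)
  seeds <- randomSeedStrings(15)
  labels <- sample(1:3, 15, replace = TRUE)
  labels[1:3] <- 1:3  # guarantee non-empty groups
  ss <- SeedSet(paste0("s", 1:15), seeds)
  g <- Grouping(setNames(labels, seqIds(ss)), k = 3L)
  mine <- unname(silhouetteScores(g, ss))
  expect_equal(mine, oracleSilhouette(seeds, labels))
  skip_if_not_installed("cluster")
  ref <- cluster::silhouette(labels, dist(seedmix:::.oneHot(
    seedmix:::.encodeSeeds(ss)), method = "manhattan") / 2)
  expect_equal(mine, unname(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("match score formula hits its exact extremes", {
  prof <- groupProfile(rep("AUACAA", 10))
  expect_equal(matchScore("AUACAA", prof), 1)
  expect_false(isDegenerate(prof))
  expect_equal(consensusString(prof), "AUACAA")

  uni <- groupProfile(c("AAAAAA", "CCCCCC", "GGGGGG", "UUUUUU"))
  expect_true(isDegenerate(uni))
  expect_equal(matchScore("AUACAA", uni), 0)

  expect_error(matchScore("AUA", prof), "length")
})

test_that("match score agrees with the explicit formula oracle", {
  grp <- c("AAAAAA", "AAAAAC", "AAAACC")
  prof <- groupProfile(grp)
  expect_equal(matchScore("AAAAAA", prof), oracleMatchScore("AAAAAA", grp))
  set.seed(13)
  for (i in 1:20) {
    grp <- randomSeedStrings(sample(2:12, 1))
    prof <- groupProfile(grp)
    probe <- randomSeedStrings(1)
    expect_equal(matchScore(probe, prof), oracleMatchScore(probe, grp))
    expect_gte(matchScore(probe, prof), 0)
    expect_lte(matchScore(probe, prof), 1)
    # consensus of a non-degenerate profile scores exactly 1
    if (!isDegenerate(prof))
      expect_equal(matchScore(consensusString(prof), prof), 1)
  }
})

test_that("group summaries aggregate both scores per non-empty group", {
  ss <- SeedSet(paste0("s", 1:4),
                c("AAAAAA", "AAAAAA", "CCCCCC", "CCCCCC"))
  g <- Grouping(setNames(c(1L, 1L, 2L, 2L), seqIds(ss)), k = 2L)
  summ <- groupSummaries(g, ss)
  expect_equal(summ$mean_score_S, c(1, 1))
  expect_equal(summ$mean_score_M, c(1, 1))
  expect_equal(summ$n_members, c(2L, 2L))
  expect_equal(overallScores(g, ss), c(score_S = 1, score_M = 1))

  # one non-empty group: silhouette is not applicable
  g1 <- Grouping(setNames(rep(1L, 4), seqIds(ss)), k = 2L)
  expect_true(is.na(groupSummaries(g1, ss)$mean_score_S))
  expect_true(is.na(overallScores(g1, ss)[["score_S"]]))

  # random labels on random seeds match brute-force recomputation
  set.seed(17)
  seeds <- randomSeedStrings(12)
  labels <- c(1L, 2L, sample(1:2, 10, replace = TRUE))
  ss2 <- SeedSet(paste0("r", 1:12), seeds)
  g2 <- Grouping(setNames(labels, seqIds(ss2)), k = 2L)
  summ2 <- groupSummaries(g2, ss2)
  sil <- oracleSilhouette(seeds, labels)
  for (grp in 1:2) {
    idx <- which(labels == grp)
    expect_equal(summ2$mean_score_S[grp], mean(sil[idx]))
    expect_equal(summ2$mean_score_M[grp],
                 mean(vapply(seeds[idx], oracleMatchScore, numeric(1),
                             groupSeeds = seeds[idx])))
  }
})

test_that("random baseline is seeded and roughly balanced", {
  ids <- paste0("s", 1:4000)
  g1 <- randomGrouping(ids, k = 4, rngSeed = 3)
  g2 <- randomGrouping(ids, k = 4, rngSeed = 3)
  expect_identical(groupLabels(g1), groupLabels(g2))
  sizes <- tabulate(groupLabels(g1), 4)
  expect_true(all(abs(sizes - 1000) < 4 * sqrt(4000)))
  expect_equal(unname(groupLabels(randomGrouping(ids[1:5], 1, 1))),
               rep(1L, 5))
})

test_that("average-linkage baseline recovers separated blocks", {
  ss <- SeedSet(paste0("s", 1:6),
                c("AAAAAA", "AAAAAA", "AAAAAA", "UUUUUU", "UUUUUU", "UUUUUU"))
  g <- hierarchicalGrouping(ss, k = 2)
  lab <- unname(groupLabels(g))
  expect_equal(lab[1:3], rep(lab[1], 3))
  expect_equal(lab[4:6], rep(lab[4], 3))
  expect_false(lab[1] == lab[4])

  gN <- hierarchicalGrouping(ss, k = 6)
  expect_equal(sort(unname(groupLabels(gN))), 1:6)
  expect_error(hierarchicalGrouping(ss, k = 7), "at least")

  # hand-worked average-linkage trace: {AAAAAA,AAAAAC} merge at d=1,
  # {GGGGGG,GGGGGU} at d=1, then singleton UUUUUU joins the G-block
  # (mean distance 5.5 vs 6 to the A-block) before the final merge
  ss2 <- SeedSet(paste0("t", 1:5),
                 c("AAAAAA", "AAAAAC", "GGGGGG", "GGGGGU", "UUUUUU"))
  g3 <- hierarchicalGrouping(ss2, k = 2)
  lab3 <- unname(groupLabels(g3))
  expect_equal(lab3[1], lab3[2])
  expect_equal(lab3[3], lab3[4])
  expect_equal(lab3[5], lab3[3])
  expect_false(lab3[1] == lab3[3])
})

test_that("mixture groupings separate better than random ones", {
  # statistical property over seeded trials on well-separated data
  wins <- 0L
  for (trial in 1:20) {
    truth <- sampleMixture(k = 3, n = 90, rngSeed = 500 + trial)
    fit <- fitMixture(truth@seeds, k = 3, rngSeed = trial)
    gm <- assignGroups(fit)
    gr <- randomGrouping(seqIds(truth@seeds), k = 3, rngSeed = trial)
    sM <- mean(silhouetteScores(gm, truth@seeds))
    sR <- mean(silhouetteScores(gr, truth@seeds))
    if (sM > sR) wins <- wins + 1L
  }
  expect_equal(wins, 20L)
})

test_that("family enrichment counts the best-overlap group", {
  g <- Grouping(setNames(c(1L, 1L, 2L, 2L, 2L, 1L, 2L), paste0("m", 1:7)),
                k = 3L)
  fam <- new("FamilyTable",
             families = list(whole = paste0("m", 3:5),
                             split = c("m1", "m2", "m7"),
                             part = c("m6", "m9")),
             accessions = character())
  e <- familyEnrichment(g, fam)
  expect_equal(e$family_id, c("part", "split", "whole"))  # sorted
  expect_equal(e[e$family_id == "whole", "enrichment"], "3/3")
  expect_equal(e[e$family_id == "whole", "best_group"], 2L)
  expect_equal(e[e$family_id == "split", "enrichment"], "2/3")
  expect_equal(e[e$family_id == "split", "best_group"], 1L)
  expect_equal(e[e$family_id == "part", "n_missing"], 1L)

  # overlap tie breaks to the lowest group index
  fam2 <- new("FamilyTable", families = list(tie = c("m1", "m3")),
              accessions = character())
  expect_equal(familyEnrichment(g, fam2)$best_group, 1L)

  fam3 <- new("FamilyTable", families = list(gone = "zz"),
              accessions = character())
  expect_error(familyEnrichment(g, fam3), "no member.*zz")
})
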