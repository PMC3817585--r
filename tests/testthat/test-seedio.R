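writeFasta <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

test_that("FASTA reading normalizes case and alphabet", {
  fa <- writeFasta(c(">a desc", "ugagg"))
  recs <- readMatureFasta(fa)
  expect_equal(recs$id, "a")
  expect_equal(recs$sequence, "UGAGG")

  fa <- writeFasta(c(">a", "ACGT"))
  expect_equal(readMatureFasta(fa, alphabet = "dna_to_rna")$sequence, "ACGU")
  expect_error(readMatureFasta(fa, alphabet = "strict"), "a \\(T\\)")

  # wrapped lines are joined
  fa <- writeFasta(c(">x", "ACG", "UAC"))
  expect_equal(readMatureFasta(fa)$sequence, "ACGUAC")

  # empty file -> empty result
  fa <- writeFasta(character(0))
  expect_equal(nrow(readMatureFasta(fa)), 0)
})

test_that("FASTA errors name offenders; skipAmbiguous drops with warning", {
  fa <- writeFasta(c(">a", "ACGU", ">a", "GGGG"))
  expect_error(readMatureFasta(fa), "duplicate.*a")

  fa <- writeFasta(c(">ok", "ACGU", ">amb", "ACGN"))
  expect_error(readMatureFasta(fa), "amb \\(N\\)")
  expect_warning(recs <- readMatureFasta(fa, skipAmbiguous = TRUE),
                 "skipping 1")
  expect_equal(recs$id, "ok")

  expect_error(readMatureFasta(tempfile()), "file not found")
})

test_that("seed extraction follows the 1-based positions 2-7 convention", {
  expect_equal(extractSeed("UGAGGUAGUAGGUUGUAUAGUU"), "GAGGUA")
  expect_equal(extractSeed("ACGUAC", start = 2, width = 5), "CGUAC")
  expect_error(extractSeed("ACG", ids = "short1"), "short1.*lengths 3")
})

test_that("seedSetFromFasta chains extraction and the prefix whitelist", {
  fa <- writeFasta(c(">hsa-x", "TGAGGTAGTAGGTTGTATAGTT",
                     ">dme-y", "AAAAAAAAAAAAAAAAAAAAAA"))
  ss <- seedSetFromFasta(fa)
  expect_equal(length(ss), 2L)
  expect_equal(unname(seedStrings(ss))[1], "GAGGUA")
  ss <- seedSetFromFasta(fa, prefixFilter = "hsa-")
  expect_equal(seqIds(ss), "hsa-x")
})

test_that("family tables enforce single membership", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "let-7\thsa-let-7a\tMIPF0000002",
               "let-7\tmmu-let-7b\tMIPF0000002", "mir-15\tm1"), tf)
  fam <- readFamilyTable(tf)
  expect_equal(sort(names(familyList(fam))), c("let-7", "mir-15"))
  expect_equal(length(familyList(fam)[["let-7"]]), 2L)
  expect_equal(length(familyList(fam)[["mir-15"]]), 1L)

  writeLines(c("f1\tm1", "f2\tm1"), tf)
  expect_error(readFamilyTable(tf), "m1")

  writeLines(character(0), tf)
  expect_error(readFamilyTable(tf), "empty")
})

test_that("assignments round-trip and format responsibilities", {
  ss <- SeedSet(c("a", "b", "c"), c("AAAAAA", "CCCCCC", "AAAAAC"))
  g <- Grouping(c(a = 1L, b = 2L, c = 1L), k = 2L)
  z <- matrix(c(1, 0, 0.75, 0, 1, 0.25), 3, 2,
              dimnames = list(c("a", "b", "c"), NULL))
  path <- tempfile(fileext = ".tsv")
  writeAssignments(g, ss, z, path)
  lines <- readLines(path)
  expect_length(lines, 4L)  # header + 3 records
  expect_match(lines[2], "1\\.000000$")
  expect_match(lines[4], "0\\.750000$")

  rt <- readAssignments(path)
  expect_equal(seqIds(rt$seedSet), seqIds(ss))
  expect_equal(unname(seedStrings(rt$seedSet)), unname(seedStrings(ss)))
  expect_equal(groupLabels(rt$grouping), groupLabels(g))

  # empty grouping -> header-only file
  writeAssignments(Grouping(setNames(integer(), character()), k = 2L),
                   SeedSet(character(), character()), NULL, path)
  expect_length(readLines(path), 1L)
})

test_that("group labels can be rendered with a display prefix", {
  ss <- SeedSet(c("a", "b"), c("AAAAAA", "CCCCCC"))
  g <- Grouping(c(a = 10L, b = 2L), k = 10L)
  path <- tempfile(fileext = ".tsv")
  writeAssignments(g, ss, NULL, path, groupPrefix = "c")
  tab <- read.delim(path)
  expect_equal(tab$group_label, c("c10", "c2"))
  expect_equal(tab$group_index, c(9L, 1L))
})
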