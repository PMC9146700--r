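test_that("identity and forced-gap alignments behave as expected", {
  pa <- globalAlign("AAATTT", "AAATTT")
  expect_equal(unname(alnRows(pa)), c("AAATTT", "AAATTT"))
  expect_equal(alnScore(pa), 12)

  pa2 <- globalAlign("AAA", "AA")
  rows <- unname(alnRows(pa2))
  expect_equal(nchar(rows[1]), 3L)
  # gap leftmost in the A run after normalisation
  expect_equal(rows[2], "-AA")

  expect_error(globalAlign("", "ACGT"), class = "mitotrio_align_error")
})

test_that("banded scores equal the unbanded dynamic-programming optimum", {
  set.seed(11)
  for (r in 1:50) {
    p <- random_pair(n = 300L, subst = 0.02)
    got <- alnScore(globalAlign(p$a, p$b, normalise = FALSE))
    expect_equal(got, oracle_score(p$a, p$b), tolerance = 1e-9)
  }
})

test_that("alignment invariants: symmetry, column bounds, recoverability", {
  set.seed(12)
  for (r in 1:10) {
    p <- random_pair(n = 200L)
    ab <- globalAlign(p$a, p$b)
    ba <- globalAlign(p$b, p$a)
    expect_equal(alnScore(ab), alnScore(ba))
    rows <- unname(alnRows(ab))
    expect_gte(nchar(rows[1]), max(nchar(p$a), nchar(p$b)))
    expect_identical(gsub("-", "", rows[1]), p$a)
    expect_identical(gsub("-", "", rows[2]), p$b)
    # no gap/gap columns; maps monotone
    m1 <- columnMap(rows[1]); m2 <- columnMap(rows[2])
    expect_true(all(m1 > 0 | m2 > 0))
    expect_true(!is.unsorted(m1[m1 > 0]))
    expect_true(!is.unsorted(m2[m2 > 0]))
  }
})

test_that("gap runs are shifted maximally leftward in repeat context", {
  pa <- globalAlign("TTTTTTACG", "TTTTACG")
  expect_equal(unname(alnRows(pa))[2], "--TTTTACG")
  pa2 <- globalAlign("ACGTATATATCCA", "ACGTATATCCA")
  expect_equal(unname(alnRows(pa2))[2], "ACG--TATATCCA")
})

test_that("rotation anchoring recovers the applied offset", {
  g <- fix_base(1)$genome
  s <- genomeSeq(g)
  n <- nchar(s)
  expect_equal(rotateToAnchor(s, s)$offset, 0L)
  expect_identical(rotateSeq(rotateSeq(s, 1234L), n - 1234L), s)
  set.seed(5)
  for (r in sample(n - 1L, 3L)) {
    rot <- rotateSeq(s, r)
    rec <- rotateToAnchor(rot, s)
    expect_equal(rec$offset, (n - r) %% n)
    expect_identical(genomeSeq(rec$genome), s)
  }
  # divergent sequence with no shared seed errors out
  expect_error(rotateToAnchor(paste(rep("ACGG", 50), collapse = ""),
                              paste(rep("TTAA", 50), collapse = "")),
               class = "mitotrio_align_error")
})

test_that("anchorMerge: identity merge, identical rows, input recovery", {
  p <- random_pair(n = 150L)
  ab <- globalAlign(p$a, p$b, ids = c("A", "B"))
  m1 <- anchorMerge(list(ab))
  expect_identical(unname(alnRows(m1)), unname(alnRows(ab)))

  ident <- globalAlign(p$a, p$a, ids = c("A", "A2"))
  ident2 <- globalAlign(p$a, p$a, ids = c("A", "A3"))
  m2 <- anchorMerge(list(ident, ident2))
  expect_equal(nchar(alnRows(m2)[[1]]), nchar(p$a))
  expect_true(all(!grepl("-", unlist(alnRows(m2)))))

  # rows always ungap to their inputs
  pb <- random_pair(n = 150L)
  ac <- globalAlign(p$a, pb$b, ids = c("A", "C"))
  m3 <- anchorMerge(list(ab, ac))
  rows <- alnRows(m3)
  expect_identical(gsub("-", "", rows[["A"]]), p$a)
  expect_identical(gsub("-", "", rows[["B"]]), p$b)
  expect_identical(gsub("-", "", rows[["C"]]), pb$b)
  expect_error(anchorMerge(list(ab, globalAlign(pb$a, pb$b))),
               class = "mitotrio_align_error")
})

test_that("planted events occupy contiguous column runs in the trio MSA", {
  res <- fix_pipeline(1)
  ev <- res$events
  expect_true(all(ev$col_end >= ev$col_start))
  # events never overlap in column space
  ord <- ev[order(ev$col_start), ]
  expect_true(all(diff(ord$col_start) > 0))
  expect_true(all(ord$col_start[-1] > ord$col_end[-nrow(ord)]))
  # per-row ungapping recovers the rotated-back inputs
  tr <- fix_trio(1)
  rows <- alnRows(res$msa)
  # near-identical genomes: column count stays close to the longest input
  maxlen <- max(vapply(tr$genomes, genomeLength, integer(1)))
  expect_lt(nchar(rows[[1]]), 1.05 * maxlen)
  rot <- ledgerRotations(tr$ledger)
  for (id in names(rows)) {
    n <- nchar(genomeSeq(tr$genomes[[id]]))
    expected <- rotateSeq(genomeSeq(tr$genomes[[id]]),
                          (n - rot[[id]]) %% n)
    expect_identical(gsub("-", "", rows[[id]]), expected)
  }
})

test_that("gapped FASTA export round-trips rows", {
  p <- random_pair(n = 120L)
  ab <- globalAlign(p$a, p$b, ids = c("x", "y"))
  path <- withr::local_tempfile(fileext = ".fasta")
  writeGappedFasta(ab, path)
  ss <- Biostrings::readBStringSet(path)
  expect_equal(as.character(ss[["x"]]), alnRows(ab)[["x"]])
  expect_equal(as.character(ss[["y"]]), alnRows(ab)[["y"]])
})
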