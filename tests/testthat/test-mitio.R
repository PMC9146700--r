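test_that("GenBank writer/reader round-trips sequence and features", {
  g <- fix_base(1)$genome
  path <- withr::local_tempfile(fileext = ".gb")
  writeGenBank(g, path)
  g2 <- readGenBank(path)
  expect_identical(genomeSeq(g2), genomeSeq(g))
  expect_true(isCircular(g2))
  cols <- c("name", "fclass", "strand", "start", "end")
  expect_identical(featureTable(g2)[, cols], featureTable(g)[, cols])

  # wrapped feature: rotate so the control region spans the origin
  ctrl <- featureTable(g)[featureTable(g)$fclass == "control", ]
  gr <- rotateGenome(g, ctrl$start + 100L)
  ftr <- featureTable(gr)
  wrapped <- ftr[ftr$fclass == "control", ]
  expect_true(wrapped$end < wrapped$start)
  writeGenBank(gr, path)
  gr2 <- readGenBank(path)
  expect_identical(featureTable(gr2)[, cols], ftr[, cols])
  expect_identical(genomeSeq(gr2), genomeSeq(gr))
})

test_that("GenBank parser handles minimal, malformed and ambiguous input", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       mini 12 bp DNA circular INV",
               "ORIGIN",
               "        1 acgtacgtac gt",
               "//"), path)
  g <- readGenBank(path, infer_control = FALSE)
  expect_equal(genomeLength(g), 12L)
  expect_equal(nrow(featureTable(g)), 0L)

  writeLines(c("LOCUS", "ORIGIN", "        1 acgt", "//"), path)
  expect_error(readGenBank(path), class = "mitotrio_parse_error")

  writeLines(c("LOCUS       amb 4 bp DNA circular INV",
               "ORIGIN", "        1 acrt", "//"), path)
  expect_error(readGenBank(path), class = "mitotrio_parse_error")

  writeLines(c("LOCUS       nofeat 4 bp DNA linear INV",
               "FEATURES             Location/Qualifiers",
               "     oddkey          1..2",
               "                     /note=\"strange\"",
               "ORIGIN", "        1 acgt", "//"), path)
  expect_warning(g3 <- readGenBank(path, infer_control = FALSE),
                 "unknown feature key")
  expect_equal(featureTable(g3)$fclass, "intergenic")
})

test_that("an unannotated control region is synthesised from the gap", {
  g <- fix_base(1)$genome
  ft <- featureTable(g)
  path <- withr::local_tempfile(fileext = ".gb")
  writeGenBank(MitoGenome(genomeId(g), genomeSeq(g), TRUE,
                          ft[ft$fclass != "control", ]), path)
  g2 <- readGenBank(path, infer_control = TRUE)
  ctrl <- featureTable(g2)[featureTable(g2)$fclass == "control", ]
  truth <- ft[ft$fclass == "control", ]
  # the inferred region is the whole unannotated stretch, which absorbs
  # the intergenic spacer directly upstream of the true control region
  expect_lte(ctrl$start, truth$start)
  expect_equal(ctrl$end, truth$end)
  expect_gte(truth$start - ctrl$start, 0L)
  expect_lt(truth$start - ctrl$start, 150L)
  expect_equal(ctrl$name, "control_region")
})

test_that("composition counts sum to length and hit the AT target", {
  g <- MitoGenome("t", "ACGT", circular = FALSE)
  cmp <- composition(g)
  expect_equal(unname(cmp$counts[c("A", "C", "G", "T")]), rep(1L, 4))
  expect_equal(cmp$gc, 0.5)

  gb <- fix_base(1)$genome
  cmpb <- composition(gb)
  expect_equal(sum(cmpb$counts), genomeLength(gb))
  expect_gt(cmpb$at, 0.83)
  expect_lt(cmpb$at, 0.87)

  # permutation invariance
  perm <- paste(sample(strsplit(genomeSeq(gb), "")[[1]]), collapse = "")
  cmpp <- composition(MitoGenome("p", perm))
  expect_identical(cmpp$counts, cmpb$counts)
})

test_that("regionOf classifies containment, overlap priority, intergenic", {
  g <- fix_base(1)$genome
  ft <- featureTable(g)
  cox1 <- ft[ft$name == "cox1", ]
  r <- regionOf(g, cox1$start + 10L)
  expect_equal(r$fclass, "PCG")
  expect_equal(r$name, "cox1")

  # position between two genes -> intergenic named by flanks
  leu <- ft[ft$name == "tRNA-Leu1", ]
  r2 <- regionOf(g, leu$end + 5L)
  expect_equal(r2$fclass, "intergenic")
  expect_equal(r2$name, "IR:tRNA-Leu1-cox2")

  # atp8/atp6 overlap: primary = nearest upstream start, both memberships
  atp6 <- ft[ft$name == "atp6", ]
  r3 <- regionOf(g, atp6$start + 2L)
  expect_equal(r3$name, "atp6")
  expect_setequal(strsplit(r3$all_names, ",")[[1]], c("atp8", "atp6"))

  expect_error(regionOf(g, 0L), class = "mitotrio_domain_error")
  expect_error(regionOf(g, genomeLength(g) + 1L),
               class = "mitotrio_domain_error")
})

test_that("regionOf partitions every position; census matches the layout", {
  g <- fix_base(1)$genome
  sweep <- regionOf(g, seq_len(genomeLength(g)))
  census <- table(sweep$fclass)
  lay <- beeTemplate()$layout
  exp_len <- tapply(lay$length, lay$fclass, sum)
  expect_equal(unname(census[["PCG"]]), unname(exp_len[["PCG"]]) - 19L)
  expect_equal(unname(census[["tRNA"]]), unname(exp_len[["tRNA"]]))
  expect_equal(unname(census[["rRNA"]]), unname(exp_len[["rRNA"]]))
  expect_equal(unname(census[["control"]]), unname(exp_len[["control"]]))
  expect_equal(unname(census[["intergenic"]]),
               sum(lay$spacer_after[lay$spacer_after > 0L]))
  expect_equal(sum(census), genomeLength(g))
})

test_that("FASTA I/O round-trips through Biostrings", {
  g <- fix_base(1)$genome
  path <- withr::local_tempfile(fileext = ".fa")
  writeFastaGenomes(g, path)
  gs <- readFastaGenomes(path)
  expect_length(gs, 1L)
  expect_identical(genomeSeq(gs[[1]]), genomeSeq(g))
  expect_identical(genomeId(gs[[1]]), genomeId(g))
})
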