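msa_from_rows <- function(rows) {
  new("AnchoredMSA", refId = names(rows)[1], ids = names(rows),
      rows = unname(rows))
}

test_that("uniqueness patterns follow the allele multiset", {
  expect_equal(classifyPattern(c("A", "T", "T")), "unique_target")
  expect_equal(classifyPattern(c("C", "C", "T")), "diagnostic_pair")
  expect_equal(classifyPattern(c("A", "G", "A")), "unique_other1")
  expect_equal(classifyPattern(c("A", "C", "G")), "all_distinct")
  expect_equal(classifyPattern(c("AT", "AT", "-")), "diagnostic_pair")
  expect_error(classifyPattern(c("A", "A", "A")),
               class = "mitotrio_domain_error")
  expect_error(classifyPattern(c("A", "A")), class = "mitotrio_domain_error")
})

test_that("identical rows yield an empty event list and zero tallies", {
  g <- MitoGenome("T", "ACGTACGTACGTACGT", TRUE)
  msa <- msa_from_rows(c(T = genomeSeq(g), B = genomeSeq(g),
                         C = genomeSeq(g)))
  ev <- callEvents(msa, g)
  expect_equal(nrow(ev), 0L)
  tl <- tallyEvents(ev, ids = c("T", "B", "C"))
  expect_true(all(tl$pair_totals == 0))
  expect_equal(nrow(tl$missense), 0L)
})

test_that("hand-built columns produce the expected events", {
  # target genome: 12 bp, one intergenic annotation-free stretch
  g <- MitoGenome("T", "ACGTAAATTTGC", TRUE)
  #            T: ACGTAAATTTGC
  #            B: ACGTAAATTTGC  with one substitution at pos 3
  #            C: ACG--AATTTGC  a 2 bp deletion (cols 4-5)
  rows <- c(T = "ACGTAAATTTGC", B = "ACTTAAATTTGC", C = "ACG--AATTTGC")
  msa <- msa_from_rows(rows)
  ev <- callEvents(msa, g)
  expect_equal(nrow(ev), 2L)
  sub <- ev[ev$kind == "substitution", ]
  expect_equal(sub$col_start, 3L)
  expect_equal(sub$allele_T, "G")
  expect_equal(sub$allele_B, "T")
  expect_equal(sub$pattern, "unique_other1")
  ind <- ev[ev$kind == "indel", ]
  expect_equal(c(ind$col_start, ind$col_end), c(4L, 5L))
  expect_equal(ind$allele_T, "TA")
  expect_equal(ind$allele_C, "-")
  expect_equal(ind$pattern, "diagnostic_pair")
  expect_equal(ind$pos_T, 4L)
  expect_equal(ind$pos_C, 3L)  # left flank in the gapped genome
})

test_that("event partition covers every non-unanimous MSA column", {
  res <- fix_pipeline(1)
  rows <- alnRows(res$msa)
  M <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]]))
  non_unan <- which(apply(M, 2, function(cc) length(unique(cc)) > 1L))
  covered <- unlist(lapply(seq_len(nrow(res$events)), function(i)
    res$events$col_start[i]:res$events$col_end[i]))
  expect_setequal(non_unan, covered)
  expect_equal(anyDuplicated(covered), 0L)
})

test_that("uniqueness algebra holds on trios without all_distinct plants", {
  res <- fix_pipeline(1)
  ev <- res$events
  expect_false(any(ev$pattern == "all_distinct"))
  tl <- res$tallies
  pt <- tl$pair_totals
  nu <- sum(ev$pattern == "unique_target")
  expect_equal(unname(pt[["SIC|ATC"]] + pt[["SIC|REF"]] - pt[["ATC|REF"]]),
               2L * nu)
})

test_that("tallies reproduce the planted spectrum and respect count mode", {
  tr <- fix_trio(1)
  res <- fix_pipeline(1)
  truth <- ledgerEvents(tr$ledger)
  tl <- res$tallies
  # SIC vs REF differs wherever either carries a mutation
  expect_equal(unname(tl$pair_totals[["SIC|REF"]]), nrow(truth))
  expect_equal(unname(tl$pair_totals[["SIC|ATC"]]),
               sum(truth$pattern == "unique_target"))
  expect_equal(unname(tl$pair_totals[["ATC|REF"]]),
               sum(truth$pattern == "diagnostic_pair"))
  reg <- with(tl$pair_by_region[tl$pair_by_region$pair == "SIC|ATC", ],
              setNames(n, region))
  treg <- table(truth$region_class[truth$pattern == "unique_target"])
  expect_equal(reg[sort(names(reg))],
               setNames(as.numeric(treg[sort(names(reg))]),
                        sort(names(reg))))
  # column counting weighs multi-base indels by their span
  tcol <- tallyEvents(res$events, count_mode = "column")
  extra <- sum((res$events$col_end - res$events$col_start)[
    res$events$allele_SIC != res$events$allele_REF])
  expect_equal(unname(tcol$pair_totals[["SIC|REF"]]),
               unname(tl$pair_totals[["SIC|REF"]]) + extra)
})

test_that("missense calls are invariant to which genome anchors the MSA", {
  tr <- fix_trio(1)
  res <- fix_pipeline(1)
  # re-anchor on the conspecific: annotate it from the reference first
  ref <- tr$genomes$REF
  ftc <- which(featureTable(ref)$fclass == "control")
  ref2 <- rotateGenome(ref, featureTable(ref)$start[
    which.min((featureTable(ref)$start -
                 featureTable(ref)$end[ftc]) %% nchar(genomeSeq(ref)))] - 1L)
  sib <- rotateToAnchor(tr$genomes$ATC, ref2)$genome
  tgt <- rotateToAnchor(tr$genomes$SIC, ref2)$genome
  aln <- globalAlign(ref2, sib)
  pr <- projectFeatures(ref2, sib, aln)
  sib_ann <- pr$genome
  msa2 <- anchorMerge(list(globalAlign(sib_ann, tgt,
                                       ids = c("ATC", "SIC")),
                           globalAlign(sib_ann, ref2,
                                       ids = c("ATC", "REF"))))
  ev2 <- callEvents(msa2, sib_ann)
  m1 <- res$events[which(res$events$effect == "missense"), ]
  m2 <- ev2[which(ev2$effect == "missense"), ]
  expect_equal(nrow(m1), nrow(m2))
  # unordered amino-acid pairs agree regardless of anchor
  pairs1 <- sort(paste(pmin(m1$aa_from, m1$aa_to),
                       pmax(m1$aa_from, m1$aa_to)))
  pairs2 <- sort(paste(pmin(m2$aa_from, m2$aa_to),
                       pmax(m2$aa_from, m2$aa_to)))
  expect_equal(pairs1, pairs2)
})

test_that("event export writes readable TSV and minimal VCF", {
  res <- fix_pipeline(1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeEventsTSV(res$events, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(res$events))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeEventsVCF(res$events, res$target_annotated, vcf)
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(res$events))
  fields <- strsplit(body, "\t")
  expect_true(all(lengths(fields) == 8L))
  # REF alleles match the target sequence at POS
  s <- genomeSeq(res$target_annotated)
  ok <- vapply(fields, function(f) {
    pos <- as.integer(f[2]); ref <- f[4]
    substr(s, pos, pos + nchar(ref) - 1L) == ref
  }, logical(1))
  expect_true(all(ok))
})
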