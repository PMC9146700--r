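test_that("projection through an identity alignment is a no-op", {
  g <- fix_base(1)$genome
  bare <- MitoGenome("copy", genomeSeq(g), TRUE)
  aln <- globalAlign(g, bare)
  pr <- projectFeatures(g, bare, aln)
  expect_true(all(pr$report$status == "projected"))
  expect_true(all(pr$report$delta_len == 0L))
  cols <- c("name", "fclass", "strand", "start", "end")
  expect_identical(featureTable(pr$genome)[, cols],
                   featureTable(g)[, cols])
})

test_that("an in-gene insertion lengthens the gene and shifts downstream", {
  g <- fix_base(1)$genome
  ft <- featureTable(g)
  nd2 <- ft[ft$name == "nd2", ]
  s <- genomeSeq(g)
  at <- nd2$start + 101L
  ins <- "GCGCA"
  s2 <- paste0(substr(s, 1, at), ins, substr(s, at + 1L, nchar(s)))
  target <- MitoGenome("ins5", s2, TRUE)
  pr <- projectFeatures(g, target, globalAlign(g, target))
  rep <- pr$report
  expect_equal(rep$delta_len[rep$name == "nd2"], 5L)
  downstream <- featureTable(pr$genome)
  expect_equal(downstream$start[downstream$name == "cox1"],
               ft$start[ft$name == "cox1"] + 5L)
  before <- downstream[downstream$name == "tRNA-Ile", ]
  expect_equal(before$start, ft$start[ft$name == "tRNA-Ile"])
})

test_that("projection is monotone along the target", {
  res <- fix_pipeline(1)
  ft <- featureTable(res$target_annotated)
  expect_true(!is.unsorted(ft$start))
})

test_that("dropped short features are rescued at their true coordinates", {
  tr <- fix_trio(1)
  res <- fix_pipeline(1)
  ref <- res$target_annotated  # use as annotation donor for this scenario
  truth <- tr$ledger@truth$SIC
  # simulate a transfer that dropped two tRNAs
  drop <- c("tRNA-Ser1", "tRNA-Gln")
  ft <- featureTable(ref)
  gden <- MitoGenome(genomeId(ref), genomeSeq(ref), TRUE,
                     ft[!ft$name %in% drop, ])
  aln <- globalAlign(ref, gden, ids = c(genomeId(ref), "self"))
  report <- data.frame(
    name = drop, fclass = "tRNA", status = "failed",
    ref_start = ft$start[match(drop, ft$name)],
    ref_end = ft$end[match(drop, ft$name)],
    target_start = NA_integer_, target_end = NA_integer_,
    delta_len = NA_integer_, stringsAsFactors = FALSE)
  resc <- rescueUnmapped(gden, ref, report, aln)
  expect_true(all(resc$report$status == "rescued"))
  got <- featureTable(resc$genome)
  for (nm in drop) {
    expect_equal(got$start[got$name == nm], ft$start[ft$name == nm])
    expect_equal(got$end[got$name == nm], ft$end[ft$name == nm])
  }
})

test_that("a feature absent from the target stays failed with a reason", {
  g <- fix_base(1)$genome
  ft <- featureTable(g)
  vict <- ft[ft$name == "tRNA-Asp", ]
  s <- genomeSeq(g)
  # delete the whole gene from the target
  s2 <- paste0(substr(s, 1, vict$start - 1L),
               substr(s, vict$end + 1L, nchar(s)))
  target <- MitoGenome("del", s2, TRUE)
  aln <- globalAlign(g, target)
  pr <- projectFeatures(g, target, aln)
  expect_equal(pr$report$status[pr$report$name == "tRNA-Asp"], "failed")
  resc <- rescueUnmapped(pr$genome, g, pr$report, aln)
  row <- resc$report[resc$report$name == "tRNA-Asp", ]
  expect_equal(row$status, "failed")
  expect_match(row$reason, "identity")
})

test_that("cox1-style PCG/tRNA overlap is curated to a truncated stop", {
  g <- fix_base(1)$genome
  ft <- featureTable(g)
  i <- which(ft$name == "cox1")
  true_end <- ft$end[i]
  # mis-annotate cox1 five bases into tRNA-Leu1 (which begins TTTAA,
  # presenting an apparent in-tRNA TAA)
  ft$end[i] <- ft$end[i] + 5L
  gm <- MitoGenome(genomeId(g), genomeSeq(g), TRUE, ft)
  expect_equal(translateCDS(featureCodingSeq(gm, "cox1"))$stop_kind, "TAA")
  cur <- curateOverlaps(gm)
  expect_equal(featureTable(cur$genome)$end[
    featureTable(cur$genome)$name == "cox1"], true_end)
  act <- cur$actions[cur$actions$action == "trimmed", ]
  expect_equal(act$gene, "cox1")
  expect_match(act$detail, "truncated 'T'")
  # idempotent: curating again changes nothing
  cur2 <- curateOverlaps(cur$genome)
  expect_identical(featureTable(cur2$genome), featureTable(cur$genome))
  expect_true(!any(cur2$actions$action == "trimmed"))
})

test_that("the whitelisted atp8/atp6 overlap is preserved", {
  g <- fix_base(1)$genome
  cur <- curateOverlaps(g)
  ft <- featureTable(cur$genome)
  a8 <- ft[ft$name == "atp8", ]; a6 <- ft[ft$name == "atp6", ]
  expect_equal(a8$end - a6$start + 1L, 19L)
  expect_true(any(cur$actions$action == "preserved" &
                    grepl("atp8/atp6", cur$actions$gene)))
  expect_true(!any(cur$actions$action == "trimmed"))
})

test_that("gene-order comparison is rotation invariant with zero self-diff", {
  g <- fix_base(1)$genome
  ord <- geneOrder(g)
  expect_equal(ord$name[1], "tRNA-Glu")  # first gene after the CR
  d0 <- geneOrderDiff(ord, ord)
  expect_equal(d0$n_breakpoints, 0L)
  rot <- rbind(ord[15:nrow(ord), ], ord[1:14, ])
  d1 <- geneOrderDiff(ord, rot)
  expect_equal(d1$n_breakpoints, 0L)
})

test_that("honeybee vs ancestral insect order: tRNA clusters moved, PCGs not", {
  g <- fix_base(1)$genome
  anc <- ancestralInsectOrder()
  d <- geneOrderDiff(geneOrder(g), anc)
  expect_gt(d$n_breakpoints, 0L)
  moved <- unique(unlist(d$breakpoints))
  expect_true(all(c("tRNA-Trp", "tRNA-Cys", "tRNA-Tyr") %in% moved |
                    c("tRNA-Trp", "tRNA-Cys", "tRNA-Tyr") %in%
                      d$breakpoints$to))
  # the Asp/Lys swap shows up as breakpoints around cox2/atp8
  expect_true(any(grepl("tRNA-Asp|tRNA-Lys", moved)))
  # PCG-only orders agree completely (ancestral PCG arrangement conserved)
  dp <- geneOrderDiff(geneOrder(g, classes = "PCG"),
                      anc[anc$name %in% geneOrder(g, "PCG")$name, ])
  expect_equal(dp$n_breakpoints, 0L)
})
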