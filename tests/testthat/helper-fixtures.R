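# shared fixtures, built in code and memoised per seed so several test
# files can reuse the same synthetic genomes without regenerating them

.fixture_cache <- new.env(parent = emptyenv())

fix_base <- function(seed = 1L) {
  key <- paste0("base", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- makeBase(seed = seed)
  .fixture_cache[[key]]
}

fix_trio <- function(seed = 1L) {
  key <- paste0("trio", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- makeTrio(fix_base(seed), seed = seed)
  .fixture_cache[[key]]
}

fix_pipeline <- function(seed = 1L) {
  key <- paste0("pipe", seed)
  if (is.null(.fixture_cache[[key]])) {
    tr <- fix_trio(seed)
    .fixture_cache[[key]] <- runTrioPipeline(tr$genomes$SIC, tr$genomes$ATC,
                                             tr$genomes$REF)
  }
  .fixture_cache[[key]]
}

# random near-identical pair for alignment oracles
random_pair <- function(n = 300L, subst = 0.02, indels = 1L) {
  a <- sample(c("A", "C", "G", "T"), n, TRUE, prob = c(.43, .095, .055, .42))
  b <- a
  k <- max(1L, rbinom(1L, n, subst))
  idx <- sample(n, k)
  for (i in idx) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  for (j in seq_len(indels)) {
    if (runif(1) < 0.5) {
      p <- sample(length(b) - 5L, 1L)
      b <- b[-(p:(p + sample(0:2, 1L)))]
    } else {
      p <- sample(length(b) - 1L, 1L)
      ins <- sample(c("A", "C", "G", "T"), sample(1:3, 1L), TRUE)
      b <- append(b, ins, after = p)
    }
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# independent unbanded optimal score via Biostrings (Gotoh, global)
oracle_score <- function(a, b, match = 2, mismatch = -3, gap_open = 6,
                         gap_ext = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = gap_open,
                                gapExtension = gap_ext, scoreOnly = TRUE)
}

# key used to match called events against the ledger
event_key <- function(df) {
  sort(paste(df$pos_SIC, df$pos_ATC, df$pos_REF, df$allele_SIC,
             df$allele_ATC, df$allele_REF, df$pattern, df$region_class))
}
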