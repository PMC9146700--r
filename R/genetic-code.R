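# Invertebrate mitochondrial genetic code (NCBI translation table 5) and
# the start/stop conventions of insect mitochondrial PCGs.

#' The invertebrate mitochondrial codon table
#'
#' Codon-to-amino-acid map for NCBI translation table 5 (deviations from the
#' standard code: AGA/AGG = Ser, ATA = Met, TGA = Trp), the initiator set
#' observed in insect mitogenomes, the stop set \{TAA, TAG\}, and the
#' truncated-stop tokens \{T, TA\} completed to TAA by polyadenylation.
#'
#' @param table_id NCBI genetic-code id; only \code{"5"} is supported.
#' @return a list with \code{codons} (named character vector of 64 amino
#'   acids), \code{starts}, \code{stops}, \code{truncated}.
#' @export
codonTable <- function(table_id = "5") {
  if (!identical(as.character(table_id), "5"))
    .stop_domain("only the invertebrate mitochondrial code (table 5) ships")
  code <- Biostrings::getGeneticCode("5")
  names(code) <- gsub("U", "T", names(code))
  list(codons = code,
       starts = c("ATG", "ATA", "ATT", "ATC", "GTG", "TTG"),
       stops = c("TAA", "TAG"),
       truncated = c("T", "TA"))
}

#' Translate a coding sequence under the invertebrate mitochondrial code
#'
#' The input is the coding-strand nucleotide sequence of a PCG (heavy-strand
#' genes must already be reverse complemented, as [featureCodingSeq()]
#' does). A trailing remainder of 1 nt (\code{T}) or 2 nt (\code{TA}) is
#' accepted as a truncated stop codon completed by polyadenylation; a full
#' terminal TAA/TAG is reported verbatim. An internal stop raises an
#' integrity error naming the codon index. By convention the protein begins
#' with \code{M} whatever the initiator codon; the raw initiator is reported
#' alongside.
#'
#' @param seq coding nucleotide string, length >= 3.
#' @param table a [codonTable()].
#' @return list with \code{protein}, \code{start_codon}, \code{stop_kind}
#'   (\code{"TAA"}, \code{"TAG"}, \code{"T"} or \code{"TA"}) and
#'   \code{stop_codon}.
#' @export
translateCDS <- function(seq, table = codonTable()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3L) .stop_domain("coding sequence shorter than one codon")
  rem <- n %% 3L
  tail_tok <- if (rem) substr(seq, n - rem + 1L, n) else ""
  if (rem == 1L && tail_tok != "T")
    .stop_integrity("length %% 3 == 1 but trailing base is '%s', not T",
                    tail_tok)
  if (rem == 2L && tail_tok != "TA")
    .stop_integrity("length %% 3 == 2 but trailing bases are '%s', not TA",
                    tail_tok)
  body <- substr(seq, 1L, n - rem)
  codons <- substring(body, seq(1L, nchar(body) - 2L, 3L),
                      seq(3L, nchar(body), 3L))
  if (rem == 0L) {
    last <- codons[length(codons)]
    if (!last %in% table$stops)
      .stop_integrity("no stop codon: CDS ends in '%s'", last)
    stop_kind <- last; stop_codon <- last
    codons <- codons[-length(codons)]
  } else {
    stop_kind <- tail_tok
    stop_codon <- tail_tok
  }
  aa <- unname(table$codons[codons])
  if (anyNA(aa))
    .stop_integrity("unresolvable codon at index %d",
                    which(is.na(aa))[1])
  internal <- which(aa == "*")
  if (length(internal))
    .stop_integrity("internal stop codon at codon index %d", internal[1])
  aa[1] <- "M"  # formyl-Met convention, raw initiator reported separately
  list(protein = paste(aa, collapse = ""),
       start_codon = codons[1],
       stop_kind = stop_kind, stop_codon = stop_codon)
}

#' Coding-orientation sequence of an annotated feature
#'
#' @param g a \linkS4class{MitoGenome}.
#' @param name feature name.
#' @return nucleotide string in coding orientation (heavy-strand features
#'   reverse complemented).
#' @export
featureCodingSeq <- function(g, name) {
  ft <- g@features
  i <- which(ft$name == name)
  if (!length(i)) .stop_domain("no feature named '%s'", name)
  .feature_seq(g, ft[i[1], ])
}

#' Start- and stop-codon survey of all protein-coding genes
#'
#' Translates every PCG of the genome and tallies the start codons used and
#' the stop kinds (full TAA/TAG or truncated T/TA). For the honeybee
#' mitogenome this reproduces the canonical tally of one ATC, three ATG,
#' three ATA and six ATT starts, with all genes ending TAA except the
#' truncated-T cox1.
#'
#' @param g an annotated \linkS4class{MitoGenome} with at least one PCG.
#' @param table a [codonTable()].
#' @return list with \code{per_gene} data.frame and \code{starts},
#'   \code{stops} tally tables.
#' @export
codonUsageSurvey <- function(g, table = codonTable()) {
  ft <- g@features
  pcg <- ft[ft$fclass == "PCG", , drop = FALSE]
  if (!nrow(pcg)) .stop_domain("genome has no protein-coding genes")
  rows <- lapply(seq_len(nrow(pcg)), function(i) {
    tr <- translateCDS(.feature_seq(g, pcg[i, ]), table)
    data.frame(gene = pcg$name[i], start_codon = tr$start_codon,
               stop_kind = tr$stop_kind,
               protein_length = nchar(tr$protein),
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  list(per_gene = per_gene,
       starts = table(per_gene$start_codon),
       stops = table(per_gene$stop_kind))
}
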