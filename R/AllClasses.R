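#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib mitotrio, .registration = TRUE
NULL

FCLASSES <- c("PCG", "tRNA", "rRNA", "control", "intergenic")
STRANDS  <- c("light", "heavy")

.empty_features <- function() {
  data.frame(name = character(), fclass = character(), strand = character(),
             start = integer(), end = integer(), notes = character(),
             stringsAsFactors = FALSE)
}

#' MitoGenome: a circular mitochondrial genome with its feature table
#'
#' The central container of the package: a nucleotide sequence (over
#' \code{A,C,G,T,N}), a circular-topology flag, and an ordered, typed feature
#' table. Feature spans are 1-based inclusive; on a circular sequence a span
#' with \code{end < start} wraps the origin. Feature classes are one of
#' \code{PCG}, \code{tRNA}, \code{rRNA}, \code{control}, \code{intergenic};
#' strands are \code{light} (the plus strand of the deposited sequence) and
#' \code{heavy} (its reverse complement).
#'
#' @slot id single character label.
#' @slot seq the nucleotide sequence as an uppercase character scalar.
#' @slot circular logical topology flag.
#' @slot features \code{data.frame} with columns \code{name}, \code{fclass},
#'   \code{strand}, \code{start}, \code{end}, \code{notes}, sorted by
#'   \code{start}.
#'
#' @seealso [readGenBank()], [composition()], [regionOf()]
#' @export
setClass("MitoGenome",
         representation(id = "character", seq = "character",
                        circular = "logical", features = "data.frame"))

setValidity("MitoGenome", function(object) {
  msg <- character()
  if (length(object@seq) != 1L || nchar(object@seq) == 0L)
    msg <- c(msg, "sequence must be a single non-empty string")
  else if (grepl("[^ACGTN]", object@seq))
    msg <- c(msg, "sequence contains characters outside {A,C,G,T,N}")
  ft <- object@features
  need <- c("name", "fclass", "strand", "start", "end", "notes")
  if (!all(need %in% names(ft)))
    msg <- c(msg, paste("feature table must have columns:",
                        paste(need, collapse = ", ")))
  else if (nrow(ft)) {
    n <- nchar(object@seq)
    if (any(ft$start < 1L | ft$start > n | ft$end < 1L | ft$end > n))
      msg <- c(msg, "feature coordinates out of range")
    if (!object@circular && any(ft$end < ft$start))
      msg <- c(msg, "wrapped spans are only permitted on circular sequences")
    if (!all(ft$fclass %in% FCLASSES))
      msg <- c(msg, "fclass outside the allowed set")
    if (!all(ft$strand %in% STRANDS))
      msg <- c(msg, "strand must be 'light' or 'heavy'")
    if (is.unsorted(ft$start))
      msg <- c(msg, "features must be sorted by start")
    named <- ft$name[ft$fclass %in% c("PCG", "tRNA", "rRNA", "control")]
    if (anyDuplicated(named))
      msg <- c(msg, "gene names must be unique within PCG/tRNA/rRNA/control")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MitoGenome
#'
#' @param id sequence label.
#' @param seq nucleotide string (coerced to upper case).
#' @param circular logical; circular topology.
#' @param features feature table (see [MitoGenome-class]); missing columns
#'   are filled with defaults, and rows are sorted by start.
#' @return a validated \linkS4class{MitoGenome}.
#' @export
MitoGenome <- function(id, seq, circular = TRUE, features = NULL) {
  seq <- toupper(as.character(seq))
  if (is.null(features)) features <- .empty_features()
  if (!"notes" %in% names(features)) features$notes <- ""
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  new("MitoGenome", id = as.character(id), seq = seq,
      circular = isTRUE(circular), features = features)
}

#' PairAlignment: a global pairwise alignment
#'
#' Two gapped rows of equal column count plus the alignment score. Gaps are
#' \code{-}; no column is gap/gap. Column-to-position maps are derived on
#' demand with [columnMap()].
#'
#' @slot ids labels of the two sequences.
#' @slot rows the two gapped strings.
#' @slot score alignment score under the scoring scheme used.
#' @export
setClass("PairAlignment",
         representation(ids = "character", rows = "character",
                        score = "numeric"))

setValidity("PairAlignment", function(object) {
  if (length(object@rows) != 2L) return("exactly two rows required")
  if (nchar(object@rows[1]) != nchar(object@rows[2]))
    return("rows must have equal column counts")
  both <- strsplit(object@rows[1], "")[[1]] == "-" &
          strsplit(object@rows[2], "")[[1]] == "-"
  if (any(both)) return("gap/gap columns are not allowed")
  TRUE
})

#' AnchoredMSA: a reference-anchored multiple alignment
#'
#' All rows share one column space induced by the reference (first) row;
#' ungapping any row recovers its input sequence.
#'
#' @slot refId id of the reference row.
#' @slot ids row labels (reference first).
#' @slot rows gapped strings of equal length, reference first.
#' @export
setClass("AnchoredMSA",
         representation(refId = "character", ids = "character",
                        rows = "character"))

setValidity("AnchoredMSA", function(object) {
  if (length(object@ids) != length(object@rows))
    return("ids and rows differ in length")
  if (length(unique(nchar(object@rows))) > 1L)
    return("rows must have equal column counts")
  if (object@ids[1] != object@refId)
    return("reference row must come first")
  TRUE
})

#' TrioLedger: ground truth for a synthetic mitogenome trio
#'
#' Produced by [makeTrio()]. Records every planted event with its
#' coordinates in all three genomes, expected uniqueness pattern and coding
#' effect, the rotation applied to each sibling, and the start/stop codons
#' assigned to each protein-coding gene.
#'
#' @slot events data.frame of planted events.
#' @slot rotations named integer vector of rotations applied per genome.
#' @slot codons data.frame of assigned start/stop codons per PCG.
#' @slot truth list of per-genome ground-truth feature tables (analysis
#'   frame, i.e. before the recorded rotations were applied).
#' @export
setClass("TrioLedger",
         representation(events = "data.frame", rotations = "integer",
                        codons = "data.frame", truth = "list"))

#' @describeIn MitoGenome-class compact printing
#' @param object a MitoGenome
#' @export
setMethod("show", "MitoGenome", function(object) {
  cat(sprintf("MitoGenome '%s': %d bp, %s, %d features\n",
              object@id, nchar(object@seq),
              if (object@circular) "circular" else "linear",
              nrow(object@features)))
  if (nrow(object@features)) {
    tab <- table(factor(object@features$fclass, levels = FCLASSES))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
})

#' @describeIn PairAlignment-class compact printing
#' @param object a PairAlignment
#' @export
setMethod("show", "PairAlignment", function(object) {
  cat(sprintf("PairAlignment %s vs %s: %d columns, score %.1f\n",
              object@ids[1], object@ids[2], nchar(object@rows[1]),
              object@score))
})

#' @describeIn AnchoredMSA-class compact printing
#' @param object an AnchoredMSA
#' @export
setMethod("show", "AnchoredMSA", function(object) {
  cat(sprintf("AnchoredMSA on '%s': %d rows x %d columns\n",
              object@refId, length(object@rows), nchar(object@rows[1])))
})

#' @describeIn TrioLedger-class compact printing
#' @param object a TrioLedger
#' @export
setMethod("show", "TrioLedger", function(object) {
  cat(sprintf("TrioLedger: %d planted events; rotations %s\n",
              nrow(object@events),
              paste(sprintf("%s=%d", names(object@rotations),
                            object@rotations), collapse = ", ")))
})
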