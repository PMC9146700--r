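# internal helpers: circular-sequence arithmetic and classed conditions

.stop_parse <- function(...) {
  stop(errorCondition(sprintf(...), class = c("mitotrio_parse_error", "error")))
}
.stop_align <- function(...) {
  stop(errorCondition(sprintf(...), class = c("mitotrio_align_error", "error")))
}
.stop_integrity <- function(...) {
  stop(errorCondition(sprintf(...),
                      class = c("mitotrio_integrity_error", "error")))
}
.stop_domain <- function(...) {
  stop(errorCondition(sprintf(...), class = c("mitotrio_domain_error", "error")))
}

#' Reverse complement of a nucleotide string
#' @param s nucleotide string over A,C,G,T,N.
#' @return the reverse complement string.
#' @export
revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Rotate a circular sequence
#'
#' \code{rotateSeq(s, k)} moves the first \code{k} residues to the end, so the
#' rotated sequence starts at original position \code{k + 1}. Rotating by
#' \code{k} and then by \code{length - k} is the identity.
#'
#' @param s nucleotide string.
#' @param k rotation offset, reduced modulo \code{nchar(s)}.
#' @return the rotated string.
#' @export
rotateSeq <- function(s, k) {
  n <- nchar(s)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(s)
  paste0(substr(s, k + 1L, n), substr(s, 1L, k))
}

# position arithmetic on the circle: map original position to rotated frame
.rot_pos <- function(pos, k, n) ((pos - 1L - k) %% n) + 1L

# extract span [start, end] (1-based inclusive) allowing origin wrap
.circ_substr <- function(s, start, end) {
  n <- nchar(s)
  if (end >= start) return(substr(s, start, end))
  paste0(substr(s, start, n), substr(s, 1L, end))
}

.span_len <- function(start, end, n) {
  if (end >= start) end - start + 1L else n - start + 1L + end
}

# feature nucleotide sequence in coding orientation
.feature_seq <- function(g, row) {
  s <- .circ_substr(g@seq, row$start, row$end)
  if (row$strand == "heavy") revComp(s) else s
}

#' Rotate a MitoGenome
#'
#' Rotates the sequence with [rotateSeq()] and remaps all feature spans into
#' the rotated frame (spans may wrap the new origin).
#'
#' @param g a \linkS4class{MitoGenome}; must be circular.
#' @param k rotation offset.
#' @return the rotated \linkS4class{MitoGenome}.
#' @export
rotateGenome <- function(g, k) {
  if (!g@circular) .stop_domain("cannot rotate a linear sequence")
  n <- nchar(g@seq)
  k <- ((k %% n) + n) %% n
  ft <- g@features
  if (nrow(ft)) {
    ft$start <- .rot_pos(ft$start, k, n)
    ft$end <- .rot_pos(ft$end, k, n)
    ft <- ft[order(ft$start), , drop = FALSE]
    rownames(ft) <- NULL
  }
  new("MitoGenome", id = g@id, seq = rotateSeq(g@seq, k),
      circular = TRUE, features = ft)
}

# split a gapped row into characters
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Column-to-position map of a gapped row
#'
#' @param row a gapped string.
#' @return integer vector, one entry per column: the 1-based ungapped
#'   position, or \code{0} at gap columns.
#' @export
columnMap <- function(row) {
  ch <- .chars(row)
  m <- cumsum(ch != "-")
  m[ch == "-"] <- 0L
  as.integer(m)
}

# nearest ungapped position at or before each column (0 before the first)
.nearest_pos_map <- function(row) cumsum(.chars(row) != "-")

.ungap <- function(row) gsub("-", "", row, fixed = TRUE)
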