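# tRNA-Leu/cox2 mitotype marker extraction and in-silico DraI digestion.

#' Extract the tRNA-Leu/cox2 intergenic mitotype marker
#'
#' Returns the purely intergenic span between the end of the tRNA-Leu gene
#' flanking cox1/cox2 and the start of cox2 (the classic honeybee lineage
#' marker). The tRNA-Leu copy is resolved from an \code{anticodon=UUR} (or
#' \code{UUR} in the notes) annotation when present; otherwise the copy
#' adjacent to cox1 is used and the result is flagged. Optionally the tRNA
#' itself can be included, since amplicon conventions vary.
#'
#' @param g annotated \linkS4class{MitoGenome}.
#' @param include_trna include the tRNA-Leu gene in the marker.
#' @return list with \code{seq}, \code{start}, \code{end} (1-based,
#'   wrap-aware; \code{start > end + 1} never occurs, an empty marker has
#'   zero-length \code{seq}), \code{leu_name}, and \code{flagged} (TRUE if
#'   the tRNA-Leu copy was chosen positionally).
#' @export
extractMarker <- function(g, include_trna = FALSE) {
  ft <- g@features
  n <- nchar(g@seq)
  cox2 <- ft[ft$name == "cox2", , drop = FALSE]
  if (!nrow(cox2)) .stop_domain("missing flanking feature: cox2")
  leus <- ft[ft$fclass == "tRNA" & grepl("^tRNA-Leu", ft$name), ,
             drop = FALSE]
  if (!nrow(leus)) .stop_domain("missing flanking feature: tRNA-Leu")
  flagged <- FALSE
  uur <- grepl("UUR", leus$notes, ignore.case = TRUE)
  if (any(uur)) {
    leu <- leus[which(uur)[1], , drop = FALSE]
  } else {
    cox1 <- ft[ft$name == "cox1", , drop = FALSE]
    if (!nrow(cox1)) .stop_domain("missing flanking feature: cox1")
    dist_after_cox1 <- (leus$start - cox1$end[1]) %% n
    leu <- leus[which.min(dist_after_cox1), , drop = FALSE]
    flagged <- TRUE
  }
  start <- if (include_trna) leu$start[1] else (leu$end[1] %% n) + 1L
  end <- ((cox2$start[1] - 2L) %% n) + 1L
  len <- (end - start + 1L) %% n
  if (((cox2$start[1] - 1L - leu$end[1]) %% n) == 0L && !include_trna) {
    # cox2 immediately follows the tRNA: empty marker, still valid
    return(list(seq = "", start = start, end = start - 1L,
                leu_name = leu$name[1], flagged = flagged))
  }
  list(seq = .circ_substr(g@seq, start, end), start = start, end = end,
       leu_name = leu$name[1], flagged = flagged)
}

#' In-silico DraI restriction profile
#'
#' Digests a linear marker sequence at every DraI recognition site
#' (TTTAAA), cutting between the third T and the first A, and reports the
#' ordered 5'-to-3' fragment lengths. Fragment lengths always sum to the
#' marker length and the number of fragments equals the number of sites
#' plus one.
#'
#' @param marker nucleotide string (may be empty).
#' @return list with \code{sites} (1-based positions of the TTTAAA motifs),
#'   \code{cuts} (positions after which the backbone is cut) and
#'   \code{fragments} (integer lengths, 5' to 3').
#' @export
draiProfile <- function(marker) {
  n <- nchar(marker)
  if (n == 0L)
    return(list(sites = integer(), cuts = integer(), fragments = integer()))
  hits <- gregexpr("TTTAAA", toupper(marker), fixed = TRUE)[[1]]
  sites <- if (hits[1] == -1L) integer() else as.integer(hits)
  cuts <- sites + 2L  # cut between TTT and AAA
  bounds <- c(0L, cuts, n)
  list(sites = sites, cuts = cuts, fragments = diff(bounds))
}
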