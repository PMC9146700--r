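#' Base composition of a mitogenome
#'
#' Counts of A, C, G, T (N counted separately) plus GC and AT fractions of
#' the unambiguous positions. Honeybee mitogenomes are strongly AT biased
#' (around 85 percent AT).
#'
#' @param g a \linkS4class{MitoGenome}.
#' @return a list with \code{counts} (named integer vector A,C,G,T,N),
#'   \code{length}, \code{gc} and \code{at} fractions.
#' @export
composition <- function(g) {
  ch <- .chars(g@seq)
  counts <- vapply(c("A", "C", "G", "T", "N"),
                   function(b) sum(ch == b), integer(1))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  list(counts = counts, length = nchar(g@seq),
       gc = unname((counts["G"] + counts["C"]) / acgt),
       at = unname((counts["A"] + counts["T"]) / acgt))
}

#' Classify a position by region
#'
#' Maps a 1-based position to its feature class and feature name. Positions
#' covered by no annotated feature are \code{intergenic}, named after the
#' flanking genes (\code{IR:<upstream>-<downstream>}). Where annotated
#' features overlap (for example atp8/atp6, which overlap by 19 bases), the
#' primary attribution is the feature whose start is nearest upstream of the
#' position; all memberships are returned in \code{all_names}.
#'
#' @param g an annotated \linkS4class{MitoGenome}.
#' @param pos 1-based position (vectorised).
#' @return a data.frame with columns \code{pos}, \code{fclass}, \code{name},
#'   \code{all_names}.
#' @export
regionOf <- function(g, pos) {
  n <- nchar(g@seq)
  if (any(pos < 1L | pos > n))
    .stop_domain("position out of range 1..%d", n)
  ft <- g@features
  res <- data.frame(pos = as.integer(pos), fclass = "intergenic",
                    name = "", all_names = "", stringsAsFactors = FALSE)
  if (!nrow(ft)) {
    res$name <- "IR:unannotated"
    res$all_names <- res$name
    return(res)
  }
  contains <- function(p) {
    w <- ifelse(ft$end >= ft$start,
                p >= ft$start & p <= ft$end,
                p >= ft$start | p <= ft$end)
    which(w)
  }
  # upstream distance on the circle from feature start to p
  updist <- function(p, starts) (p - starts) %% n
  for (i in seq_along(pos)) {
    hits <- contains(pos[i])
    if (length(hits)) {
      prim <- hits[which.min(updist(pos[i], ft$start[hits]))]
      res$fclass[i] <- ft$fclass[prim]
      res$name[i] <- ft$name[prim]
      res$all_names[i] <- paste(ft$name[hits], collapse = ",")
    } else {
      d_up <- updist(pos[i], ft$end)     # distance since each feature ended
      d_dn <- updist(ft$start, pos[i])   # distance until each feature starts
      up <- ft$name[which.min(d_up)]
      dn <- ft$name[which.min(d_dn)]
      res$name[i] <- sprintf("IR:%s-%s", up, dn)
      res$all_names[i] <- res$name[i]
    }
  }
  res
}
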