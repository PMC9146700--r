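# Banded global alignment with affine gaps, circular rotation anchoring,
# and reference-anchored merging of pairwise alignments.

#' Default alignment scoring for near-identical mitochondrial DNA
#'
#' Match +2, mismatch -3, gap open -6, gap extend -1 (a gap of length L
#' scores open + L * extend). At the >= 99.5 percent identity typical of
#' conspecific mitogenomes away from the control region, any sensible scheme
#' yields the same alignment; these defaults keep single-base indels
#' distinctly cheaper than two substitutions.
#'
#' @param match,mismatch,gap_open,gap_ext scoring parameters.
#' @param band initial band half-width (columns around the anchor diagonal).
#' @param band_cap maximum half-width tried before giving up.
#' @return a named list of parameters.
#' @export
alignParams <- function(match = 2, mismatch = -3, gap_open = -6,
                        gap_ext = -1, band = 300L, band_cap = 2400L) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext, band = as.integer(band),
       band_cap = as.integer(band_cap))
}

#' Banded global pairwise alignment
#'
#' Optimal global alignment under affine gap scoring, computed inside a
#' diagonal band. If the optimal path touches the band edge the band is
#' doubled automatically up to \code{band_cap}; if the cap is reached an
#' alignment error is raised. Gap runs are then left-normalised: each run is
#' shifted maximally leftward while the aligned residue pairs it touches are
#' preserved, which pins indels to the 5' end of homopolymer and repeat
#' context (the VCF convention) and makes event coordinates reproducible.
#'
#' @param a,b nucleotide strings (or \linkS4class{MitoGenome}s).
#' @param params an [alignParams()] list.
#' @param ids labels for the two rows.
#' @param normalise left-normalise gap runs (default TRUE).
#' @return a \linkS4class{PairAlignment}.
#' @export
globalAlign <- function(a, b, params = alignParams(),
                        ids = c("a", "b"), normalise = TRUE) {
  if (is(a, "MitoGenome")) { ids[1] <- a@id; a <- a@seq }
  if (is(b, "MitoGenome")) { ids[2] <- b@id; b <- b@seq }
  if (!nchar(a) || !nchar(b))
    .stop_align("cannot align empty sequences")
  band <- max(params$band, abs(nchar(a) - nchar(b)) + 8L)
  repeat {
    res <- .banded_align_cpp(a, b, params$match, params$mismatch,
                             params$gap_open, params$gap_ext, band)
    if (!res$edge_hit) break
    if (band >= params$band_cap)
      .stop_align("band cap %d reached with path on band edge",
                  params$band_cap)
    band <- min(band * 2L, params$band_cap)
  }
  rows <- c(res$aln1, res$aln2)
  if (normalise) rows <- .left_normalise(rows)
  new("PairAlignment", ids = ids, rows = rows, score = res$score)
}

# shift every gap run maximally leftward while preserving the residue pairs
.left_normalise <- function(rows) {
  x <- .chars(rows[1]); y <- .chars(rows[2])
  for (pass in 1:2) {
    gr <- if (pass == 1) y else x      # row carrying the gaps this pass
    or <- if (pass == 1) x else y      # row carrying residues
    runs <- rle(gr == "-")
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    idx <- which(runs$values)
    for (ri in idx) {
      c1 <- starts[ri]; c2 <- ends[ri]
      while (c1 > 1L && gr[c1 - 1L] != "-" && or[c1 - 1L] != "-" &&
             or[c1 - 1L] == or[c2]) {
        # rotate: the residue left of the gap pairs identically at the right
        gr[c2] <- gr[c1 - 1L]
        gr[c1 - 1L] <- "-"
        c1 <- c1 - 1L; c2 <- c2 - 1L
      }
    }
    if (pass == 1) y <- gr else x <- gr
  }
  c(paste(x, collapse = ""), paste(y, collapse = ""))
}

#' Rotate a circular sequence to a reference anchor
#'
#' Finds the position of the reference's leading k-mer in the doubled target
#' string and rotates the target so that it begins at the position
#' homologous to reference position 1. If the first k-mer is absent
#' (mutated), successive reference k-mers are tried, stepping through the
#' reference until one seeds; if none does the sequences are too divergent
#' and an alignment error is raised.
#'
#' @param target a circular \linkS4class{MitoGenome} (or plain string).
#' @param ref the reference \linkS4class{MitoGenome} (or string).
#' @param k seed length (default 31).
#' @param max_tries how many successive reference seeds to try.
#' @return list with \code{genome} (rotated target, features remapped when
#'   annotated) and \code{offset} (the rotation recovered, i.e. the rotated
#'   target equals \code{rotateSeq(target, offset)}).
#' @export
rotateToAnchor <- function(target, ref, k = 31L, max_tries = 200L) {
  tg <- if (is(target, "MitoGenome")) target else
    MitoGenome("target", target, circular = TRUE)
  rs <- if (is(ref, "MitoGenome")) ref@seq else ref
  n <- nchar(tg@seq)
  doubled <- paste0(tg@seq, tg@seq)
  for (t in seq_len(max_tries)) {
    r0 <- (t - 1L) * 1L + 1L          # successive seeds step by 1
    if (r0 + k - 1L > nchar(rs)) break
    seed <- substr(rs, r0, r0 + k - 1L)
    hit <- regexpr(seed, doubled, fixed = TRUE)[1]
    if (hit > 0L && hit <= n) {
      offset <- (hit - r0) %% n
      return(list(genome = rotateGenome(tg, offset), offset = offset))
    }
  }
  .stop_align("no anchor seed of length %d found: sequences too divergent", k)
}

#' Merge pairwise alignments sharing a reference into an anchored MSA
#'
#' All pairwise alignments must carry the identical ungapped reference as
#' their first row. The merged column space contains every reference
#' position plus, between consecutive reference positions, insertion
#' columns sized to the largest insertion any pair places at that
#' junction. Insertions from different pairs at one junction share columns
#' left-aligned (deterministically), so identical material deleted from
#' the reference relative to several other genomes occupies one column
#' run; shorter insertions are padded with gaps on the right.
#'
#' @param ref_alignments list of \linkS4class{PairAlignment} objects whose
#'   first row is the shared reference.
#' @return an \linkS4class{AnchoredMSA} (reference row first).
#' @export
anchorMerge <- function(ref_alignments) {
  stopifnot(length(ref_alignments) >= 1L)
  refs <- vapply(ref_alignments, function(p) .ungap(p@rows[1]), "")
  if (length(unique(refs)) != 1L)
    .stop_align("pairwise alignments disagree on the reference sequence")
  refseq <- refs[1]
  refid <- ref_alignments[[1]]@ids[1]
  L <- nchar(refseq)
  np <- length(ref_alignments)
  # per pair: insertion counts before each ref position (slot i = before
  # position i; slot L+1 = after the last position)
  ins <- matrix(0L, nrow = np, ncol = L + 1L)
  for (p in seq_len(np)) {
    map <- columnMap(ref_alignments[[p]]@rows[1])
    slot <- 1L; run <- 0L
    for (cc in seq_along(map)) {
      if (map[cc] == 0L) run <- run + 1L
      else {
        ins[p, map[cc]] <- run
        run <- 0L
      }
    }
    ins[p, L + 1L] <- run
  }
  slot_width <- apply(ins, 2L, max)
  ncol_out <- L + sum(slot_width)
  refrow <- character(ncol_out)
  other <- matrix("-", nrow = np, ncol = ncol_out)
  refch <- .chars(refseq)
  pairch <- lapply(ref_alignments, function(p)
    list(r = .chars(p@rows[1]), o = .chars(p@rows[2])))
  # per pair cursor into its own columns
  cur <- rep(1L, np)
  out <- 1L
  for (slot in seq_len(L + 1L)) {
    w <- slot_width[slot]
    if (w > 0L) {
      refrow[seq.int(out, out + w - 1L)] <- "-"
      for (p in seq_len(np)) {
        k <- ins[p, slot]
        if (k > 0L) {
          cols <- seq.int(cur[p], cur[p] + k - 1L)
          other[p, seq.int(out, out + k - 1L)] <- pairch[[p]]$o[cols]
          cur[p] <- cur[p] + k
        }
      }
      out <- out + w
    }
    if (slot <= L) {
      refrow[out] <- refch[slot]
      for (p in seq_len(np)) {
        other[p, out] <- pairch[[p]]$o[cur[p]]
        cur[p] <- cur[p] + 1L
      }
      out <- out + 1L
    }
  }
  rows <- c(paste(refrow, collapse = ""),
            apply(other, 1L, paste, collapse = ""))
  ids <- c(refid, vapply(ref_alignments, function(p) p@ids[2], ""))
  new("AnchoredMSA", refId = refid, ids = ids, rows = rows)
}

#' Export alignment rows as gapped FASTA
#'
#' @param x a \linkS4class{PairAlignment} or \linkS4class{AnchoredMSA}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGappedFasta <- function(x, path) {
  rows <- alnRows(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(rows)) {
    writeLines(paste0(">", names(rows)[i]), con)
    s <- rows[[i]]
    writeLines(substring(s, seq(1L, nchar(s), 70L),
                         pmin(seq(70L, nchar(s) + 69L, 70L), nchar(s))), con)
  }
  invisible(path)
}
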