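# Annotation transfer through a pairwise alignment, rescue of unmapped
# short features, overlap curation, and gene-order comparison.

#' Project a reference feature table onto a target genome
#'
#' Maps each reference feature's endpoints through the alignment column
#' maps. Endpoints landing in target gap columns are snapped inward to the
#' nearest aligned column. A feature whose projected span falls below half
#' its reference length is marked \code{failed} (candidate for
#' [rescueUnmapped()]); this mirrors how annotation-liftover tools drop
#' short tRNAs whose alignment support is weak.
#'
#' @param ref the annotated reference \linkS4class{MitoGenome}.
#' @param target the target \linkS4class{MitoGenome} (annotation ignored).
#' @param aln a \linkS4class{PairAlignment} whose first row ungaps to the
#'   reference sequence and second row to the target sequence.
#' @param min_frac length floor: projected span shorter than
#'   \code{min_frac} times the reference span fails (default 0.5).
#' @return list with \code{genome} (target with projected features) and
#'   \code{report} (per-feature status and coordinate deltas).
#' @export
projectFeatures <- function(ref, target, aln, min_frac = 0.5) {
  if (.ungap(aln@rows[1]) != ref@seq)
    .stop_domain("alignment's first row does not match the reference")
  if (.ungap(aln@rows[2]) != target@seq)
    .stop_domain("alignment's second row does not match the target")
  rmap <- columnMap(aln@rows[1])      # column -> ref pos
  tmap <- columnMap(aln@rows[2])      # column -> target pos
  # ref pos -> column
  r2c <- integer(nchar(ref@seq)); r2c[rmap[rmap > 0L]] <- which(rmap > 0L)
  tnear <- .nearest_pos_map(aln@rows[2])  # column -> target pos at/before
  n_t <- nchar(target@seq)

  ft <- ref@features
  out <- ft[0, ]
  rep_rows <- list()
  for (i in seq_len(nrow(ft))) {
    f <- ft[i, ]
    ref_len <- .span_len(f$start, f$end, nchar(ref@seq))
    # wrapped features: project the two arcs and re-wrap
    proj_end_of <- function(pos, side) {
      cc <- r2c[pos]
      if (tmap[cc] > 0L) return(tmap[cc])
      if (side == "start") {
        # snap inward (rightward) to first aligned target column
        later <- which(tmap > 0L & seq_along(tmap) >= cc)
        if (length(later)) tmap[later[1]] else 0L
      } else {
        if (tnear[cc] > 0L) tnear[cc] else 0L
      }
    }
    ps <- proj_end_of(f$start, "start")
    pe <- proj_end_of(f$end, "end")
    ok <- ps > 0L && pe > 0L
    wrapped <- f$end < f$start
    plen <- if (!ok) 0L
            else if (wrapped) .span_len(ps, pe, n_t)
            else max(pe - ps + 1L, 0L)  # crossed snaps = collapsed span
    status <- if (ok && plen >= ceiling(min_frac * ref_len)) "projected"
              else "failed"
    rep_rows[[i]] <- data.frame(
      name = f$name, fclass = f$fclass, status = status,
      ref_start = f$start, ref_end = f$end,
      target_start = if (status == "projected") ps else NA_integer_,
      target_end = if (status == "projected") pe else NA_integer_,
      delta_len = if (status == "projected") plen - ref_len else NA_integer_,
      stringsAsFactors = FALSE)
    if (status == "projected") {
      f$start <- ps; f$end <- pe
      out <- rbind(out, f)
    }
  }
  report <- do.call(rbind, rep_rows)
  g <- MitoGenome(target@id, target@seq, target@circular, out)
  list(genome = g, report = report)
}

#' Rescue features that failed projection by local re-alignment
#'
#' Each failed feature's reference sequence is re-aligned (banded, affine)
#' against a window of the target centred on the projected neighbourhood,
#' and placed at the best local hit if the identity over the reference
#' length reaches \code{min_identity}. Placements overlapping an existing
#' feature of the same class by more than half their length are rejected.
#'
#' @param target annotated target genome from [projectFeatures()].
#' @param ref the reference genome.
#' @param report the projection report (rows with status \code{failed} are
#'   attempted).
#' @param aln the reference/target \linkS4class{PairAlignment} (for locating
#'   the neighbourhood window).
#' @param min_identity identity threshold for placement (default 0.85).
#' @param window half-width of the target search window around the expected
#'   location (default 600 bp).
#' @return list with \code{genome} (updated) and \code{report} (updated
#'   statuses: \code{rescued} or \code{failed} with reason).
#' @export
rescueUnmapped <- function(target, ref, report, aln, min_identity = 0.85,
                           window = 600L) {
  failed <- which(report$status == "failed")
  if (!length(failed)) return(list(genome = target, report = report))
  rmap <- columnMap(aln@rows[1])
  r2c <- integer(nchar(ref@seq)); r2c[rmap[rmap > 0L]] <- which(rmap > 0L)
  tnear <- .nearest_pos_map(aln@rows[2])
  n_t <- nchar(target@seq)
  ft <- target@features
  report$reason <- if ("reason" %in% names(report)) report$reason else ""
  for (i in failed) {
    fseq <- .circ_substr(ref@seq, report$ref_start[i], report$ref_end[i])
    # heavy-strand features are searched in genome orientation, so no
    # reverse complement here; strand is carried over from the reference
    anchor <- tnear[r2c[report$ref_start[i]]]
    lo <- max(1L, anchor - window)
    hi <- min(n_t, anchor + window + nchar(fseq))
    sub <- substr(target@seq, lo, hi)
    hit <- .best_local_placement(fseq, sub)
    ident <- hit$matches / nchar(fseq)
    if (ident < min_identity) {
      report$reason[i] <- sprintf("best identity %.2f < %.2f", ident,
                                  min_identity)
      next
    }
    ps <- lo + hit$start - 1L
    pe <- lo + hit$end - 1L
    rr <- ref@features[ref@features$name == report$name[i], ][1, ]
    # reject placements overlapping a same-class feature by > 50%
    ov <- .overlap_frac(ps, pe, ft[ft$fclass == rr$fclass, , drop = FALSE],
                        n_t)
    if (ov > 0.5) {
      report$reason[i] <- sprintf("overlaps same-class feature by %.0f%%",
                                  100 * ov)
      next
    }
    ft <- rbind(ft, data.frame(name = rr$name, fclass = rr$fclass,
                               strand = rr$strand, start = ps, end = pe,
                               notes = "rescued by local re-alignment",
                               stringsAsFactors = FALSE))
    report$status[i] <- "rescued"
    report$target_start[i] <- ps
    report$target_end[i] <- pe
    report$delta_len[i] <- (pe - ps + 1L) -
      .span_len(report$ref_start[i], report$ref_end[i], nchar(ref@seq))
  }
  g <- MitoGenome(target@id, target@seq, target@circular, ft)
  list(genome = g, report = report)
}

# glocal placement of a short query inside a window: global in the query,
# free end gaps in the window; simple DP, query lengths are <= ~1.5 kb
.best_local_placement <- function(query, window) {
  q <- .chars(query); w <- .chars(window)
  nq <- length(q); nw <- length(w)
  # score: match 1, mismatch/gap -1; track matches on best path
  prev <- list(sc = rep(0, nw + 1L), mt = rep(0L, nw + 1L),
               st = 0:nw)  # start column of the window hit
  for (i in seq_len(nq)) {
    cur <- list(sc = numeric(nw + 1L), mt = integer(nw + 1L),
                st = integer(nw + 1L))
    cur$sc[1] <- -i; cur$mt[1] <- 0L; cur$st[1] <- 0L
    for (j in seq_len(nw)) {
      m <- q[i] == w[j]
      diag <- prev$sc[j] + if (m) 1 else -1
      up <- prev$sc[j + 1L] - 1
      left <- cur$sc[j] - 1
      best <- max(diag, up, left)
      cur$sc[j + 1L] <- best
      if (best == diag) {
        cur$mt[j + 1L] <- prev$mt[j] + if (m) 1L else 0L
        cur$st[j + 1L] <- prev$st[j]
      } else if (best == up) {
        cur$mt[j + 1L] <- prev$mt[j + 1L]; cur$st[j + 1L] <- prev$st[j + 1L]
      } else {
        cur$mt[j + 1L] <- cur$mt[j]; cur$st[j + 1L] <- cur$st[j]
      }
    }
    prev <- cur
  }
  jbest <- which.max(prev$sc[-1L])
  list(start = prev$st[jbest + 1L] + 1L, end = jbest,
       matches = prev$mt[jbest + 1L])
}

.overlap_frac <- function(ps, pe, ft, n) {
  if (!nrow(ft)) return(0)
  span <- ps:pe
  best <- 0
  for (i in seq_len(nrow(ft))) {
    other <- if (ft$end[i] >= ft$start[i]) ft$start[i]:ft$end[i]
             else c(ft$start[i]:n, 1L:ft$end[i])
    best <- max(best, length(intersect(span, other)) / length(span))
  }
  best
}

#' Curate annotation overlaps
#'
#' Applies the manual-curation rules used for honeybee mitogenomes: a PCG
#' overlapping a downstream tRNA is trimmed back to a truncated stop codon
#' (T or TA) at the tRNA boundary when one is available in frame — the cox1
#' case, where an apparent in-tRNA TAA is replaced by a truncated T,
#' shortening the gene and removing the overlap. The known atp8/atp6
#' overlap (19 bases) is whitelisted and preserved. Trims that would leave
#' an invalid CDS are aborted and flagged. The operation is idempotent.
#'
#' @param g annotated \linkS4class{MitoGenome}.
#' @param table a [codonTable()].
#' @param whitelist character vector of \code{"geneA/geneB"} PCG/PCG
#'   overlaps to preserve.
#' @return list with \code{genome} and \code{actions} (data.frame logging
#'   every rule applied or aborted).
#' @export
curateOverlaps <- function(g, table = codonTable(),
                           whitelist = "atp8/atp6") {
  ft <- g@features
  n <- nchar(g@seq)
  actions <- data.frame(gene = character(), action = character(),
                        detail = character(), stringsAsFactors = FALSE)
  if (nrow(ft) < 2L) return(list(genome = g, actions = actions))
  ord <- order(ft$start)
  ft <- ft[ord, , drop = FALSE]
  for (i in seq_len(nrow(ft))) {
    if (ft$fclass[i] != "PCG" || ft$strand[i] != "light") next
    for (j in seq_len(nrow(ft))) {
      if (i == j) next
      ov <- .span_overlap(ft$start[i], ft$end[i], ft$start[j], ft$end[j], n)
      if (ov <= 0L) next
      pairkey <- paste(ft$name[i], ft$name[j], sep = "/")
      if (ft$fclass[j] == "PCG" &&
          (pairkey %in% whitelist ||
           paste(ft$name[j], ft$name[i], sep = "/") %in% whitelist)) {
        actions <- rbind(actions, data.frame(
          gene = pairkey, action = "preserved",
          detail = sprintf("whitelisted PCG/PCG overlap of %d bases", ov),
          stringsAsFactors = FALSE))
        next
      }
      if (ft$fclass[j] != "tRNA") next
      # only curate when the tRNA starts inside the PCG tail
      # candidate new end: one base before the tRNA start
      new_end <- (ft$start[j] - 2L) %% n + 1L
      cds <- .circ_substr(g@seq, ft$start[i], new_end)
      len <- nchar(cds)
      rem <- len %% 3L
      tailok <- (rem == 1L && substr(cds, len, len) == "T") ||
                (rem == 2L && substr(cds, len - 1L, len) == "TA")
      if (!tailok) {
        actions <- rbind(actions, data.frame(
          gene = pairkey, action = "aborted",
          detail = "no truncated stop available at the tRNA boundary",
          stringsAsFactors = FALSE))
        next
      }
      tr <- tryCatch(translateCDS(cds, table), error = function(e) e)
      if (inherits(tr, "error")) {
        actions <- rbind(actions, data.frame(
          gene = pairkey, action = "aborted",
          detail = conditionMessage(tr), stringsAsFactors = FALSE))
        next
      }
      old_end <- ft$end[i]
      ft$end[i] <- new_end
      actions <- rbind(actions, data.frame(
        gene = ft$name[i], action = "trimmed",
        detail = sprintf(
          "end %d -> %d (-%d bp), stop recorded as truncated '%s'",
          old_end, new_end, ov, tr$stop_kind),
        stringsAsFactors = FALSE))
    }
  }
  g2 <- MitoGenome(g@id, g@seq, g@circular, ft)
  list(genome = g2, actions = actions)
}

# overlap length of two (possibly wrapped) spans on a circle
.span_overlap <- function(s1, e1, s2, e2, n) {
  pos1 <- if (e1 >= s1) s1:e1 else c(s1:n, 1L:e1)
  pos2 <- if (e2 >= s2) s2:e2 else c(s2:n, 1L:e2)
  length(intersect(pos1, pos2))
}

#' Gene order of a genome starting from the control region
#'
#' @param g annotated \linkS4class{MitoGenome} with a control feature.
#' @param classes feature classes to include (default all genes).
#' @return data.frame with columns \code{name}, \code{strand}, circularly
#'   ordered beginning with the first gene after the control region.
#' @export
geneOrder <- function(g, classes = c("PCG", "tRNA", "rRNA")) {
  ft <- g@features
  ctrl <- which(ft$fclass == "control")
  genes <- ft[ft$fclass %in% classes, , drop = FALSE]
  genes <- genes[order(genes$start), , drop = FALSE]
  if (length(ctrl)) {
    n <- nchar(g@seq)
    after <- (genes$start - ft$end[ctrl[1]]) %% n
    genes <- genes[order(after), , drop = FALSE]
  }
  data.frame(name = genes$name, strand = genes$strand,
             stringsAsFactors = FALSE)
}

#' Compare two circular gene orders
#'
#' Rotation-invariant adjacency comparison of two signed circular gene
#' orders. Genes absent from either order are reported and excluded.
#' Returns the adjacencies present in one order but not the other
#' (breakpoints) and the conserved-block decomposition of the first order.
#'
#' @param a,b data.frames with columns \code{name}, \code{strand} (as
#'   returned by [geneOrder()]).
#' @return list with \code{breakpoints} (data.frame of differing
#'   adjacencies), \code{n_breakpoints}, \code{blocks} (list of conserved
#'   runs of \code{a}), and \code{unshared} gene names.
#' @export
geneOrderDiff <- function(a, b) {
  shared <- intersect(a$name, b$name)
  unshared <- union(setdiff(a$name, b$name), setdiff(b$name, a$name))
  a2 <- a[a$name %in% shared, , drop = FALSE]
  b2 <- b[b$name %in% shared, , drop = FALSE]
  adj <- function(d) {
    k <- nrow(d)
    nxt <- c(2:k, 1L)
    # signed adjacency, canonicalised so orientation reversal matches
    fwd <- sprintf("%s(%s)>%s(%s)", d$name, d$strand,
                   d$name[nxt], d$strand[nxt])
    rev_strand <- c(light = "heavy", heavy = "light")
    bwd <- sprintf("%s(%s)>%s(%s)", d$name[nxt],
                   rev_strand[d$strand[nxt]], d$name,
                   rev_strand[d$strand])
    canon <- ifelse(fwd < bwd, fwd, bwd)
    data.frame(from = d$name, to = d$name[nxt], key = canon,
               stringsAsFactors = FALSE)
  }
  aa <- adj(a2); bb <- adj(b2)
  brk <- aa[!aa$key %in% bb$key, c("from", "to"), drop = FALSE]
  conserved <- aa$key %in% bb$key
  # conserved blocks: maximal runs of a2 whose internal adjacencies hold
  blocks <- list(); cur <- a2$name[1]
  k <- nrow(a2)
  for (i in seq_len(k - 1L)) {
    if (conserved[i]) cur <- c(cur, a2$name[i + 1L])
    else { blocks <- c(blocks, list(cur)); cur <- a2$name[i + 1L] }
  }
  if (conserved[k] && length(blocks)) {
    # circular closure: merge last block into first
    blocks[[1]] <- c(cur, blocks[[1]])
  } else blocks <- c(blocks, list(cur))
  list(breakpoints = brk, n_breakpoints = nrow(brk), blocks = blocks,
       unshared = unshared)
}

#' Read the bundled ancestral insect gene order
#'
#' The proposed ancestral insect (Drosophila-like) mitochondrial gene
#' arrangement, shipped as a plain-text fixture, for comparison against
#' honeybee gene orders.
#'
#' @return data.frame with columns \code{name}, \code{strand}.
#' @export
ancestralInsectOrder <- function() {
  path <- system.file("extdata", "ancestral_insect_gene_order.tsv",
                      package = "mitotrio")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
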