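# Variable-site discovery on an anchored MSA, uniqueness classification,
# coding-effect prediction, and report tallies.

#' Classify the uniqueness pattern of a set of alleles
#'
#' For three genomes (target first): \code{unique_target} when the target
#' allele differs and the two others agree; \code{unique_other1} /
#' \code{unique_other2} when the second / third genome is the odd one out;
#' \code{diagnostic_pair} when target and its conspecific (second genome)
#' agree and differ from the third; \code{all_distinct} otherwise.
#'
#' @param alleles character vector of alleles, target first (gaps as
#'   \code{"-"}).
#' @return the pattern string.
#' @export
classifyPattern <- function(alleles) {
  if (length(alleles) != 3L)
    .stop_domain("pattern classification needs exactly 3 genomes")
  a <- alleles[1]; b <- alleles[2]; c <- alleles[3]
  if (a == b && b == c) .stop_domain("alleles are not variable")
  if (b == c && a != b) return("unique_target")
  if (a == c && b != a) return("unique_other1")
  if (a == b && c != a) return("diagnostic_pair")
  "all_distinct"
}

#' Call variable events on an anchored MSA
#'
#' Every non-unanimous column belongs to exactly one event: a column where
#' all rows carry residues is a single-site substitution event; maximal
#' runs of contiguous columns sharing one gap pattern coalesce into one
#' indel event. Events carry a region classification from the target
#' annotation (the MSA reference); columns gapped in the reference are
#' attributed to the nearest reference position. Coding effects for PCG
#' events are predicted with [codingEffect()].
#'
#' @param msa an \linkS4class{AnchoredMSA} with >= 3 rows, reference =
#'   target genome.
#' @param target annotated \linkS4class{MitoGenome}; its sequence must
#'   equal the ungapped reference row.
#' @param table a [codonTable()].
#' @return data.frame of events: columns \code{col_start}, \code{col_end},
#'   \code{kind}, per-genome alleles \code{allele_<id>} and positions
#'   \code{pos_<id>}, \code{pattern}, \code{region_class},
#'   \code{region_name}, \code{effect}, \code{aa_from}, \code{aa_to}.
#' @export
callEvents <- function(msa, target, table = codonTable()) {
  rows <- alnRows(msa)
  if (length(rows) < 2L) .stop_domain("MSA must have at least 2 rows")
  if (.ungap(rows[[1]]) != target@seq)
    .stop_domain("target annotation does not match the MSA reference row")
  ids <- names(rows)
  M <- do.call(rbind, lapply(rows, .chars))
  nc <- ncol(M)
  refmap <- columnMap(rows[[1]])
  refnear <- .nearest_pos_map(rows[[1]])
  maps <- lapply(rows, columnMap)
  nears <- lapply(rows, .nearest_pos_map)

  isgap <- M == "-"
  varcol <- apply(M, 2L, function(cc) length(unique(cc)) > 1L)
  anygap <- colSums(isgap) > 0L
  gap_sig <- apply(isgap, 2L, function(cc) paste(as.integer(cc),
                                                 collapse = ""))
  events <- list()
  cc <- 1L
  while (cc <= nc) {
    if (!varcol[cc]) { cc <- cc + 1L; next }
    if (!anygap[cc]) {
      events[[length(events) + 1L]] <- list(c1 = cc, c2 = cc,
                                            kind = "substitution")
      cc <- cc + 1L
    } else {
      c2 <- cc
      while (c2 < nc && anygap[c2 + 1L] && gap_sig[c2 + 1L] == gap_sig[cc])
        c2 <- c2 + 1L
      events[[length(events) + 1L]] <- list(c1 = cc, c2 = c2,
                                            kind = "indel")
      cc <- c2 + 1L
    }
  }
  if (!length(events)) {
    out <- data.frame(col_start = integer(), col_end = integer(),
                      kind = character(), stringsAsFactors = FALSE)
    for (id in ids) {
      out[[paste0("allele_", id)]] <- character()
      out[[paste0("pos_", id)]] <- integer()
    }
    out$pattern <- character(); out$region_class <- character()
    out$region_name <- character(); out$effect <- character()
    out$aa_from <- character(); out$aa_to <- character()
    return(out)
  }

  recs <- lapply(events, function(e) {
    span <- e$c1:e$c2
    alleles <- apply(M[, span, drop = FALSE], 1L, function(r) {
      s <- paste(r[r != "-"], collapse = "")
      if (nzchar(s)) s else "-"
    })
    pos <- vapply(seq_along(ids), function(k) {
      p <- maps[[k]][e$c1]
      if (p > 0L) p else max(nears[[k]][e$c1], 1L)
    }, integer(1))
    rp <- refmap[e$c1]
    if (rp == 0L) rp <- max(refnear[e$c1], 1L)
    reg <- regionOf(target, rp)
    rec <- data.frame(col_start = e$c1, col_end = e$c2, kind = e$kind,
                      stringsAsFactors = FALSE)
    for (k in seq_along(ids)) {
      rec[[paste0("allele_", ids[k])]] <- alleles[k]
      rec[[paste0("pos_", ids[k])]] <- pos[k]
    }
    rec$pattern <- if (length(ids) == 3L) classifyPattern(alleles) else NA
    rec$region_class <- reg$fclass
    rec$region_name <- reg$name
    rec
  })
  out <- do.call(rbind, recs)
  eff <- lapply(seq_len(nrow(out)), function(i)
    codingEffect(out[i, ], msa, target, table))
  out$effect <- vapply(eff, `[[`, "", "effect")
  out$aa_from <- vapply(eff, `[[`, "", "aa_from")
  out$aa_to <- vapply(eff, `[[`, "", "aa_to")
  out
}

#' Predict the coding effect of one event
#'
#' Non-PCG events are \code{NA}. A PCG substitution is evaluated by
#' translating the codon containing the site from each genome's own
#' sequence (strand-aware); if the target amino acid differs from the
#' comparator's the event is \code{missense} with the change reported as
#' (other -> target), otherwise \code{synonymous}. The comparator is the
#' consensus of the non-target genomes when they agree (unique-target
#' events) and the differing third genome for diagnostic-pair events. An
#' indel whose length is not a multiple of three is a \code{frameshift}.
#' Events at annotated gene boundaries (start or stop codon, or codon
#' extraction crossing the feature edge) are \code{boundary}.
#'
#' @param event one row of the [callEvents()] data.frame.
#' @param msa the \linkS4class{AnchoredMSA} the event was called on.
#' @param target the annotated target genome.
#' @param table a [codonTable()].
#' @return list with \code{effect}, \code{aa_from}, \code{aa_to}.
#' @export
codingEffect <- function(event, msa, target, table = codonTable()) {
  na <- list(effect = NA_character_, aa_from = NA_character_,
             aa_to = NA_character_)
  if (event$region_class != "PCG") return(na)
  if (event$kind == "indel") {
    rows <- alnRows(msa)
    lens <- vapply(rows, function(r)
      sum(.chars(substr(r, event$col_start, event$col_end)) != "-"),
      integer(1))
    L <- max(lens)
    if (L %% 3L != 0L)
      return(list(effect = "frameshift", aa_from = NA_character_,
                  aa_to = NA_character_))
    return(na)
  }
  ft <- target@features
  gi <- which(ft$name == event$region_name & ft$fclass == "PCG")
  if (!length(gi)) return(na)
  f <- ft[gi[1], ]
  n <- nchar(target@seq)
  rows <- alnRows(msa)
  ids <- names(rows)
  tpos <- event[[paste0("pos_", ids[1])]]
  glen <- .span_len(f$start, f$end, n)
  off <- if (f$strand == "light") (tpos - f$start) %% n
         else (f$end - tpos) %% n
  codon_idx <- off %/% 3L            # 0-based codon index
  within <- off %% 3L                # 0-based position within codon
  ncod <- glen %/% 3L                # truncated tail excluded
  if (codon_idx == 0L || codon_idx >= ncod - 1L || off >= 3L * ncod)
    return(list(effect = "boundary", aa_from = NA_character_,
                aa_to = NA_character_))
  # genomic positions of the codon (in gene orientation)
  if (f$strand == "light") {
    gpos <- ((f$start - 1L + 3L * codon_idx + 0:2) %% n) + 1L
  } else {
    # ascending genome order; revComp below restores the coding frame
    gpos <- ((f$end - 1L - 3L * codon_idx - 2:0) %% n) + 1L
  }
  # map target positions to MSA columns
  tmap <- columnMap(rows[[1]])
  t2c <- integer(nchar(target@seq)); t2c[tmap[tmap > 0L]] <- which(tmap > 0L)
  cols <- t2c[gpos]
  if (any(cols == 0L))
    return(list(effect = "boundary", aa_from = NA_character_,
                aa_to = NA_character_))
  codon_of <- function(k) {
    ch <- vapply(cols, function(cc) substr(rows[[k]], cc, cc), "")
    if (any(ch == "-")) return(NA_character_)
    s <- paste(ch, collapse = "")
    if (f$strand == "heavy") s <- revComp(s)
    s
  }
  cods <- vapply(seq_along(ids), codon_of, "")
  if (anyNA(cods))
    return(list(effect = "boundary", aa_from = NA_character_,
                aa_to = NA_character_))
  aas <- unname(table$codons[cods])
  if (anyNA(aas) || any(aas == "*"))
    return(list(effect = "boundary", aa_from = NA_character_,
                aa_to = NA_character_))
  # comparator: consensus of the non-target genomes when they agree,
  # else the genome whose allele differs from the target
  tgt_aa <- aas[1]
  others <- aas[-1]
  cmp_aa <- if (length(unique(others)) == 1L) others[1] else {
    al <- vapply(ids, function(id) event[[paste0("allele_", id)]], "")
    odd <- which(al[-1] != al[1])
    others[if (length(odd)) odd[1] else 1L]
  }
  if (cmp_aa == tgt_aa)
    return(list(effect = "synonymous", aa_from = cmp_aa, aa_to = tgt_aa))
  list(effect = "missense", aa_from = cmp_aa, aa_to = tgt_aa)
}

#' Tally events into a comparison report
#'
#' Computes, for every genome pair, the number of variable sites (events
#' restricted to those where the pair's alleles differ), broken down by
#' region class; plus uniqueness-pattern tallies and the missense roster.
#' Under \code{count_mode = "event"} a multi-base indel counts once; under
#' \code{"column"} it counts one per alignment column it spans.
#'
#' @param events data.frame from [callEvents()].
#' @param ids genome ids (in MSA row order); inferred from the column names
#'   when NULL.
#' @param count_mode \code{"event"} or \code{"column"}.
#' @return list with \code{pair_totals}, \code{pair_by_region} (data.frame),
#'   \code{patterns} (table), \code{missense} (data.frame roster),
#'   \code{count_mode}.
#' @export
tallyEvents <- function(events, ids = NULL, count_mode = c("event",
                                                           "column")) {
  count_mode <- match.arg(count_mode)
  if (is.null(ids))
    ids <- sub("^allele_", "",
               grep("^allele_", names(events), value = TRUE))
  w <- if (count_mode == "event") rep(1L, nrow(events)) else
    events$col_end - events$col_start + 1L
  pairs <- utils::combn(ids, 2L, simplify = FALSE)
  pt <- list(); pr <- list()
  for (p in pairs) {
    key <- paste(p, collapse = "|")
    dif <- events[[paste0("allele_", p[1])]] !=
           events[[paste0("allele_", p[2])]]
    pt[[key]] <- sum(w[dif])
    if (any(dif)) {
      agg <- stats::aggregate(w[dif],
                              by = list(region = events$region_class[dif]),
                              FUN = sum)
      pr[[key]] <- data.frame(pair = key, region = agg$region,
                              n = agg$x, stringsAsFactors = FALSE)
    }
  }
  miss <- events[!is.na(events$effect) & events$effect == "missense", ,
                 drop = FALSE]
  list(pair_totals = unlist(pt),
       pair_by_region = if (length(pr)) do.call(rbind, pr) else
         data.frame(pair = character(), region = character(),
                    n = numeric()),
       patterns = table(events$pattern),
       missense = miss, count_mode = count_mode)
}

#' Export events as TSV (Table 1/2 layout) or minimal VCF
#'
#' The TSV mirrors the published table layout: alignment position,
#' per-genome position and allele, region, amino-acid change. The VCF uses
#' the target as reference, 1-based positions, indels left-aligned with the
#' anchor-base convention.
#'
#' @param events data.frame from [callEvents()].
#' @param path output path.
#' @param target annotated target genome (needed for VCF anchor bases).
#' @return \code{path}, invisibly.
#' @export
writeEventsTSV <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsTSV
#' @export
writeEventsVCF <- function(events, target, path) {
  ids <- sub("^allele_", "", grep("^allele_", names(events), value = TRUE))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(sprintf("##reference=%s", target@id), con)
  writeLines(sprintf("##contig=<ID=%s,length=%d>", target@id,
                     nchar(target@seq)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO"), collapse = "\t"), con)
  tcol <- paste0("allele_", ids[1])
  pcol <- paste0("pos_", ids[1])
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    alt_all <- unique(unlist(ev[paste0("allele_", ids[-1])]))
    alt_all <- setdiff(alt_all, ev[[tcol]])
    if (ev$kind == "substitution") {
      pos <- ev[[pcol]]; ref <- ev[[tcol]]; alts <- alt_all
    } else {
      # anchor-base convention
      pos <- max(ev[[pcol]] - 1L, 1L)
      anchor <- substr(target@seq, pos, pos)
      reft <- if (ev[[tcol]] == "-") "" else ev[[tcol]]
      ref <- paste0(anchor, reft)
      alts <- vapply(alt_all, function(a)
        paste0(anchor, if (a == "-") "" else a), "")
    }
    writeLines(paste(c(target@id, pos, sprintf("ev%d", i), ref,
                       paste(alts, collapse = ","), ".", "PASS",
                       sprintf("KIND=%s;REGION=%s;PATTERN=%s", ev$kind,
                               ev$region_class, ev$pattern)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
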