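# Seeded synthetic honeybee-like mitogenome trios with a ground-truth
# ledger, emulating the statistical structure the comparative analysis
# assumes: ~16.4 kb circular AT-rich (85%) genomes carrying 13 PCGs with
# valid invertebrate-mitochondrial-code ORFs, 22 tRNAs (63-78 bp), 2 rRNAs
# and an AT-rich control region in the A. mellifera gene arrangement, with
# the atp8/atp6 19-base overlap and a truncated-T cox1 stop.

.BASE_PROBS <- c(A = 0.43, C = 0.095, G = 0.055, T = 0.42)
.CR_PROBS <- c(A = 0.50, C = 0.02, G = 0.02, T = 0.46)

# start codons per PCG reproducing the canonical tally
# (one ATC, three ATG, three ATA, six ATT)
.START_ASSIGN <- c(nd2 = "ATA", cox1 = "ATT", cox2 = "ATT", atp8 = "ATT",
                   atp6 = "ATG", cox3 = "ATG", nd3 = "ATT", nd5 = "ATT",
                   nd4 = "ATA", nd4l = "ATT", nd6 = "ATA", cytb = "ATG",
                   nd1 = "ATC")

#' The honeybee-like genome template
#'
#' Gene layout (names, classes, strands, lengths, downstream spacers) in
#' the A. mellifera arrangement, starting at the first gene after the
#' control region and ending with the control region. Negative spacer
#' encodes the atp8/atp6 overlap (19 bases). Total genome length 16,447 bp.
#'
#' @param at_target target AT fraction of the genome (default 0.85).
#' @return list with \code{layout} (data.frame), \code{at_target}, and
#'   \code{truncated_gene} (the PCG ending on a truncated T).
#' @export
beeTemplate <- function(at_target = 0.85) {
  L <- function(name, fclass, strand, len, sp, notes = "")
    data.frame(name = name, fclass = fclass, strand = strand,
               length = len, spacer_after = sp, notes = notes,
               stringsAsFactors = FALSE)
  layout <- rbind(
    L("tRNA-Glu",  "tRNA", "light", 65L, 3L),
    L("tRNA-Ser1", "tRNA", "light", 63L, 12L),
    L("tRNA-Met",  "tRNA", "light", 69L, 5L),
    L("tRNA-Gln",  "tRNA", "light", 63L, 60L),
    L("tRNA-Ala",  "tRNA", "light", 68L, 9L),
    L("tRNA-Ile",  "tRNA", "light", 70L, 17L),
    L("nd2",  "PCG", "light", 1002L, 34L),
    L("tRNA-Cys",  "tRNA", "heavy", 66L, 2L),
    L("tRNA-Tyr",  "tRNA", "heavy", 66L, 49L),
    L("tRNA-Trp",  "tRNA", "light", 68L, 47L),
    L("cox1", "PCG", "light", 1564L, 0L),
    L("tRNA-Leu1", "tRNA", "light", 67L, 96L, notes = "anticodon=UUR"),
    L("cox2", "PCG", "light", 678L, 19L),
    L("tRNA-Asp",  "tRNA", "light", 68L, 8L),
    L("tRNA-Lys",  "tRNA", "light", 70L, 15L),
    L("atp8", "PCG", "light", 159L, -19L),
    L("atp6", "PCG", "light", 678L, 30L),
    L("cox3", "PCG", "light", 780L, 14L),
    L("tRNA-Gly",  "tRNA", "light", 66L, 6L),
    L("nd3",  "PCG", "light", 354L, 22L),
    L("tRNA-Arg",  "tRNA", "heavy", 65L, 11L),
    L("tRNA-Asn",  "tRNA", "light", 67L, 26L),
    L("tRNA-Phe",  "tRNA", "heavy", 67L, 4L),
    L("nd5",  "PCG", "heavy", 1665L, 70L),
    L("tRNA-His",  "tRNA", "heavy", 66L, 13L),
    L("nd4",  "PCG", "heavy", 1338L, 1L),
    L("nd4l", "PCG", "heavy", 264L, 70L),
    L("tRNA-Thr",  "tRNA", "light", 78L, 10L),
    L("tRNA-Pro",  "tRNA", "heavy", 66L, 7L),
    L("nd6",  "PCG", "light", 498L, 2L),
    L("cytb", "PCG", "light", 1149L, 16L),
    L("tRNA-Ser2", "tRNA", "light", 72L, 21L),
    L("nd1",  "PCG", "heavy", 915L, 18L),
    L("tRNA-Leu2", "tRNA", "heavy", 71L, 5L, notes = "anticodon=CUN"),
    L("16S rRNA",  "rRNA", "heavy", 1371L, 3L),
    L("tRNA-Val",  "tRNA", "heavy", 69L, 9L),
    L("12S rRNA",  "rRNA", "heavy", 786L, 96L),
    L("control_region", "control", "light", 945L, 0L))
  list(layout = layout, at_target = at_target, truncated_gene = "cox1")
}

.sample_bases <- function(n, probs = .BASE_PROBS) {
  if (n <= 0L) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

.sample_codon <- function(table, probs = .BASE_PROBS) {
  repeat {
    cod <- paste(.sample_bases(3L, probs), collapse = "")
    if (!cod %in% table$stops) return(cod)
  }
}

.sample_codons <- function(k, table, probs = .BASE_PROBS) {
  if (k <= 0L) return(character(0))
  vapply(seq_len(k), function(i) .sample_codon(table, probs), "")
}

# the 19-base atp8/atp6 overlap block: atp6's ATG + codons 2..6 + one base,
# simultaneously a valid atp8 tail ending in TAA
.overlap_block <- function(table) {
  repeat {
    c2to5 <- .sample_codons(4L, table)
    b16 <- .sample_bases(1L)
    B <- paste0("ATG", paste(c2to5, collapse = ""), b16, "TAA")
    stopifnot(nchar(B) == 19L)
    # atp8-frame codons at B[2..4], B[5..7], ..., B[14..16] must be non-stop
    shifted <- substring(B, seq(2L, 14L, 3L), seq(4L, 16L, 3L))
    if (!any(shifted %in% table$stops)) return(B)
  }
}

#' Generate the base synthetic mitogenome
#'
#' Deterministic under \code{seed}. Every PCG is a valid table-5 ORF with
#' its assigned start codon and a TAA stop (cox1 ends on a truncated T);
#' the atp8/atp6 overlap is generated jointly so both frames are clean;
#' tRNA-Leu1 begins TTTAA so that a naive cox1 annotation extended into it
#' finds an apparent TAA (the curation scenario). The AT fraction lands
#' within about one percent of the template target.
#'
#' @param template a [beeTemplate()].
#' @param seed integer RNG seed.
#' @param id genome label.
#' @return list with \code{genome} (annotated \linkS4class{MitoGenome})
#'   and \code{codons} (data.frame of assigned start/stop per PCG).
#' @export
makeBase <- function(template = beeTemplate(), seed = 1L, id = "base") {
  set.seed(seed)
  table <- codonTable()
  lay <- template$layout
  if (any(lay$spacer_after < 0L & lay$name != "atp8"))
    .stop_domain("only the atp8/atp6 overlap is whitelisted in the layout")
  pieces <- character(0)
  feats <- list()
  codons <- list()
  pos <- 1L
  pending_atp6 <- NULL
  for (i in seq_len(nrow(lay))) {
    row <- lay[i, ]
    if (row$name == "atp6") {
      # first 19 bases already emitted with atp8; generate the continuation
      stopifnot(!is.null(pending_atp6))
      ncod <- row$length %/% 3L
      # codon 7 begins with the overlap's final A
      cont_cod7 <- repeat_until_nonstop_tail(table)
      body <- .sample_codons(ncod - 8L, table)
      gene_seq_tail <- paste0(cont_cod7, paste(body, collapse = ""), "TAA")
      stopifnot(nchar(gene_seq_tail) == row$length - 19L)
      pieces <- c(pieces, gene_seq_tail)
      start <- pending_atp6
      end <- start + row$length - 1L
      feats[[length(feats) + 1L]] <- data.frame(
        name = row$name, fclass = row$fclass, strand = row$strand,
        start = start, end = end, notes = row$notes,
        stringsAsFactors = FALSE)
      codons[[length(codons) + 1L]] <- data.frame(
        gene = row$name, start_codon = "ATG", stop_kind = "TAA",
        stringsAsFactors = FALSE)
      pos <- end + 1L
      pending_atp6 <- NULL
    } else if (row$fclass == "PCG") {
      truncated <- row$name == template$truncated_gene
      startc <- .START_ASSIGN[[row$name]]
      if (row$name == "atp8") {
        # 46 codons + 2 bases of codon 47 + the 19-base overlap block
        ncod <- row$length %/% 3L  # 53
        interior <- .sample_codons(ncod - 7L - 1L, table)
        c47a <- repeat_until_not_TA()
        B <- .overlap_block(table)
        gene_seq <- paste0(startc, paste(interior, collapse = ""), c47a, B)
        stopifnot(nchar(gene_seq) == row$length)
        pending_atp6 <- pos + row$length - 19L
      } else if (truncated) {
        ncod <- (row$length - 1L) %/% 3L
        interior <- .sample_codons(ncod - 1L, table)
        gene_seq <- paste0(startc, paste(interior, collapse = ""), "T")
      } else {
        ncod <- row$length %/% 3L
        interior <- .sample_codons(ncod - 2L, table)
        gene_seq <- paste0(startc, paste(interior, collapse = ""), "TAA")
      }
      genome_seq <- if (row$strand == "heavy") revComp(gene_seq) else
        gene_seq
      pieces <- c(pieces, genome_seq)
      feats[[length(feats) + 1L]] <- data.frame(
        name = row$name, fclass = row$fclass, strand = row$strand,
        start = pos, end = pos + row$length - 1L, notes = row$notes,
        stringsAsFactors = FALSE)
      codons[[length(codons) + 1L]] <- data.frame(
        gene = row$name, start_codon = startc,
        stop_kind = if (truncated) "T" else "TAA",
        stringsAsFactors = FALSE)
      pos <- pos + row$length
    } else {
      probs <- if (row$fclass == "control") .CR_PROBS else .BASE_PROBS
      s <- paste(.sample_bases(row$length, probs), collapse = "")
      if (row$name == "tRNA-Leu1")
        s <- paste0("TTTAA", substr(s, 6L, nchar(s)))
      pieces <- c(pieces, s)
      feats[[length(feats) + 1L]] <- data.frame(
        name = row$name, fclass = row$fclass, strand = row$strand,
        start = pos, end = pos + row$length - 1L, notes = row$notes,
        stringsAsFactors = FALSE)
      pos <- pos + row$length
    }
    sp <- row$spacer_after
    if (sp > 0L) {
      spacer <- paste(.sample_bases(sp), collapse = "")
      if (row$name == "tRNA-Leu1" && sp >= 60L) {
        # plant two DraI sites in the mitotype marker spacer
        substr(spacer, 11L, 16L) <- "TTTAAA"
        substr(spacer, 51L, 56L) <- "TTTAAA"
      }
      pieces <- c(pieces, spacer)
      pos <- pos + sp
    }
  }
  seq <- paste(pieces, collapse = "")
  g <- MitoGenome(id, seq, circular = TRUE, features = do.call(rbind, feats))
  list(genome = g, codons = do.call(rbind, codons))
}

# codon starting with A (continuation of the overlap's final base belongs
# to codon 7, so only two bases are drawn here); A-initial codons are never
# stops, kept as a helper for clarity
repeat_until_nonstop_tail <- function(table) {
  paste(.sample_bases(2L), collapse = "")
}

# two bases (x, y) != (T, A): the atp8 codon ending on the overlap's first
# base A must not become TAA
repeat_until_not_TA <- function() {
  repeat {
    xy <- .sample_bases(2L)
    if (!(xy[1] == "T" && xy[2] == "A")) return(paste(xy, collapse = ""))
  }
}

#' Default plant specification
#'
#' Counts of planted events per (pattern, region class, kind, effect),
#' mirroring the observed spectrum of a conspecific trio: 44 events unique
#' to the target (8 of them missense, one a 4 bp rRNA deletion) and 23
#' diagnostic events shared by the conspecific pair (3 missense).
#'
#' @return data.frame with columns \code{pattern}, \code{region},
#'   \code{kind}, \code{effect}, \code{len}, \code{count}.
#' @export
defaultPlantSpec <- function() {
  S <- function(pattern, region, kind, effect, len, count)
    data.frame(pattern = pattern, region = region, kind = kind,
               effect = effect, len = len, count = count,
               stringsAsFactors = FALSE)
  rbind(
    S("unique_target", "PCG", "substitution", "missense", 1L, 8L),
    S("unique_target", "PCG", "substitution", "synonymous", 1L, 8L),
    S("unique_target", "tRNA", "substitution", NA, 1L, 3L),
    S("unique_target", "rRNA", "substitution", NA, 1L, 7L),
    S("unique_target", "16S rRNA", "deletion", NA, 4L, 1L),
    S("unique_target", "control", "substitution", NA, 1L, 8L),
    S("unique_target", "control", "deletion", NA, 2L, 1L),
    S("unique_target", "control", "insertion", NA, 3L, 1L),
    S("unique_target", "intergenic", "substitution", NA, 1L, 7L),
    S("diagnostic_pair", "PCG", "substitution", "missense", 1L, 3L),
    S("diagnostic_pair", "PCG", "substitution", "synonymous", 1L, 5L),
    S("diagnostic_pair", "tRNA", "substitution", NA, 1L, 2L),
    S("diagnostic_pair", "rRNA", "substitution", NA, 1L, 5L),
    S("diagnostic_pair", "control", "substitution", NA, 1L, 4L),
    S("diagnostic_pair", "intergenic", "substitution", NA, 1L, 3L),
    S("diagnostic_pair", "intergenic", "deletion", NA, 2L, 1L))
}

# which genome receives the mutation for each pattern (target first)
.PATTERN_CARRIER <- c(unique_target = "target", unique_other1 = "sib",
                      diagnostic_pair = "other")

#' Generate a synthetic trio with ground truth
#'
#' Plants the events of \code{plant_spec} into copies of the base genome:
#' \code{unique_target} events mutate the target only,
#' \code{unique_other1} the conspecific sibling only, and
#' \code{diagnostic_pair} the third (outgroup-subspecies-like) genome only,
#' so that the carnica-pair alleles stay ancestral. Missense and synonymous
#' plants are verified against the invertebrate mitochondrial code at
#' generation time; indels are re-drawn until their placement is
#' unambiguous under gap left-normalisation; all events keep a minimum
#' spacing and stay clear of feature boundaries. Each genome is finally
#' rotated by a recorded random offset.
#'
#' @param base result of [makeBase()] (list with genome and codons).
#' @param plant_spec data.frame as [defaultPlantSpec()].
#' @param seed integer RNG seed.
#' @param ids labels for (target, conspecific, other).
#' @param rotate apply random rotations (default TRUE).
#' @return list with \code{genomes} (named list: target and conspecific
#'   unannotated, other annotated — the annotation-transfer reference) and
#'   \code{ledger} (a \linkS4class{TrioLedger}; coordinates are in the
#'   analysis frame, i.e. before rotation).
#' @export
makeTrio <- function(base, plant_spec = defaultPlantSpec(), seed = 1L,
                     ids = c(target = "SIC", sib = "ATC", other = "REF"),
                     rotate = TRUE) {
  set.seed(seed + 1L)
  g0 <- base$genome
  table <- codonTable()
  n <- nchar(g0@seq)
  ft <- g0@features
  basech <- .chars(g0@seq)
  min_sep <- 15L
  edge_pad <- 6L

  if (nrow(plant_spec) &&
      any(!plant_spec$pattern %in% names(.PATTERN_CARRIER)))
    .stop_domain("unsupported pattern in plant_spec")
  if (nrow(plant_spec) &&
      any(plant_spec$region != "PCG" & !is.na(plant_spec$effect)))
    .stop_domain("coding effects can only be planted in PCGs")

  used <- integer(0)  # base positions already claimed (with halo)
  claim <- function(p, len = 1L) {
    span <- (p - min_sep):(p + len - 1L + min_sep)
    if (any(span %in% used)) return(FALSE)
    used <<- c(used, (p - min_sep):(p + len - 1L + min_sep))
    TRUE
  }

  # positions covered by exactly one feature, away from its edges
  singly <- function(frow) {
    lo <- frow$start + edge_pad
    hi <- frow$end - edge_pad
    if (hi < lo) return(integer(0))
    lo:hi
  }
  gaps <- .unannotated_gaps(g0)

  events <- list()
  plant_one <- function(spec_row) {
    pattern <- spec_row$pattern
    carrier <- .PATTERN_CARRIER[[pattern]]
    kind <- spec_row$kind
    len <- spec_row$len
    for (try in 1:500) {
      if (spec_row$region == "PCG" || !is.na(spec_row$effect)) {
        ev <- .plant_pcg_sub(g0, ft, table, spec_row$effect, claim)
      } else if (kind == "substitution") {
        ev <- .plant_plain_sub(g0, ft, gaps, spec_row$region, singly, claim)
      } else {
        ev <- .plant_indel(g0, ft, gaps, spec_row$region, kind, len,
                           singly, claim, basech)
      }
      if (!is.null(ev)) {
        ev$pattern <- pattern
        ev$carrier <- carrier
        return(ev)
      }
    }
    .stop_domain("could not place a %s %s event in region '%s'",
                 pattern, kind, spec_row$region)
  }
  for (i in seq_len(nrow(plant_spec))) {
    for (k in seq_len(plant_spec$count[i]))
      events[[length(events) + 1L]] <- plant_one(plant_spec[i, ])
  }

  ev <- if (length(events)) do.call(rbind, lapply(events, as.data.frame))
        else data.frame()
  if (nrow(ev)) {
    # expected amino-acid change direction as reported downstream:
    # (comparator -> target); the comparator carries the mutation unless
    # the target itself does
    tgt_mut <- ev$carrier == "target"
    ev$aa_from <- ifelse(tgt_mut, ev$aa_base, ev$aa_mut)
    ev$aa_to <- ifelse(tgt_mut, ev$aa_mut, ev$aa_base)
  }
  # apply to sequences ------------------------------------------------
  genome_names <- c("target", "sib", "other")
  seqs <- list(); shifts <- list(); truth <- list()
  for (gn in genome_names) {
    mine <- if (nrow(ev)) ev[ev$carrier == gn, , drop = FALSE] else ev
    res <- .apply_events(basech, mine)
    seqs[[gn]] <- res$seq
    shifts[[gn]] <- res$shift  # function(base_pos) -> genome pos
    truth_ft <- ft
    if (nrow(truth_ft)) {
      truth_ft$start <- vapply(truth_ft$start, res$shift, integer(1))
      truth_ft$end <- vapply(truth_ft$end, res$shift, integer(1))
    }
    truth[[ids[[gn]]]] <- truth_ft
  }

  # ledger coordinates ------------------------------------------------
  if (nrow(ev)) {
    for (gn in genome_names) {
      id <- ids[[gn]]
      posv <- integer(nrow(ev)); allv <- character(nrow(ev))
      for (i in seq_len(nrow(ev))) {
        e <- ev[i, ]
        carrier <- e$carrier == gn
        if (e$kind == "substitution") {
          posv[i] <- shifts[[gn]](e$base_pos)
          allv[i] <- if (carrier) e$alt else e$ref
        } else if (e$kind == "deletion") {
          if (carrier) {
            posv[i] <- shifts[[gn]](e$base_pos - 1L)
            allv[i] <- "-"
          } else {
            posv[i] <- shifts[[gn]](e$base_pos)
            allv[i] <- e$ref
          }
        } else {  # insertion after base_pos
          if (carrier) {
            posv[i] <- shifts[[gn]](e$base_pos) + 1L
            allv[i] <- e$alt
          } else {
            posv[i] <- shifts[[gn]](e$base_pos)
            allv[i] <- "-"
          }
        }
      }
      ev[[paste0("pos_", id)]] <- posv
      ev[[paste0("allele_", id)]] <- allv
    }
  }

  rotations <- setNames(integer(3), unname(ids))
  genomes <- list()
  for (gn in genome_names) {
    id <- ids[[gn]]
    feats <- if (gn == "other") truth[[id]] else .empty_features()
    g <- MitoGenome(id, paste(seqs[[gn]], collapse = ""), TRUE, feats)
    k <- if (rotate) sample.int(nchar(g@seq), 1L) - 1L else 0L
    rotations[id] <- k
    genomes[[id]] <- if (k > 0L) rotateGenome(g, k) else g
  }

  ledger <- new("TrioLedger",
                events = if (nrow(ev)) ev else data.frame(),
                rotations = rotations,
                codons = base$codons,
                truth = truth)
  list(genomes = genomes, ledger = ledger)
}

# --- planting helpers -------------------------------------------------

# PCG substitution with a required coding effect
.plant_pcg_sub <- function(g0, ft, table, effect, claim) {
  pcg <- ft[ft$fclass == "PCG", , drop = FALSE]
  w <- pmax(pcg$end - pcg$start + 1L, 1L)
  gi <- sample.int(nrow(pcg), 1L, prob = w)
  f <- pcg[gi, ]
  n <- nchar(g0@seq)
  glen <- f$end - f$start + 1L
  ncod <- glen %/% 3L
  ci <- sample(1:(ncod - 2L), 1L)          # 0-based interior codon index
  within <- if (effect == "synonymous") 2L else sample(0:1, 1L)
  if (f$strand == "light") {
    gpos <- f$start + 3L * ci + within
    codon_pos <- f$start + 3L * ci + 0:2
  } else {
    gpos <- f$end - 3L * ci - within
    codon_pos <- f$end - 3L * ci - 2:0   # ascending; revComp restores frame
  }
  # require single-feature coverage (avoid the atp8/atp6 overlap)
  cover <- sum(ft$start <= gpos & ft$end >= gpos)
  if (cover != 1L) return(NULL)
  if (!claim(gpos)) return(NULL)
  codon <- paste(.chars(g0@seq)[codon_pos], collapse = "")
  if (f$strand == "heavy") codon <- revComp(codon)
  aa0 <- unname(table$codons[codon])
  base_cod <- .chars(codon)[within + 1L]
  for (b in sample(setdiff(c("A", "C", "G", "T"), base_cod))) {
    new_codon <- codon
    substr(new_codon, within + 1L, within + 1L) <- b
    if (new_codon %in% table$stops) next
    aa1 <- unname(table$codons[new_codon])
    if (aa1 == "*") next
    hit <- if (effect == "missense") aa1 != aa0 else aa1 == aa0
    if (hit) {
      refb <- substr(g0@seq, gpos, gpos)
      altb <- if (f$strand == "heavy") revComp(b) else b
      return(list(kind = "substitution", base_pos = gpos, len = 1L,
                  ref = refb, alt = altb, region_class = "PCG",
                  region_name = f$name, effect = effect,
                  aa_base = aa0, aa_mut = aa1))
    }
  }
  NULL
}

.region_positions <- function(ft, gaps, region, singly) {
  if (region == "intergenic") {
    ok <- gaps[gaps$end - gaps$start + 1L >= 13L, , drop = FALSE]
    if (!nrow(ok)) return(integer(0))
    unlist(lapply(seq_len(nrow(ok)), function(i)
      (ok$start[i] + 4L):(ok$end[i] - 4L)))
  } else {
    sel <- if (region %in% FCLASSES) ft$fclass == region else
      ft$name == region
    rows <- ft[sel, , drop = FALSE]
    if (!nrow(rows)) return(integer(0))
    unlist(lapply(seq_len(nrow(rows)), function(i) singly(rows[i, ])))
  }
}

.plant_plain_sub <- function(g0, ft, gaps, region, singly, claim) {
  cand <- .region_positions(ft, gaps, region, singly)
  if (!length(cand)) return(NULL)
  gpos <- sample(cand, 1L)
  cover <- sum(ft$start <= gpos & ft$end >= gpos)
  if (cover > 1L) return(NULL)
  if (!claim(gpos)) return(NULL)
  refb <- substr(g0@seq, gpos, gpos)
  altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
  reg <- regionOf(g0, gpos)
  list(kind = "substitution", base_pos = gpos, len = 1L, ref = refb,
       alt = altb, region_class = reg$fclass, region_name = reg$name,
       effect = NA_character_, aa_base = NA_character_,
       aa_mut = NA_character_)
}

.plant_indel <- function(g0, ft, gaps, region, kind, len, singly, claim,
                         basech) {
  cand <- .region_positions(ft, gaps, region, singly)
  if (!length(cand)) return(NULL)
  gpos <- sample(cand, 1L)
  cover <- sum(ft$start <= gpos & ft$end >= gpos)
  if (cover > 1L) return(NULL)
  if (kind == "deletion") {
    if (!all((gpos:(gpos + len - 1L)) %in% cand)) return(NULL)
    # unambiguous under left-normalisation: left flank differs from the
    # run's last base
    if (basech[gpos - 1L] == basech[gpos + len - 1L]) return(NULL)
    if (!claim(gpos, len)) return(NULL)
    reg <- regionOf(g0, gpos)
    return(list(kind = "deletion", base_pos = gpos, len = len,
                ref = paste(basech[gpos:(gpos + len - 1L)], collapse = ""),
                alt = "-", region_class = reg$fclass,
                region_name = reg$name, effect = NA_character_,
                aa_base = NA_character_, aa_mut = NA_character_))
  }
  # insertion after gpos
  ins <- paste(.sample_bases(len), collapse = "")
  if (substr(ins, len, len) == basech[gpos]) {
    # re-draw last base so the gap cannot shift left
    alt_last <- sample(setdiff(c("A", "C", "G", "T"), basech[gpos]), 1L)
    substr(ins, len, len) <- alt_last
  }
  if (!claim(gpos, 1L)) return(NULL)
  reg <- regionOf(g0, gpos)
  list(kind = "insertion", base_pos = gpos, len = len, ref = "-",
       alt = ins, region_class = reg$fclass, region_name = reg$name,
       effect = NA_character_, aa_base = NA_character_,
       aa_mut = NA_character_)
}

# apply a genome's own events to the base character vector; returns the
# mutated char vector and a base-position -> genome-position mapper
.apply_events <- function(basech, ev) {
  n <- length(basech)
  if (!nrow(ev)) {
    return(list(seq = basech, shift = function(p) as.integer(p)))
  }
  ev <- ev[order(ev$base_pos), , drop = FALSE]
  out <- list()
  cursor <- 1L
  brk_pos <- integer(0); brk_delta <- integer(0)
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (e$kind == "substitution") {
      out[[length(out) + 1L]] <- basech[cursor:e$base_pos]
      out[[length(out)]][length(out[[length(out)]])] <- e$alt
      cursor <- e$base_pos + 1L
    } else if (e$kind == "deletion") {
      if (e$base_pos > cursor)
        out[[length(out) + 1L]] <- basech[cursor:(e$base_pos - 1L)]
      cursor <- e$base_pos + e$len
      brk_pos <- c(brk_pos, e$base_pos + e$len - 1L)
      brk_delta <- c(brk_delta, -e$len)
    } else {  # insertion after base_pos
      out[[length(out) + 1L]] <- basech[cursor:e$base_pos]
      out[[length(out) + 1L]] <- .chars(e$alt)
      cursor <- e$base_pos + 1L
      brk_pos <- c(brk_pos, e$base_pos)
      brk_delta <- c(brk_delta, e$len)
    }
  }
  if (cursor <= n) out[[length(out) + 1L]] <- basech[cursor:n]
  seqv <- unlist(out)
  shift <- function(p) {
    as.integer(p + sum(brk_delta[brk_pos < p]))
  }
  list(seq = seqv, shift = shift)
}
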