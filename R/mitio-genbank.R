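# GenBank flat-file reader/writer (NCBI LOCUS/FEATURES/ORIGIN dialect).
# Hand-written because the feature-table dialect has no installed R parser;
# only the subset used by mitochondrial records is supported.

# feature keys mapped to fclass; anything else is kept as notes on a
# misc_feature-style record or ignored (gene lines duplicate CDS/tRNA/rRNA)
.GB_KEY_MAP <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                 D_loop = "control", misc_feature = "intergenic")

#' Read a GenBank flat file into a MitoGenome
#'
#' Parses the LOCUS line (length, topology), the FEATURES table and the
#' ORIGIN sequence block. \code{CDS}, \code{tRNA}, \code{rRNA},
#' \code{D-loop} and \code{misc_feature} entries become typed features;
#' \code{complement(...)} locations map to the heavy strand and
#' \code{join(x..N,1..y)} locations spanning the origin become wrapped
#' spans. Unknown feature keys raise a warning and are stored with their
#' qualifiers in \code{notes}. If the record leaves the control region
#' unannotated, the longest unannotated gap is synthesised as a feature
#' named \code{control_region} when \code{infer_control = TRUE}.
#'
#' @param path path to a GenBank flat file.
#' @param infer_control synthesise a \code{control_region} feature from the
#'   longest unannotated gap (>= 200 bp) when none is annotated.
#' @return a \linkS4class{MitoGenome}.
#' @export
readGenBank <- function(path, infer_control = TRUE) {
  lines <- readLines(path, warn = FALSE)
  iloc <- grep("^LOCUS", lines)
  if (!length(iloc))
    .stop_parse("%s: no LOCUS line", path)
  loc <- lines[iloc[1]]
  toks <- strsplit(trimws(loc), "\\s+")[[1]]
  if (length(toks) < 3L || is.na(suppressWarnings(as.integer(toks[3]))))
    .stop_parse("malformed LOCUS line (line %d): %s", iloc[1], loc)
  declared_len <- as.integer(toks[3])
  circular <- any(grepl("circular", loc, ignore.case = TRUE))
  id <- toks[2]

  iver <- grep("^VERSION", lines)
  if (length(iver)) {
    vt <- strsplit(trimws(lines[iver[1]]), "\\s+")[[1]]
    if (length(vt) >= 2L) id <- vt[2]
  }

  ifeat <- grep("^FEATURES", lines)
  iorig <- grep("^ORIGIN", lines)
  if (!length(iorig))
    .stop_parse("%s: no ORIGIN block", path)
  iend <- grep("^//", lines)
  iend <- if (length(iend)) iend[iend > iorig[1]][1] else length(lines) + 1L
  seqlines <- lines[(iorig[1] + 1L):(iend - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (grepl("[^ACGTN]", seq))
    .stop_parse("%s: ambiguity codes other than N are not supported", path)
  if (nchar(seq) == 0L)
    .stop_parse("%s: empty ORIGIN block (line %d)", path, iorig[1])
  if (nchar(seq) != declared_len)
    warning(sprintf("LOCUS declares %d bp but ORIGIN has %d bp",
                    declared_len, nchar(seq)))

  feats <- .empty_features()
  if (length(ifeat)) {
    fend <- iorig[1] - 1L
    flines <- lines[(ifeat[1] + 1L):fend]
    # group lines into entries: a new entry starts with a key at column 6
    starts <- grep("^ {5}\\S", flines)
    for (e in seq_along(starts)) {
      from <- starts[e]
      to <- if (e < length(starts)) starts[e + 1L] - 1L else length(flines)
      entry <- flines[from:to]
      key <- sub("^ {5}(\\S+).*$", "\\1", entry[1])
      locstr <- trimws(sub("^ {5}\\S+\\s*", "", entry[1]))
      # location may continue on following lines until a qualifier starts
      qi <- grep("^\\s+/", entry)
      locend <- if (length(qi)) qi[1] - 1L else length(entry)
      if (locend > 1L)
        locstr <- paste0(locstr,
                         paste(trimws(entry[2:locend]), collapse = ""))
      quals <- .gb_parse_qualifiers(entry[if (length(qi)) qi[1]:length(entry)
                                          else integer()])
      if (key %in% c("source", "gene")) next
      key_std <- gsub("-", "_", key)
      if (!key_std %in% names(.GB_KEY_MAP)) {
        warning(sprintf("unknown feature key '%s' stored as notes", key))
        fclass <- "intergenic"
      } else fclass <- unname(.GB_KEY_MAP[[key_std]])
      span <- .gb_parse_location(locstr, nchar(seq), circular)
      nm <- quals[["gene"]]
      if (is.null(nm)) nm <- quals[["product"]]
      if (is.null(nm)) nm <- key
      if (fclass == "control") nm <- "control_region"
      notes <- quals[["note"]]
      if (is.null(notes)) notes <- ""
      if (!key_std %in% names(.GB_KEY_MAP))
        notes <- paste0("key=", key, if (nzchar(notes)) "; ", notes)
      feats <- rbind(feats, data.frame(
        name = nm, fclass = fclass,
        strand = if (span$complement) "heavy" else "light",
        start = span$start, end = span$end, notes = notes,
        stringsAsFactors = FALSE))
    }
  }
  g <- MitoGenome(id = id, seq = seq, circular = circular, features = feats)
  if (infer_control && !any(g@features$fclass == "control"))
    g <- .infer_control_region(g)
  g
}

.gb_parse_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  txt <- trimws(lines)
  # join continuation lines onto their qualifier
  out <- list(); cur <- NULL; val <- NULL
  for (ln in txt) {
    if (startsWith(ln, "/")) {
      if (!is.null(cur)) out[[cur]] <- val
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq > 0) {
        cur <- substr(ln, 2L, eq - 1L)
        val <- gsub("\"", "", substr(ln, eq + 1L, nchar(ln)))
      } else { cur <- substring(ln, 2L); val <- "" }
    } else if (!is.null(cur)) {
      val <- paste(val, gsub("\"", "", ln))
    }
  }
  if (!is.null(cur)) out[[cur]] <- val
  out
}

.gb_parse_location <- function(locstr, n, circular) {
  s <- gsub("[<>]", "", gsub("\\s", "", locstr))
  complement <- FALSE
  if (grepl("^complement\\(", s)) {
    complement <- TRUE
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^join\\(", s)) {
    body <- sub("^join\\((.*)\\)$", "\\1", s)
    parts <- strsplit(body, ",", fixed = TRUE)[[1]]
    rng <- lapply(parts, .gb_parse_range)
    if (length(rng) == 2L && rng[[1]]$end == n && rng[[2]]$start == 1L &&
        circular) {
      return(list(start = rng[[1]]$start, end = rng[[2]]$end,
                  complement = complement))
    }
    .stop_parse("unsupported join() location: %s", locstr)
  }
  r <- .gb_parse_range(s)
  list(start = r$start, end = r$end, complement = complement)
}

.gb_parse_range <- function(s) {
  if (grepl("^\\d+$", s)) {
    p <- as.integer(s); return(list(start = p, end = p))
  }
  m <- regmatches(s, regexec("^(\\d+)\\.\\.(\\d+)$", s))[[1]]
  if (length(m) != 3L) .stop_parse("cannot parse location range '%s'", s)
  list(start = as.integer(m[2]), end = as.integer(m[3]))
}

.infer_control_region <- function(g, min_len = 200L) {
  gaps <- .unannotated_gaps(g)
  if (!nrow(gaps)) return(g)
  lens <- mapply(.span_len, gaps$start, gaps$end,
                 MoreArgs = list(n = nchar(g@seq)))
  i <- which.max(lens)
  if (lens[i] < min_len) return(g)
  ft <- rbind(g@features, data.frame(
    name = "control_region", fclass = "control", strand = "light",
    start = gaps$start[i], end = gaps$end[i],
    notes = "inferred from longest unannotated gap",
    stringsAsFactors = FALSE))
  MitoGenome(g@id, g@seq, g@circular, ft)
}

# unannotated gaps on the circle (start/end 1-based, may wrap)
.unannotated_gaps <- function(g) {
  n <- nchar(g@seq)
  cov <- logical(n)
  ft <- g@features
  for (i in seq_len(nrow(ft))) {
    if (ft$end[i] >= ft$start[i]) cov[ft$start[i]:ft$end[i]] <- TRUE
    else cov[c(ft$start[i]:n, 1L:ft$end[i])] <- TRUE
  }
  if (all(cov) || !any(cov))
    return(data.frame(start = integer(), end = integer()))
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gap <- !r$values
  gaps <- data.frame(start = starts[gap], end = ends[gap])
  # merge a wrap-around gap (last run and first run both uncovered)
  if (g@circular && nrow(gaps) >= 2L && gaps$start[1] == 1L &&
      gaps$end[nrow(gaps)] == n) {
    gaps$end[nrow(gaps)] <- gaps$end[1]
    gaps <- gaps[-1L, , drop = FALSE]
  }
  gaps
}

#' Write a MitoGenome as a GenBank flat file
#'
#' Emits the LOCUS/FEATURES/ORIGIN dialect that [readGenBank()] parses;
#' reading the file back reproduces the genome (sequence and canonical
#' feature table) exactly.
#'
#' @param g a \linkS4class{MitoGenome}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenBank <- function(g, path) {
  n <- nchar(g@seq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s     INV",
                     g@id, n, if (g@circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion.", g@id), con)
  writeLines(sprintf("VERSION     %s", g@id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  inv <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
           control = "D_loop", intergenic = "misc_feature")
  ft <- g@features
  for (i in seq_len(nrow(ft))) {
    key <- inv[[ft$fclass[i]]]
    locstr <- if (ft$end[i] >= ft$start[i])
      sprintf("%d..%d", ft$start[i], ft$end[i])
    else
      sprintf("join(%d..%d,1..%d)", ft$start[i], n, ft$end[i])
    if (ft$strand[i] == "heavy")
      locstr <- sprintf("complement(%s)", locstr)
    writeLines(sprintf("     %-15s %s", key, locstr), con)
    writeLines(sprintf("                     /gene=\"%s\"", ft$name[i]), con)
    if (nzchar(ft$notes[i]))
      writeLines(sprintf("                     /note=\"%s\"", ft$notes[i]),
                 con)
  }
  writeLines("ORIGIN", con)
  sq <- tolower(g@seq)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(sq, off, min(off + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read / write plain FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O returning/accepting
#' \linkS4class{MitoGenome} objects (no feature table).
#'
#' @param path FASTA file path.
#' @param circular topology flag to set on the genomes read.
#' @return \code{readFastaGenomes}: list of \linkS4class{MitoGenome}.
#' @export
readFastaGenomes <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(ss), function(i)
    MitoGenome(id = sub("\\s.*$", "", names(ss)[i]),
               seq = as.character(ss[[i]]), circular = circular))
}

#' @rdname readFastaGenomes
#' @param genomes list of \linkS4class{MitoGenome} (or a single genome).
#' @export
writeFastaGenomes <- function(genomes, path) {
  if (is(genomes, "MitoGenome")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, genomeSeq, ""))
  names(ss) <- vapply(genomes, genomeId, "")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
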