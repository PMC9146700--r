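# End-to-end orchestration: rotate -> align -> transfer annotation ->
# call/classify events -> distances/ABGD -> reports.

#' Run the full trio comparison pipeline
#'
#' Given an annotated reference genome and two unannotated genomes (the
#' target assembly and its conspecific), the pipeline (1) linearises the
#' reference so the first gene downstream of the control region starts at
#' position 1, (2) rotates the other genomes to that anchor, (3) transfers
#' the reference annotation onto the target through a banded alignment
#' (projection, rescue of dropped short features, overlap curation),
#' (4) builds a target-anchored MSA of the three genomes, (5) calls and
#' classifies variable events and predicts coding effects, and (6)
#' computes pairwise distances.
#'
#' @param target unannotated target \linkS4class{MitoGenome}.
#' @param sib unannotated conspecific \linkS4class{MitoGenome}.
#' @param ref annotated reference \linkS4class{MitoGenome}.
#' @param align_params an [alignParams()] list.
#' @param dist_params a [distanceParams()] list.
#' @param count_mode tally counting mode, see [tallyEvents()].
#' @param table a [codonTable()].
#' @return list with \code{target_annotated}, \code{msa}, \code{events},
#'   \code{tallies}, \code{distances}, \code{transfer_report},
#'   \code{curation}, \code{rotations} (offsets applied to each input),
#'   \code{gene_order_vs_ancestral}.
#' @export
runTrioPipeline <- function(target, sib, ref,
                            align_params = alignParams(),
                            dist_params = distanceParams(),
                            count_mode = "event",
                            table = codonTable()) {
  # 1. linearise the reference: first gene after the control region -> 1
  ft <- ref@features
  ctrl <- which(ft$fclass == "control")
  if (length(ctrl)) {
    n <- nchar(ref@seq)
    after <- (ft$start - ft$end[ctrl[1]]) %% n
    after[ctrl] <- NA
    first_gene <- which.min(after)
    ref <- rotateGenome(ref, ft$start[first_gene] - 1L)
  }
  # 2. anchor-rotate the unannotated genomes
  rt <- rotateToAnchor(target, ref)
  rs <- rotateToAnchor(sib, ref)
  target <- rt$genome; sib <- rs$genome

  # 3. annotation transfer ref -> target
  aln_rt <- globalAlign(ref, target, align_params,
                        ids = c(ref@id, target@id))
  proj <- projectFeatures(ref, target, aln_rt)
  resc <- rescueUnmapped(proj$genome, ref, proj$report, aln_rt)
  cur <- curateOverlaps(resc$genome, table)
  target_ann <- cur$genome

  # 4. target-anchored MSA
  aln_ts <- globalAlign(target_ann, sib, align_params,
                        ids = c(target_ann@id, sib@id))
  aln_tr <- globalAlign(target_ann, ref, align_params,
                        ids = c(target_ann@id, ref@id))
  msa <- anchorMerge(list(aln_ts, aln_tr))

  # 5. events + tallies
  events <- callEvents(msa, target_ann, table)
  tallies <- tallyEvents(events, count_mode = count_mode)

  # 6. distances
  D <- distanceMatrix(msa, dist_params)

  god <- tryCatch(
    geneOrderDiff(geneOrder(target_ann), ancestralInsectOrder()),
    error = function(e) NULL)

  list(target_annotated = target_ann, msa = msa, events = events,
       tallies = tallies, distances = D,
       transfer_report = resc$report, curation = cur$actions,
       rotations = c(setNames(rt$offset, target@id),
                     setNames(rs$offset, sib@id)),
       gene_order_vs_ancestral = god)
}

#' Run the comparison and write report files
#'
#' Writes the events table, per-pair tallies, the missense roster, the
#' composition table, the distance matrix and a minimal VCF into
#' \code{out_dir}, each as TSV with a commented provenance header echoing
#' every tunable in effect (a run is reconstructible from its reports).
#'
#' @inheritParams runTrioPipeline
#' @param out_dir output directory (created if needed).
#' @return the [runTrioPipeline()] result, invisibly, with
#'   \code{files} (named vector of the paths written) appended.
#' @export
runCompare <- function(target, sib, ref, out_dir,
                       align_params = alignParams(),
                       dist_params = distanceParams(),
                       count_mode = "event",
                       table = codonTable()) {
  res <- runTrioPipeline(target, sib, ref, align_params, dist_params,
                         count_mode, table)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(
    sprintf("# mitotrio %s", as.character(utils::packageVersion("mitotrio"))),
    sprintf("# target=%s sib=%s ref=%s", res$target_annotated@id,
            setdiff(rownames(res$distances), res$target_annotated@id)[1],
            setdiff(rownames(res$distances), res$target_annotated@id)[2]),
    sprintf("# align: match=%g mismatch=%g gap_open=%g gap_ext=%g band=%d",
            align_params$match, align_params$mismatch,
            align_params$gap_open, align_params$gap_ext,
            align_params$band),
    sprintf("# dist: model=%s gamma_shape=%g deletion=%s",
            dist_params$model, dist_params$gamma_shape,
            dist_params$deletion),
    sprintf("# count_mode=%s", count_mode))
  wtsv <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(prov, con)
    close(con)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }
  files <- c(
    events = wtsv(res$events, "events.tsv"),
    tallies = wtsv(res$tallies$pair_by_region, "tallies.tsv"),
    missense = wtsv(res$tallies$missense, "missense.tsv"),
    transfer = wtsv(res$transfer_report, "transfer_report.tsv"))
  cmp <- composition(res$target_annotated)
  comp_df <- data.frame(base = names(cmp$counts),
                        count = as.integer(cmp$counts))
  comp_df <- rbind(comp_df,
                   data.frame(base = c("GC_fraction", "AT_fraction"),
                              count = c(round(cmp$gc, 4),
                                        round(cmp$at, 4))))
  files["composition"] <- wtsv(comp_df, "composition.tsv")
  files["distances"] <- writeDistanceMatrix(res$distances,
                                            file.path(out_dir,
                                                      "distances.tsv"))
  files["vcf"] <- writeEventsVCF(res$events, res$target_annotated,
                                 file.path(out_dir, "events.vcf"))
  res$files <- files
  invisible(res)
}

#' Fetch a GenBank flat file from NCBI efetch
#'
#' Convenience helper for reproducing the published comparisons on the
#' deposited accessions; the package itself never requires network access.
#'
#' @param accession GenBank accession.
#' @param dest destination path (default a tempfile).
#' @param timeout seconds before giving up.
#' @return the path to the downloaded flat file.
#' @export
fetchGenBank <- function(accession, dest = tempfile(fileext = ".gb"),
                         timeout = 30) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", accession, "&rettype=gb&retmode=text")
  old <- options(timeout = timeout); on.exit(options(old))
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  dest
}
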