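# End-to-end curation: ingest -> filter/merge -> anchor -> resolve ->
# classify -> emit, with per-stage counts and optional on-disk artifacts.

#' Bundle run parameters
#'
#' @param aparams [alignerParams()].
#' @param uparams [uasParams()].
#' @param min_svlen Strict locus length floor (default 50).
#' @param merge_gap Region merge gap (default 500).
#' @param unmerge_len Container unmerge threshold (default 20000).
#' @param sub_max_identity SUB decomposition threshold (default 0.8).
#' @param size_floor Strict SV size floor (default 50).
#' @param diagnose Also run scenario diagnosis per region (slower).
#' @return Named list, serialized verbatim into the run manifest.
#' @export
runConfig <- function(aparams = alignerParams(), uparams = uasParams(),
                      min_svlen = 50L, merge_gap = 500L,
                      unmerge_len = 20000L, sub_max_identity = 0.8,
                      size_floor = 50L, diagnose = FALSE) {
  list(aparams = aparams, uparams = uparams,
       min_svlen = as.integer(min_svlen),
       merge_gap = as.integer(merge_gap),
       unmerge_len = as.integer(unmerge_len),
       sub_max_identity = sub_max_identity,
       size_floor = as.integer(size_floor), diagnose = diagnose)
}

#' Run the full curation pipeline
#'
#' Pools the caller loci, filters them, merges them into SV regions,
#' anchors every region with UAS flanks, resolves base-pair breakpoints,
#' classifies the events and emits benchmark records, reporting counts at
#' every stage.
#'
#' @param ref,qry [Genome-class] objects.
#' @param calls Named list of loci `GRanges` (from [readCallerVcf()] or
#'   [simulateCalls()]).
#' @param config [runConfig()].
#' @param out_dir Optional output directory: writes `benchmark.vcf`,
#'   `regions.bed`, `report.tsv`, `manifest.json`.
#' @return A list: `benchmark` (resolved-SV `GRanges`), `regions`
#'   (`GRanges` with per-region `status`), `report` (named counts),
#'   `type_counts`, `pattern_counts`.
#' @export
curate <- function(ref, qry, calls, config = runConfig(), out_dir = NULL) {
  stopifnot(is(ref, "Genome"), is(qry, "Genome"), length(calls) >= 1L)
  loci <- do.call(c, unname(calls))
  filt <- filterLoci(loci, min_svlen = config$min_svlen)
  regions <- mergeLoci(filt, merge_gap = config$merge_gap,
                       unmerge_len = config$unmerge_len)
  qidx <- genomeIndex(qry, config$aparams$k)

  status <- character(length(regions))
  scenario <- rep(NA_character_, length(regions))
  resolved <- list()
  for (i in seq_along(regions)) {
    region <- regions[i]
    anchor <- findUAS(region, ref, qry, params = config$uparams,
                      aparams = config$aparams, qidx = qidx)
    status[i] <- anchor$status
    if (anchor$status != "anchored") next
    uas_up <- sprintf("%d-%d|%d-%d", anchor$up$ref_start,
                      anchor$up$ref_end, anchor$up$mate_start,
                      anchor$up$mate_end)
    uas_down <- sprintf("%d-%d|%d-%d", anchor$down$ref_start,
                        anchor$down$ref_end, anchor$down$mate_start,
                        anchor$down$mate_end)
    svs <- resolveRegion(anchor$ref_window, anchor$qry_window, ref, qry,
                         params = config$aparams,
                         sub_max_identity = config$sub_max_identity,
                         size_floor = config$size_floor,
                         uas_up = uas_up, uas_down = uas_down)
    if (isTRUE(config$diagnose)) {
      scenario[i] <- as.character(diagnoseScenario(
        region, ref, qry, qry_interval = anchor$qry_interval,
        params = config$aparams))
    }
    if (length(svs)) resolved[[length(resolved) + 1L]] <- svs
  }
  mcols(regions)$status <- status
  mcols(regions)$scenario <- scenario

  benchmark <- if (length(resolved)) {
    do.call(c, resolved)
  } else resolvedSV()
  if (length(benchmark)) {
    # containers can overlap ordinary regions: drop exact duplicates
    key <- paste(seqnames(benchmark), start(benchmark), end(benchmark),
                 mcols(benchmark)$svtype, mcols(benchmark)$qry_start)
    benchmark <- benchmark[!duplicated(key)]
    benchmark <- benchmark[order(as.character(seqnames(benchmark)),
                                 start(benchmark))]
    mcols(benchmark)$id <- sprintf("sv_%03d", seq_along(benchmark))
  }
  report <- c(loci_in = length(loci), loci_filtered = length(filt),
              regions = length(regions),
              anchored = sum(status == "anchored"),
              resolved = length(benchmark))
  tc <- svTypeCounts(benchmark)
  pc <- table(factor(mcols(benchmark)$pattern,
                     levels = c("unique", "cat1", "cat2", "cat3")))
  out <- list(benchmark = benchmark, regions = regions, report = report,
              type_counts = tc, pattern_counts = c(pc))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeBenchmarkVcf(benchmark, ref, file.path(out_dir, "benchmark.vcf"))
    writeRegionsBed(regions, file.path(out_dir, "regions.bed"))
    rep_df <- data.frame(metric = c(names(report), names(tc), names(pc)),
                         value = c(report, tc, c(pc)))
    write.table(rep_df, file.path(out_dir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_json(list(config = config[c("min_svlen", "merge_gap",
                                      "unmerge_len", "sub_max_identity",
                                      "size_floor")],
                    aparams = config$aparams, uparams = config$uparams,
                    report = as.list(report)),
               file.path(out_dir, "manifest.json"), auto_unbox = TRUE,
               pretty = TRUE)
  }
  out
}

#' Write SV regions as BED
#'
#' 1-based inclusive internal intervals become 0-based half-open BED lines;
#' region id, locus count and status/scenario go in columns 4-6.
#'
#' @param regions `GRanges` from [mergeLoci()] (optionally annotated by
#'   [curate()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
  mc <- mcols(regions)
  lines <- vapply(seq_along(regions), function(i) {
    paste(as.character(seqnames(regions)[i]), start(regions)[i] - 1L,
          end(regions)[i], mc$region_id[i], mc$n_loci[i],
          (if (!is.null(mc$status)) mc$status[i] else ".") %||% ".",
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
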