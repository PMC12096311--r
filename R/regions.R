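# Region building: filter raw caller loci, consolidate them into SV regions
# (single-linkage, 500-bp gap tolerance, with >20-kb container unmerging),
# and diagnose each region's boundary scenario.

#' Filter raw caller loci
#'
#' A locus is kept iff its FILTER flags intersect {PASS, PRECISE} (when the
#' caller emits flags at all; callers with no FILTER discipline bypass the
#' flag rule) and its length strictly exceeds `min_svlen`.
#'
#' @param loci `GRanges` from [readCallerVcf()] / [svLoci()].
#' @param min_svlen Strict length floor in bp (default 50: a 50-bp locus is
#'   dropped, a 51-bp locus kept).
#' @param accept_flags Flags counting as a pass (default PASS, PRECISE).
#' @return Filtered `GRanges`; `metadata()$drop_counts` holds per-caller
#'   drop counts.
#' @export
filterLoci <- function(loci, min_svlen = 50L,
                       accept_flags = c("PASS", "PRECISE")) {
  if (length(loci) == 0L) return(loci)
  mc <- mcols(loci)
  flags <- strsplit(ifelse(is.na(mc$filter), "", mc$filter), ";",
                    fixed = TRUE)
  no_discipline <- vapply(flags, function(f) {
    length(f) == 0L || all(f %in% c("", "."))
  }, logical(1))
  flag_ok <- no_discipline |
    vapply(flags, function(f) any(f %in% accept_flags), logical(1))
  len_ok <- mc$svlen > min_svlen
  keep <- flag_ok & len_ok
  dropped <- tapply(!keep, mc$caller, sum)
  out <- loci[keep]
  metadata(out) <- c(metadata(loci),
                     list(drop_counts = dropped[!is.na(dropped)]))
  out
}

#' Merge loci into SV regions
#'
#' Single-linkage clustering with a 500-bp inter-locus gap tolerance.  Loci
#' longer than `unmerge_len` are excluded from clustering and emitted as
#' their own container regions (they may span several smaller loci, which
#' still cluster among themselves).
#'
#' @param loci Filtered `GRanges` (any order; merging is order-invariant).
#' @param merge_gap Maximum gap between loci in one region (default 500).
#' @param unmerge_len Container threshold in bp (default 20000; strict).
#' @return `GRanges` of regions with mcols `region_id`, `n_loci`,
#'   `is_container`, and a `member_ids` CharacterList-like comma string.
#' @export
mergeLoci <- function(loci, merge_gap = 500L, unmerge_len = 20000L) {
  if (length(loci) == 0L) {
    out <- GRanges()
    mcols(out)$region_id <- character()
    return(out)
  }
  o <- order(as.character(seqnames(loci)), start(loci), end(loci))
  loci <- loci[o]
  mc <- mcols(loci)
  big <- mc$svlen > unmerge_len
  rows <- list()
  small <- loci[!big]
  if (length(small)) {
    # single linkage: a zero/width-aware gap rule on sorted loci
    ch <- as.character(seqnames(small))
    s <- start(small); e <- pmax(end(small), s - 1L)  # width-0 INS anchors
    grp <- integer(length(small)); grp[1] <- 1L
    if (length(small) > 1L) {
      cur_end <- e[1]
      for (i in 2:length(small)) {
        new_grp <- ch[i] != ch[i - 1L] || (s[i] - cur_end - 1L) > merge_gap
        grp[i] <- grp[i - 1L] + as.integer(new_grp)
        cur_end <- if (new_grp) e[i] else max(cur_end, e[i])
      }
    }
    for (g in unique(grp)) {
      idx <- which(grp == g)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch[idx[1]], start = min(s[idx]), end = max(e[idx]),
        n_loci = length(idx), is_container = FALSE,
        member_ids = paste(mcols(small)$id[idx], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (any(big)) {
    bigl <- loci[big]
    for (i in seq_along(bigl)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(seqnames(bigl))[i], start = start(bigl)[i],
        end = end(bigl)[i], n_loci = 1L, is_container = TRUE,
        member_ids = mcols(bigl)$id[i], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- GRanges(df$chrom, IRanges(df$start, df$end))
  mcols(out)$region_id <- sprintf("region_%03d", seq_len(nrow(df)))
  mcols(out)$n_loci <- df$n_loci
  mcols(out)$is_container <- df$is_container
  mcols(out)$member_ids <- df$member_ids
  out
}

#' Diagnose the boundary scenario of an SV region
#'
#' Labels a region with the alignment pathology that makes its boundaries
#' unreliable:
#' * `copy_number_discrepancy` - two or more copies in one genome best-align
#'   to the same copy in the other;
#' * `reverse_artifact` - the region hits many dispersed reverse-orientation
#'   locations although its best alignment is forward;
#' * `copy_misalignment` - the similarity-optimal copy pairing disagrees
#'   with the naive positional (left-to-right) pairing;
#' * `combined` - two or more of the above fire; `simple` - none;
#' * `unlocatable` - no query anchor at all.
#'
#' @param region One region (`GRanges` row) from [mergeLoci()].
#' @param ref,qry [Genome-class] objects.
#' @param qry_interval Optional located query interval
#'   `list(chrom, start, end)` (e.g. from [findUAS()]); when absent the
#'   region sequence is located by alignment.
#' @param catalog Optional [decomposeSegments()] result for the region pair;
#'   computed when absent.
#' @param params [alignerParams()].
#' @param hit_multiplicity Dispersed reverse-hit count that triggers
#'   `reverse_artifact` (default 5).
#' @param flank Flank padding in bp added around the region when locating
#'   and cataloguing (default 2000).
#' @return Character scenario label with attribute `criteria` (logical
#'   vector of the three tests).
#' @export
diagnoseScenario <- function(region, ref, qry, qry_interval = NULL,
                             catalog = NULL, params = alignerParams(),
                             hit_multiplicity = 5L, flank = 2000L) {
  chrom <- as.character(seqnames(region))[1]
  rs <- max(1L, start(region)[1] - flank)
  re <- min(seqLengths(ref)[[chrom]], end(region)[1] + flank)
  rseq <- genomeSeq(ref, chrom, rs, re)

  # locate in query: best forward hit of the flank-extended region
  hits <- NULL
  for (qchrom in names(seqs(qry))) {
    h <- alignPair(rseq, genomeSeq(qry, qchrom), params,
                   qname = chrom, tname = qchrom)
    hits <- rbind(hits, h)
  }
  if (is.null(hits) || nrow(hits) == 0L) {
    out <- "unlocatable"
    attr(out, "criteria") <- c(copy_number = FALSE, reverse = FALSE,
                               misalignment = FALSE)
    return(out)
  }
  fwd <- hits[hits$strand == "+", , drop = FALSE]
  rev <- hits[hits$strand == "-", , drop = FALSE]
  if (nrow(fwd) == 0L) {
    out <- "unlocatable"
    attr(out, "criteria") <- c(copy_number = FALSE, reverse = FALSE,
                               misalignment = FALSE)
    return(out)
  }
  best <- fwd[which.max(fwd$matches), ]
  if (is.null(qry_interval)) {
    qry_interval <- list(chrom = best$tname, start = best$tstart,
                         end = best$tend)
  }
  qseq <- genomeSeq(qry, qry_interval$chrom, qry_interval$start,
                    qry_interval$end)
  if (is.null(catalog)) catalog <- decomposeSegments(rseq, qseq, params)

  # criterion 2: many dispersed reverse hits, best hit forward
  n_rev_loci <- 0L
  if (nrow(rev)) {
    o <- order(rev$tname, rev$tstart)
    rev <- rev[o, , drop = FALSE]
    gapped <- c(TRUE, rev$tname[-1] != rev$tname[-nrow(rev)] |
                  rev$tstart[-1] - rev$tend[-nrow(rev)] > 100L)
    n_rev_loci <- sum(gapped)
  }
  crit_rev <- n_rev_loci >= hit_multiplicity &&
    best$identity >= max(rev$identity, 0)

  # criteria 1 and 3 need the copy catalog
  crit_cn <- FALSE
  crit_mis <- FALSE
  cp <- copies(catalog)
  sm <- copySimilarityMatrix(catalog)
  for (f in unique(cp$family)) {
    ir <- which(cp$family == f & cp$genome == "ref")
    iq <- which(cp$family == f & cp$genome == "qry")
    if (length(ir) == 0L || length(iq) == 0L) next
    # best-hit mapping in both directions
    best_ref_of_qry <- vapply(iq, function(j) ir[which.max(sm[ir, j])],
                              integer(1))
    best_qry_of_ref <- vapply(ir, function(j) iq[which.max(sm[iq, j])],
                              integer(1))
    # a collapse of best hits only signals a *discrepancy* when the copy
    # counts agree (a real count difference is an actual CN change)
    if (length(ir) == length(iq) && length(iq) >= 2L &&
        (anyDuplicated(best_ref_of_qry) || anyDuplicated(best_qry_of_ref))) {
      crit_cn <- TRUE
    }
    # positional vs similarity-optimal pairing
    pair <- matchCopies(catalog, family = f)
    if (nrow(pair)) {
      np <- min(length(ir), length(iq))
      ir_ord <- ir[order(cp$start[ir])]
      iq_ord <- iq[order(cp$start[iq])]
      positional <- data.frame(ref = ir_ord[seq_len(np)],
                               qry = iq_ord[seq_len(np)])
      key_opt <- paste(pair$ref, pair$qry)
      key_pos <- paste(positional$ref, positional$qry)
      if (!setequal(key_opt, key_pos)) crit_mis <- TRUE
    }
  }
  crit <- c(copy_number = crit_cn, reverse = crit_rev,
            misalignment = crit_mis)
  out <- if (sum(crit) >= 2L) "combined"
    else if (crit_cn) "copy_number_discrepancy"
    else if (crit_rev) "reverse_artifact"
    else if (crit_mis) "copy_misalignment"
    else "simple"
  attr(out, "criteria") <- crit
  out
}
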