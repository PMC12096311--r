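# SV typing: INS, DEL, INV, SUB from the unpaired residual material of a
# resolved junction.  DUP/CNV labels are never emitted: copy-number change
# is reported as INS/DEL of the identified copies.  The three inversion
# criteria: forward-aligned flanks, reciprocal best reverse match, and no
# assembly gap inside the interval in either genome.

#' Classify residual material into an SV type
#'
#' INS when only query residual remains, DEL when only reference residual,
#' SUB when both remain and stay unaligned (forward identity below
#' `sub_max_identity`); `"decompose"` signals residual pairs that still
#' align and should be decomposed further rather than typed; `"none"` when
#' both residuals are empty.  Inversion candidates (`inv_ok = TRUE`,
#' established by [checkInversion()]) take precedence over SUB when the
#' side lengths are equal.
#'
#' @param ref_res,qry_res Residual sequences (possibly "").
#' @param fwd_identity,rev_identity End-to-end identities of the residual
#'   pair in the two orientations.
#' @param inv_ok Did the candidate pass [checkInversion()]?
#' @param sub_max_identity SUB threshold (default 0.8).
#' @return One of "INS", "DEL", "INV", "SUB", "decompose", "none".
#' @export
classifySV <- function(ref_res, qry_res, fwd_identity = 0,
                       rev_identity = 0, inv_ok = FALSE,
                       sub_max_identity = 0.8) {
  rl <- nchar(ref_res); ql <- nchar(qry_res)
  if (rl == 0L && ql == 0L) return("none")
  if (rl == 0L) return("INS")
  if (ql == 0L) return("DEL")
  if (inv_ok && rl == ql) return("INV")
  if (fwd_identity >= sub_max_identity) return("decompose")
  "SUB"
}

#' Test the three inversion criteria
#'
#' A candidate interval pair is an inversion iff (1) its flanking sequences
#' are forward-aligned between the genomes (`flanks_forward`, established
#' by the UAS anchoring / chain skeleton), (2) the reverse alignment is the
#' reciprocal best match - better than the direct forward identity of the
#' pair and better than any forward alternative of either side within the
#' region windows - and (3) no assembly-gap run intersects the interval in
#' either genome.
#'
#' @param ref_interval `list(chrom, start, end)` on the reference.
#' @param qry_interval `list(chrom, start, end)` on the query.
#' @param ref,qry [Genome-class] objects.
#' @param ref_window,qry_window Optional region windows
#'   (`list(chrom, start, end)`) to scan for forward alternatives; default
#'   is the interval padded by 2 kb.
#' @param flanks_forward Criterion 1 (default TRUE when called from the
#'   anchored pipeline).
#' @param min_identity Reverse identity floor (default 0.8).
#' @param params [alignerParams()].
#' @return Logical with attribute `detail` (the identities involved).
#' @export
checkInversion <- function(ref_interval, qry_interval, ref, qry,
                           ref_window = NULL, qry_window = NULL,
                           flanks_forward = TRUE, min_identity = 0.8,
                           params = alignerParams()) {
  pad <- 2000L
  if (is.null(ref_window)) {
    ref_window <- list(chrom = ref_interval$chrom,
                       start = ref_interval$start - pad,
                       end = ref_interval$end + pad)
  }
  if (is.null(qry_window)) {
    qry_window <- list(chrom = qry_interval$chrom,
                       start = qry_interval$start - pad,
                       end = qry_interval$end + pad)
  }
  rseq <- genomeSeq(ref, ref_interval$chrom, ref_interval$start,
                    ref_interval$end)
  qseq <- genomeSeq(qry, qry_interval$chrom, qry_interval$start,
                    qry_interval$end)
  rev_id <- as.numeric(copySimilarity(rseq, qseq, "reverse", params))
  fwd_id <- as.numeric(copySimilarity(rseq, qseq, "forward", params))
  # forward alternatives of either side within the windows
  rwin <- genomeSeq(ref, ref_window$chrom, ref_window$start, ref_window$end)
  qwin <- genomeSeq(qry, qry_window$chrom, qry_window$start, qry_window$end)
  alt_f <- 0
  segs1 <- alignPair(rseq, qwin, params, both_strands = FALSE)
  if (nrow(segs1)) alt_f <- max(alt_f, segs1$identity)
  segs2 <- alignPair(qseq, rwin, params, both_strands = FALSE)
  if (nrow(segs2)) alt_f <- max(alt_f, segs2$identity)
  gap <- hasGap(ref, ref_interval$chrom, ref_interval$start,
                ref_interval$end) ||
    hasGap(qry, qry_interval$chrom, qry_interval$start, qry_interval$end)
  ok <- flanks_forward && rev_id >= min_identity &&
    rev_id > fwd_id && rev_id > alt_f && !gap
  attr(ok, "detail") <- c(rev = rev_id, fwd = fwd_id,
                          fwd_alternative = alt_f, gap = as.numeric(gap))
  ok
}

#' Resolve one anchored region pair into classified SVs
#'
#' Runs [placeBreakpoints()] over the anchored windows, classifies every
#' junction call ([classifySV()] with [checkInversion()] for both-sided
#' residuals), applies the strict >`size_floor` SV size rule to
#' `max(ref_len, qry_len)`, and lifts region-local coordinates to genome
#' coordinates.
#'
#' @param ref_window,qry_window `list(chrom, start, end)` anchored windows
#'   (including the UAS flanks) as returned by [findUAS()].
#' @param ref,qry [Genome-class] objects.
#' @param params [alignerParams()].
#' @param sub_max_identity SUB threshold (default 0.8).
#' @param size_floor Strict SV size floor in bp (default 50).
#' @param uas_up,uas_down Optional UAS descriptor strings stamped on the
#'   output records.
#' @return Resolved-SV `GRanges` (possibly empty).
#' @export
resolveRegion <- function(ref_window, qry_window, ref, qry,
                          params = alignerParams(),
                          sub_max_identity = 0.8, size_floor = 50L,
                          uas_up = NA_character_,
                          uas_down = NA_character_) {
  R <- genomeSeq(ref, ref_window$chrom, ref_window$start, ref_window$end)
  Q <- genomeSeq(qry, qry_window$chrom, qry_window$start, qry_window$end)
  calls <- placeBreakpoints(R, Q, params = params,
                            sub_max_identity = sub_max_identity)
  if (nrow(calls) == 0L) return(resolvedSV())
  roff <- ref_window$start - 1L
  qoff <- qry_window$start - 1L
  edge <- 20L       # calls at a window edge are truncated artifacts
  keep <- list()
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    rl <- nchar(cl$ref_res); ql <- nchar(cl$qry_res)
    if (max(rl, ql) <= size_floor) next
    if (min(cl$ref_start, cl$qry_start) <= edge ||
        cl$ref_end >= nchar(R) - edge + 1L ||
        cl$qry_end >= nchar(Q) - edge + 1L) next
    inv_ok <- FALSE
    if (rl > 0L && ql > 0L && cl$rev_identity > cl$fwd_identity &&
        rl == ql) {
      inv_ok <- isTRUE(as.logical(checkInversion(
        list(chrom = ref_window$chrom, start = cl$ref_start + roff,
             end = cl$ref_end + roff),
        list(chrom = qry_window$chrom, start = cl$qry_start + qoff,
             end = cl$qry_end + qoff),
        ref, qry,
        ref_window = ref_window, qry_window = qry_window,
        min_identity = sub_max_identity, params = params)))
    }
    ty <- classifySV(cl$ref_res, cl$qry_res, cl$fwd_identity,
                     cl$rev_identity, inv_ok, sub_max_identity)
    if (ty %in% c("none", "decompose")) {
      # residuals still align but produced no sub-calls above the floor
      next
    }
    alt <- switch(ty, INS = cl$qry_res, SUB = cl$qry_res,
                  INV = cl$qry_res, DEL = NA_character_)
    keep[[length(keep) + 1L]] <- data.frame(
      chrom = ref_window$chrom,
      ref_start = cl$ref_start + roff, ref_end = cl$ref_end + roff,
      qry_chrom = qry_window$chrom,
      qry_start = cl$qry_start + qoff, qry_end = cl$qry_end + qoff,
      svtype = ty, pattern = cl$pattern, ambig_len = cl$ambig_len,
      alt_seq = alt, stringsAsFactors = FALSE)
  }
  if (!length(keep)) return(resolvedSV())
  df <- do.call(rbind, keep)
  resolvedSV(chrom = df$chrom, ref_start = df$ref_start,
             ref_end = df$ref_end, svtype = df$svtype,
             qry_chrom = df$qry_chrom, qry_start = df$qry_start,
             qry_end = df$qry_end, pattern = df$pattern,
             ambig_len = df$ambig_len, alt_seq = df$alt_seq,
             uas_up = uas_up, uas_down = uas_down)
}

#' Emit benchmark records with flanking UAS sequence
#'
#' Attaches `flank_len` bp of flanking sequence on each side in both
#' genomes to every record and tabulates per-type and per-pattern counts.
#' Optionally writes the benchmark VCF.
#'
#' @param svs Resolved-SV `GRanges`.
#' @param ref,qry [Genome-class] objects.
#' @param flank_len Flanking sequence length per side (default 500).
#' @param path Optional VCF output path (via [writeBenchmarkVcf()]).
#' @return A list: `records` (the GRanges with `uas_seq_up`/`uas_seq_down`
#'   mcols), `type_counts`, `pattern_counts`.
#' @export
emitBenchmark <- function(svs, ref, qry, flank_len = 500L, path = NULL) {
  if (length(svs)) {
    up <- character(length(svs)); down <- character(length(svs))
    for (i in seq_along(svs)) {
      chrom <- as.character(seqnames(svs)[i])
      s <- start(svs)[i]; e <- end(svs)[i]
      up[i] <- genomeSeq(ref, chrom, s - flank_len, s - 1L)
      down[i] <- genomeSeq(ref, chrom, e + 1L, e + flank_len)
    }
    mcols(svs)$uas_seq_up <- up
    mcols(svs)$uas_seq_down <- down
  }
  pat <- table(factor(mcols(svs)$pattern,
                      levels = c("unique", "cat1", "cat2", "cat3")))
  out <- list(records = svs, type_counts = svTypeCounts(svs),
              pattern_counts = c(pat))
  if (!is.null(path)) writeBenchmarkVcf(svs, ref, path)
  out
}
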