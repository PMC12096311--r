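# Resolved SVs are GRanges on the reference genome (1-based inclusive;
# insertions are zero-width ranges anchored after `start - 1`) with a fixed
# set of metadata columns.  `validateResolvedSV()` enforces the type
# invariants that define the four-type taxonomy.

#' Construct a resolved-SV GRanges
#'
#' @param chrom,ref_start,ref_end Reference interval (1-based inclusive; for
#'   INS use `ref_start = p + 1, ref_end = p`, the insertion point after
#'   base p).
#' @param svtype One of "INS", "DEL", "INV", "SUB".
#' @param qry_chrom,qry_start,qry_end Query-genome interval (zero-width for
#'   DEL).
#' @param pattern Breakpoint-pattern category: "unique", "cat1", "cat2" or
#'   "cat3".
#' @param ambig_len Length of the interval of equivalent breakpoint
#'   placements (1 when the placement is unique).
#' @param alt_seq Query-side sequence (INS/SUB; revcomp interval content for
#'   INV; `NA` for DEL).
#' @param uas_up,uas_down Flanking UAS descriptors "refStart-refEnd|qryStart-qryEnd"
#'   or `NA`.
#' @param id Record identifiers.
#' @return `GRanges` with the resolved-SV metadata columns.
#' @export
resolvedSV <- function(chrom = character(), ref_start = integer(),
                       ref_end = integer(), svtype = character(),
                       qry_chrom = NA_character_, qry_start = NA_integer_,
                       qry_end = NA_integer_, pattern = "unique",
                       ambig_len = 1L, alt_seq = NA_character_,
                       uas_up = NA_character_, uas_down = NA_character_,
                       id = NULL) {
  n <- length(ref_start)
  gr <- GRanges(rep_len(chrom, n), IRanges(start = ref_start, end = ref_end))
  mcols(gr)$svtype <- rep_len(svtype, n)
  mcols(gr)$ref_len <- as.integer(ref_end - ref_start + 1L)
  mcols(gr)$qry_chrom <- rep_len(qry_chrom, n)
  mcols(gr)$qry_start <- rep_len(as.integer(qry_start), n)
  mcols(gr)$qry_end <- rep_len(as.integer(qry_end), n)
  mcols(gr)$qry_len <- mcols(gr)$qry_end - mcols(gr)$qry_start + 1L
  mcols(gr)$pattern <- rep_len(pattern, n)
  mcols(gr)$ambig_len <- rep_len(as.integer(ambig_len), n)
  mcols(gr)$alt_seq <- rep_len(alt_seq, n)
  mcols(gr)$uas_up <- rep_len(uas_up, n)
  mcols(gr)$uas_down <- rep_len(uas_down, n)
  mcols(gr)$id <- if (is.null(id)) sprintf("sv%d", seq_len(n)) else
    rep_len(id, n)
  gr
}

#' Check resolved-SV type invariants
#'
#' INS: zero reference length and query length > `size_floor`; DEL: zero
#' query length and reference length > `size_floor`; SUB: both sides
#' non-empty and the longer side > `size_floor`; INV: equal side lengths.
#'
#' @param svs Resolved-SV `GRanges`.
#' @param size_floor Minimum SV size in bp (strict; default 50).
#' @return `TRUE`, or a character vector of violations.
#' @export
validateResolvedSV <- function(svs, size_floor = 50L) {
  mc <- mcols(svs)
  bad <- character()
  for (i in seq_along(svs)) {
    rl <- mc$ref_len[i]; ql <- mc$qry_len[i]; ty <- mc$svtype[i]
    ok <- switch(ty,
      INS = rl == 0L && ql > size_floor,
      DEL = ql == 0L && rl > size_floor,
      SUB = rl >= 1L && ql >= 1L && max(rl, ql) > size_floor,
      INV = rl == ql && rl > size_floor,
      FALSE)
    if (!ok) {
      bad <- c(bad, sprintf("%s: %s with ref_len=%d qry_len=%d",
                            mc$id[i], ty, rl, ql))
    }
  }
  if (length(bad)) bad else TRUE
}

#' Per-type summary counts
#'
#' @param svs Resolved-SV `GRanges`.
#' @return Named integer vector with INS, DEL, INV, SUB and total.
#' @export
svTypeCounts <- function(svs) {
  tys <- c("INS", "DEL", "INV", "SUB")
  cnt <- vapply(tys, function(t) sum(mcols(svs)$svtype == t), integer(1))
  c(cnt, total = sum(cnt))
}
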