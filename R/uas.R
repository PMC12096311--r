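# UAS anchoring: grow flanks around an SV region until each flank aligns to
# exactly one confident location in the other genome, then use the mate
# intervals to locate the region there.  Complex containers are split at
# long internal UAS stretches.

#' UAS parameter set
#'
#' Uniqueness of a flank is met when it has a single candidate hit, or when
#' its best hit reaches `min_identity` and beats the runner-up by
#' `min_margin` (defaults motivated by the contrast between a 0.99 true
#' orientation and a 0.90 alternative).
#'
#' @param step Flank growth increment in bp (default 5000).
#' @param max_extend Maximum flank length in bp (default 30000).
#' @param min_identity Identity the best hit must reach (default 0.95).
#' @param min_margin Best-minus-second identity margin (default 0.05).
#' @param candidate_floor Identity above which a hit locus counts as a
#'   candidate (default 0.80).
#' @param min_cov Minimum fraction of the flank a hit locus must cover to
#'   count as a candidate (default 0.5); partial hits of repeat copies
#'   elsewhere do not make a flank multi-mapping.
#' @param min_internal_uas Minimum length of an internal UAS used to split
#'   a complex container region (default 1000).
#' @return Named list.
#' @export
uasParams <- function(step = 5000L, max_extend = 30000L,
                      min_identity = 0.95, min_margin = 0.05,
                      candidate_floor = 0.80, min_cov = 0.5,
                      min_internal_uas = 1000L) {
  list(step = as.integer(step), max_extend = as.integer(max_extend),
       min_identity = min_identity, min_margin = min_margin,
       candidate_floor = candidate_floor, min_cov = min_cov,
       min_internal_uas = as.integer(min_internal_uas))
}

#' Precompute per-sequence k-mer indexes for a genome
#'
#' @param genome A [Genome-class].
#' @param k Seed length.
#' @return Named list per sequence: `list(fwd = , rc = )` [kmerIndex()]es.
#' @export
genomeIndex <- function(genome, k = 15L) {
  out <- list()
  for (nm in names(seqs(genome))) {
    s <- genomeSeq(genome, nm)
    out[[nm]] <- list(fwd = kmerIndex(s, k), rc = kmerIndex(revcomp(s), k))
  }
  out
}

#' Align a flank against every sequence of a genome
#' @noRd
.flank_hits <- function(flank, genome, aparams, gidx = NULL) {
  hits <- NULL
  for (nm in names(seqs(genome))) {
    idx <- gidx[[nm]]
    h <- alignPair(flank, genomeSeq(genome, nm), aparams,
                   qname = "flank", tname = nm,
                   b_index = idx$fwd, b_rc_index = idx$rc)
    hits <- rbind(hits, h)
  }
  if (is.null(hits)) emptySegments() else hits
}

#' Merge colinear alignment segments into hit loci
#'
#' A flank whose alignment crosses an SV in the other genome splits into
#' several colinear segments; for uniqueness they are one locus.  Segments
#' on the same target and strand are merged when consecutive in both
#' coordinates with gaps below `max_gap`.
#'
#' @param hits Alignment-segment `data.frame`.
#' @param flank_len Flank length (for coverage); inferred from the hits
#'   when NULL.
#' @param max_gap Maximum bridged gap in bp (default 4000).
#' @return `data.frame` of loci: `tname`, `tstart`, `tend`, `strand`,
#'   `identity` (match-weighted), `coverage`, `matches`.
#' @export
mergeHitLoci <- function(hits, flank_len = NULL, max_gap = 4000L) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(tname = character(), tstart = integer(),
                      tend = integer(), strand = character(),
                      identity = numeric(), coverage = numeric(),
                      matches = numeric()))
  }
  if (is.null(flank_len)) flank_len <- max(hits$qend)
  out <- NULL
  for (tn in unique(hits$tname)) {
    for (str in unique(hits$strand[hits$tname == tn])) {
      h <- hits[hits$tname == tn & hits$strand == str, , drop = FALSE]
      h <- h[order(h$tstart, h$qstart), , drop = FALSE]
      grp <- integer(nrow(h)); grp[1] <- 1L
      if (nrow(h) > 1L) {
        for (i in 2:nrow(h)) {
          joins <- h$tstart[i] - h$tend[i - 1L] <= max_gap &&
            h$tstart[i] - h$tend[i - 1L] > -50L &&
            h$qstart[i] - h$qend[i - 1L] <= max_gap &&
            h$qstart[i] - h$qend[i - 1L] > -50L
          grp[i] <- grp[i - 1L] + as.integer(!joins)
        }
      }
      for (g in unique(grp)) {
        hh <- h[grp == g, , drop = FALSE]
        qcov <- min(1, sum(hh$qend - hh$qstart + 1) / flank_len)
        out <- rbind(out, data.frame(
          tname = tn, tstart = min(hh$tstart), tend = max(hh$tend),
          strand = str,
          identity = sum(hh$matches) / sum(hh$blocklen),
          coverage = qcov, matches = sum(hh$matches),
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Is a flank uniquely aligned?
#'
#' Segments are merged into hit loci ([mergeHitLoci()]); candidates are
#' loci at identity >= `candidate_floor` covering >= `min_cov` of the
#' flank.  The flank is unique when there is a single candidate, or when
#' the best candidate reaches `min_identity` and beats the runner-up by
#' `min_margin`.
#'
#' @param hits Alignment-segment `data.frame` of the flank against the
#'   whole other genome.
#' @param params [uasParams()].
#' @param flank_len Flank length in bp (for coverage; inferred when NULL).
#' @return Logical with attributes `best` (the best locus row) and
#'   `multiplicity` (candidate count).
#' @export
isUnique <- function(hits, params = uasParams(), flank_len = NULL) {
  loci <- mergeHitLoci(hits, flank_len)
  if (nrow(loci) == 0L) return(FALSE)
  cand <- loci[loci$identity >= params$candidate_floor &
                 loci$coverage >= params$min_cov, , drop = FALSE]
  if (nrow(cand) == 0L) return(FALSE)
  o <- order(cand$identity, cand$matches, decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]
  ok <- if (nrow(cand) == 1L) TRUE else {
    margin <- cand$identity[1] - cand$identity[2]
    margin >= params$min_margin && cand$identity[1] >= params$min_identity
  }
  out <- ok
  attr(out, "best") <- cand[1, , drop = FALSE]
  attr(out, "multiplicity") <- nrow(cand)
  out
}

#' Anchor an SV region with uniquely aligned flanking sequence
#'
#' Each flank grows independently in `step` increments (upstream ends at
#' the region start, downstream begins at the region end) until it is
#' unique in the other genome per [isUnique()], up to `max_extend`.  The
#' located query interval is the span between the two mate intervals.
#'
#' @param region One region (`GRanges` row).
#' @param ref,qry [Genome-class] objects.
#' @param params [uasParams()].
#' @param aparams [alignerParams()].
#' @param qidx Optional [genomeIndex()] of `qry` (reused across regions).
#' @return A list: `status` ("anchored", "unanchorable", "reverse_only"),
#'   per-side extensions `ext_up`/`ext_down`, UAS descriptors `up`/`down`
#'   (ref interval, mate interval, identity, margin, multiplicity,
#'   truncated), the located `qry_interval`, and the resolution windows
#'   `ref_window`/`qry_window` (region plus anchored flanks in both
#'   genomes).
#' @export
findUAS <- function(region, ref, qry, params = uasParams(),
                    aparams = alignerParams(), qidx = NULL) {
  chrom <- as.character(seqnames(region))[1]
  rs <- start(region)[1]; re <- end(region)[1]
  L <- seqLengths(ref)[[chrom]]
  if (is.null(qidx)) qidx <- genomeIndex(qry, aparams$k)

  side <- function(which) {
    ext <- params$step
    repeat {
      if (which == "up") {
        fs <- max(1L, rs - ext); fe <- rs - 1L
        truncated <- fs == 1L && rs - ext < 1L
      } else {
        fs <- re + 1L; fe <- min(L, re + ext)
        truncated <- fe == L && re + ext > L
      }
      if (fe < fs) {
        return(list(ok = FALSE, truncated = TRUE, ext = ext))
      }
      flank <- genomeSeq(ref, chrom, fs, fe)
      hits <- .flank_hits(flank, qry, aparams, qidx)
      u <- isUnique(hits, params, flank_len = nchar(flank))
      if (isTRUE(as.logical(u))) {
        best <- attr(u, "best")
        return(list(ok = TRUE, ref_start = fs, ref_end = fe,
                    mate_chrom = best$tname, mate_start = best$tstart,
                    mate_end = best$tend, strand = best$strand,
                    identity = best$identity,
                    multiplicity = attr(u, "multiplicity"),
                    truncated = truncated, ext = ext))
      }
      if (ext >= params$max_extend || truncated) {
        return(list(ok = FALSE, truncated = truncated, ext = ext))
      }
      ext <- min(ext + params$step, params$max_extend)
    }
  }

  up <- side("up"); down <- side("down")
  if (!up$ok || !down$ok) {
    return(list(status = "unanchorable", up = up, down = down,
                ext_up = up$ext, ext_down = down$ext))
  }
  if (up$strand == "-" || down$strand == "-") {
    return(list(status = "reverse_only", up = up, down = down,
                ext_up = up$ext, ext_down = down$ext))
  }
  if (up$mate_chrom != down$mate_chrom ||
      down$mate_start <= up$mate_start) {
    return(list(status = "unanchorable", up = up, down = down,
                ext_up = up$ext, ext_down = down$ext))
  }
  qs <- up$mate_end + 1L
  qe <- down$mate_start - 1L
  list(status = "anchored",
       up = up, down = down, ext_up = up$ext, ext_down = down$ext,
       qry_interval = list(chrom = up$mate_chrom, start = qs, end = qe),
       ref_window = list(chrom = chrom, start = up$ref_start,
                         end = down$ref_end),
       qry_window = list(chrom = up$mate_chrom, start = up$mate_start,
                         end = down$mate_end))
}

#' Split a complex container region at internal UAS
#'
#' Cross-aligns the container windows of the two genomes, keeps long
#' forward segments that are unique (no competing candidate overlaps them),
#' and uses them as internal UAS that partition the container.  Partitions
#' whose reference and query content are identical are discarded.
#'
#' @param ref_seq,qry_seq Container window sequences (character strings).
#' @param params [uasParams()].
#' @param aparams [alignerParams()].
#' @return `data.frame` of candidate sub-regions with region-local
#'   coordinates: `ref_start`, `ref_end`, `qry_start`, `qry_end` (1-based,
#'   inclusive, relative to the container windows).
#' @export
splitComplexRegion <- function(ref_seq, qry_seq, params = uasParams(),
                               aparams = alignerParams()) {
  segs <- alignPair(ref_seq, qry_seq, aparams, qname = "ref", tname = "qry")
  fwd <- segs[segs$strand == "+", , drop = FALSE]
  long <- fwd[pmin(fwd$qend - fwd$qstart, fwd$tend - fwd$tstart) + 1L >=
                params$min_internal_uas &
                fwd$identity >= params$min_identity, , drop = FALSE]
  if (nrow(long)) {
    # uniqueness: no competing candidate segment overlapping >20% of the span
    keep <- vapply(seq_len(nrow(long)), function(i) {
      others <- segs[-match(rownames(long)[i], rownames(segs)), ,
                     drop = FALSE]
      others <- others[others$identity >= params$candidate_floor, ,
                       drop = FALSE]
      if (!nrow(others)) return(TRUE)
      ov <- vapply(seq_len(nrow(others)), function(j) {
        ovl_width(long$qstart[i], long$qend[i],
                  others$qstart[j], others$qend[j])
      }, numeric(1))
      all(ov <= 0.2 * (long$qend[i] - long$qstart[i] + 1L))
    }, logical(1))
    long <- long[keep, , drop = FALSE]
  }
  # greedy colinear selection of the internal UAS skeleton
  long <- long[order(long$qstart), , drop = FALSE]
  sel <- list()
  last_q <- 0L; last_t <- 0L
  for (i in seq_len(nrow(long))) {
    if (long$qstart[i] > last_q && long$tstart[i] > last_t) {
      sel[[length(sel) + 1L]] <- long[i, ]
      last_q <- long$qend[i]; last_t <- long$tend[i]
    }
  }
  nref <- nchar(ref_seq); nqry <- nchar(qry_seq)
  bounds_q <- c(0L, vapply(sel, function(s) s$qend, integer(1)), nref + 1L)
  starts_q <- c(vapply(sel, function(s) s$qstart, integer(1)), nref + 1L)
  bounds_t <- c(0L, vapply(sel, function(s) s$tend, integer(1)), nqry + 1L)
  starts_t <- c(vapply(sel, function(s) s$tstart, integer(1)), nqry + 1L)
  out <- NULL
  for (i in seq_len(length(sel) + 1L)) {
    a <- bounds_q[i] + 1L; b <- starts_q[i] - 1L
    cc <- bounds_t[i] + 1L; d <- starts_t[i] - 1L
    if (b < a && d < cc) next
    rsub <- substr_safe(ref_seq, a, b)
    qsub <- substr_safe(qry_seq, cc, d)
    if (identical(rsub, qsub)) next       # no inter-genome difference
    out <- rbind(out, data.frame(ref_start = a, ref_end = b,
                                 qry_start = cc, qry_end = d))
  }
  if (is.null(out)) {
    out <- data.frame(ref_start = integer(), ref_end = integer(),
                      qry_start = integer(), qry_end = integer())
  }
  out
}
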