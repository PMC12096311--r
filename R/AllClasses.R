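#' Genome: named sequences plus an assembly-gap mask
#'
#' A thin container around a [Biostrings::DNAStringSet] that records, once,
#' where runs of ambiguous bases ('N') long enough to count as assembly gaps
#' lie.  Gap runs matter downstream: an inversion call is rejected when its
#' interval intersects a gap run in either genome.
#'
#' @slot seqs A `DNAStringSet`, uppercase, alphabet {A,C,G,T,N}.
#' @slot gaps A `GRanges` of maximal runs of at least `gapMinN` consecutive
#'   Ns (1-based, inclusive).
#' @slot gapMinN Integer; minimum N-run length that constitutes a gap.
#' @slot metadata List of provenance (simulator specs, source path, ...).
#'
#' @export
setClass("Genome",
  representation(seqs = "DNAStringSet", gaps = "GRanges",
                 gapMinN = "integer", metadata = "list"))

setValidity("Genome", function(object) {
  msgs <- character()
  if (length(object@seqs) == 0L) msgs <- c(msgs, "no sequences")
  if (any(width(object@seqs) == 0L)) msgs <- c(msgs, "zero-length sequence")
  nm <- names(object@seqs)
  if (is.null(nm) || anyDuplicated(nm)) {
    msgs <- c(msgs, "sequences must have unique names")
  }
  if (length(object@gaps)) {
    g <- object@gaps
    bad <- !as.character(seqnames(g)) %in% nm
    if (any(bad)) msgs <- c(msgs, "gap run on unknown sequence")
    # disjoint & sorted within each sequence
    for (s in unique(as.character(seqnames(g)))) {
      gi <- g[as.character(seqnames(g)) == s]
      o <- order(start(gi))
      if (any(start(gi)[o][-1] <= end(gi)[o][-length(gi)])) {
        msgs <- c(msgs, "gap runs overlap")
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Genome from sequences
#'
#' Uppercases the input and computes the N-gap mask.
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param gapMinN Minimum run of consecutive Ns that counts as an assembly
#'   gap (default 10).
#' @param metadata Optional list carried along (e.g. simulator manifest).
#' @return A [Genome-class] object.
#' @examples
#' g <- Genome(c(chr1 = "ACGTNNNNNNNNNNNNACGT"))
#' gapRuns(g)
#' @export
Genome <- function(seqs, gapMinN = 10L, metadata = list()) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    seqs <- DNAStringSet(toupper(seqs))
  } else {
    seqs <- DNAStringSet(toupper(as.character(seqs)))
  }
  gaps <- .find_gap_runs(seqs, gapMinN)
  new("Genome", seqs = seqs, gaps = gaps, gapMinN = as.integer(gapMinN),
      metadata = metadata)
}

#' @noRd
.find_gap_runs <- function(seqs, gapMinN) {
  out <- list()
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    m <- gregexpr(sprintf("N{%d,}", gapMinN), s)[[1L]]
    if (m[1L] != -1L) {
      out[[length(out) + 1L]] <- GRanges(
        names(seqs)[i],
        IRanges(start = as.integer(m),
                width = attr(m, "match.length")))
    }
  }
  if (length(out)) do.call(c, out) else GRanges()
}

#' @describeIn Genome-class number of sequences
#' @param x,object A `Genome`.
#' @export
setMethod("length", "Genome", function(x) length(x@seqs))

setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome with %d sequence(s), %d gap run(s) (>=%d N)\n",
              length(object@seqs), length(object@gaps), object@gapMinN))
  for (i in seq_len(min(5L, length(object@seqs)))) {
    cat(sprintf("  %s: %d bp\n", names(object@seqs)[i],
                width(object@seqs)[i]))
  }
  if (length(object@seqs) > 5L) cat("  ...\n")
})

#' Accessors for Genome
#'
#' `seqs()` returns the `DNAStringSet`; `gapRuns()` the gap-run `GRanges`;
#' `seqLengths()` a named integer vector; `genomeSeq()` one sequence (or a
#' subsequence) as a character string.
#'
#' @param x A [Genome-class].
#' @name genome-accessors
NULL

#' @rdname genome-accessors
#' @export
seqs <- function(x) x@seqs

#' @rdname genome-accessors
#' @export
gapRuns <- function(x) x@gaps

#' @rdname genome-accessors
#' @export
seqLengths <- function(x) setNames(width(x@seqs), names(x@seqs))

#' @rdname genome-accessors
#' @param name Sequence name.
#' @param start,end Optional 1-based inclusive bounds.
#' @export
genomeSeq <- function(x, name, start = NA, end = NA) {
  stopifnot(is(x, "Genome"))
  if (!name %in% names(x@seqs)) stopf("unknown sequence '%s'", name)
  s <- x@seqs[[name]]
  if (is.na(start)) start <- 1L
  if (is.na(end)) end <- length(s)
  start <- max(1L, as.integer(start)); end <- min(length(s), as.integer(end))
  if (end < start) return("")
  as.character(subseq(s, start, end))
}

#' Does an interval intersect an assembly-gap run?
#' @param x A [Genome-class].
#' @param chrom Sequence name.
#' @param start,end 1-based inclusive interval.
#' @return Logical.
#' @export
hasGap <- function(x, chrom, start, end) {
  g <- x@gaps
  if (!length(g)) return(FALSE)
  g <- g[as.character(seqnames(g)) == chrom]
  any(start(g) <= end & end(g) >= start)
}


#' CopyCatalog: repeat segments and their copies within an anchored SV region
#'
#' Produced by [decomposeSegments()].  Coordinates are region-local (1-based,
#' relative to the anchored region sequence of each genome).
#'
#' @slot copies `data.frame` with columns `family` (integer id), `genome`
#'   ("ref"/"qry"), `start`, `end`, `strand`, `seq`, and `sub_of` (NA or the
#'   row index of a containing copy that absorbed this one).
#' @slot similarity Numeric matrix of pairwise copy identities (rows/cols in
#'   the order of `copies`), symmetric with unit diagonal.
#' @slot tandem `data.frame` with columns `genome`, `start`, `end`,
#'   `unit_len`, `copy_count` for detected tandem blocks.
#' @export
setClass("CopyCatalog",
  representation(copies = "data.frame", similarity = "matrix",
                 tandem = "data.frame"))

setValidity("CopyCatalog", function(object) {
  msgs <- character()
  n <- nrow(object@copies)
  if (n > 0L) {
    sm <- object@similarity
    if (!all(dim(sm) == c(n, n))) msgs <- c(msgs, "similarity dim mismatch")
    else {
      if (max(abs(sm - t(sm))) > 1e-9) msgs <- c(msgs, "similarity not symmetric")
      if (any(abs(diag(sm) - 1) > 1e-9)) msgs <- c(msgs, "diagonal must be 1")
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CopyCatalog", function(object) {
  nf <- length(unique(object@copies$family))
  cat(sprintf("CopyCatalog: %d cop%s in %d famil%s, %d tandem block(s)\n",
              nrow(object@copies), if (nrow(object@copies) == 1) "y" else "ies",
              nf, if (nf == 1) "y" else "ies", nrow(object@tandem)))
})

#' @rdname CopyCatalog-class
#' @param x A `CopyCatalog`.
#' @export
copies <- function(x) x@copies

#' @rdname CopyCatalog-class
#' @export
copySimilarityMatrix <- function(x) x@similarity

#' @rdname CopyCatalog-class
#' @export
tandemBlocks <- function(x) x@tandem


#' EvalResult: benchmark comparison outcome
#'
#' @slot tp,fp,fn Integer counts.
#' @slot precision,recall,f1 Numeric in `[0,1]`; `f1 = 0` when
#'   `precision + recall == 0`.
#' @slot pairs `data.frame` of matched (call, truth) indices with breakpoint
#'   distance.
#' @slot params The [matchParams()] list used.
#' @export
setClass("EvalResult",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 precision = "numeric", recall = "numeric", f1 = "numeric",
                 pairs = "data.frame", params = "list"))

setValidity("EvalResult", function(object) {
  v <- c(object@precision, object@recall, object@f1)
  if (any(v < -1e-12 | v > 1 + 1e-12)) "metrics outside [0,1]" else TRUE
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf(
    "EvalResult: TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
    object@tp, object@fp, object@fn,
    object@precision, object@recall, object@f1))
})

#' @rdname EvalResult-class
#' @param x An `EvalResult`.
#' @export
metrics <- function(x) {
  c(tp = x@tp, fp = x@fp, fn = x@fn,
    precision = x@precision, recall = x@recall, f1 = x@f1)
}

#' @rdname EvalResult-class
#' @export
matchPairs <- function(x) x@pairs


#' AnnotationTrack: genic / regulatory / intergenic partition of a genome
#'
#' @slot intervals `GRanges` with an mcol `region_class`; the three classes
#'   partition each annotated sequence (precedence genic > regulatory >
#'   intergenic).
#' @slot totals Named numeric: total bp per class.
#' @export
setClass("AnnotationTrack",
  representation(intervals = "GRanges", totals = "numeric"))

setValidity("AnnotationTrack", function(object) {
  cls <- unique(mcols(object@intervals)$region_class)
  ok <- all(cls %in% c("genic", "regulatory", "intergenic"))
  if (!ok) "unknown region class" else TRUE
})

setMethod("show", "AnnotationTrack", function(object) {
  cat("AnnotationTrack totals (bp):\n")
  print(object@totals)
})

#' @rdname AnnotationTrack-class
#' @param x An `AnnotationTrack`.
#' @export
classTotals <- function(x) x@totals

#' @rdname AnnotationTrack-class
#' @export
classIntervals <- function(x) x@intervals
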