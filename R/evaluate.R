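# Benchmark evaluation: one-to-one matching of a call set against a truth
# set under parameterized breakpoint-distance / size-ratio / reciprocal-
# overlap rules, plus the two breakpoint-context statistics (regional
# relative rate and AT content of breakpoint windows).

#' Matching parameter presets
#'
#' `strict`: zero breakpoint deviation, full size and overlap agreement.
#' `relaxed`: 50-bp deviation, 90% size/overlap agreement.  `relaxed1k`:
#' 1-kb deviation, 90% agreement.  Sequence-similarity matching is disabled
#' throughout (`pctseq = 0`).
#'
#' @param preset "strict", "relaxed" or "relaxed1k"; or NULL to set fields
#'   directly.
#' @param refdist Maximum breakpoint distance in bp.
#' @param pctsize Minimum size ratio `min(l1,l2)/max(l1,l2)`.
#' @param pctovl Minimum reciprocal overlap (non-insertions).
#' @param pctseq Minimum sequence similarity (0 disables; only 0 is
#'   supported).
#' @param sizemin,sizemax SV size bounds applied to both sets.
#' @return Named list.
#' @export
matchParams <- function(preset = NULL, refdist = 0L, pctsize = 1,
                        pctovl = 1, pctseq = 0, sizemin = 1L,
                        sizemax = 30000000L) {
  if (!is.null(preset)) {
    return(switch(preset,
      strict = matchParams(NULL, 0L, 1, 1, 0, 1L, 30000000L),
      relaxed = matchParams(NULL, 50L, 0.9, 0.9, 0, 1L, 30000000L),
      relaxed1k = matchParams(NULL, 1000L, 0.9, 0.9, 0, 1L, 30000000L),
      stopf("unknown preset '%s'", preset)))
  }
  stopifnot(pctseq == 0)
  list(refdist = as.integer(refdist), pctsize = pctsize, pctovl = pctovl,
       pctseq = pctseq, sizemin = as.integer(sizemin),
       sizemax = as.integer(sizemax))
}

# Normalized view of an SV record set for matching: chrom, start, end,
# type class, size (per matching role).
#' @noRd
.ev_table <- function(gr) {
  mc <- mcols(gr)
  ty <- if (!is.null(mc$svtype)) mc$svtype else mc$svtype_raw
  ty[ty == "DUP"] <- "INS"              # duplicated material is insertion
  size <- integer(length(gr))
  qlen <- if (!is.null(mc$qry_len)) mc$qry_len else mc$svlen
  for (i in seq_along(gr)) {
    size[i] <- switch(ty[i],
      INS = qlen[i],
      DEL = width(gr)[i],
      INV = width(gr)[i],
      SUB = max(width(gr)[i], qlen[i]),
      if (!is.null(mc$svlen)) mc$svlen[i] else width(gr)[i])
    if (is.na(size[i])) size[i] <- width(gr)[i]
  }
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
             end = end(gr), type = ty, size = size,
             ref_len = width(gr), qry_len = ifelse(is.na(qlen), 0L, qlen),
             stringsAsFactors = FALSE)
}

# Eligibility of one call/truth pair under params.
#' @noRd
.eligible <- function(a, b, params, sub_strict) {
  if (a$chrom != b$chrom) return(FALSE)
  type_ok <- a$type == b$type
  sa <- a$size; sb <- b$size
  if (!type_ok && !sub_strict) {
    # SUB may appear as INS or DEL in another comparison: match on the
    # corresponding allele side
    if (a$type == "SUB" && b$type %in% c("INS", "DEL")) {
      sa <- if (b$type == "INS") a$qry_len else a$ref_len
      type_ok <- TRUE
    } else if (b$type == "SUB" && a$type %in% c("INS", "DEL")) {
      sb <- if (a$type == "INS") b$qry_len else b$ref_len
      type_ok <- TRUE
    }
  }
  if (!type_ok) return(FALSE)
  if (min(sa, sb) <= 0) return(FALSE)
  if (min(sa, sb) / max(sa, sb) < params$pctsize) return(FALSE)
  ds <- abs(a$start - b$start)
  de <- abs(a$end - b$end)
  ins_like <- a$type == "INS" || b$type == "INS"
  if (ins_like) {
    if (ds > params$refdist) return(FALSE)
  } else {
    if (max(ds, de) > params$refdist) return(FALSE)
  }
  if (!ins_like && a$ref_len > 0 && b$ref_len > 0) {
    w <- ovl_width(a$start, a$end, b$start, b$end)
    if (w / a$ref_len < params$pctovl || w / b$ref_len < params$pctovl) {
      return(FALSE)
    }
  }
  TRUE
}

#' Match a call set against a truth set
#'
#' One-to-one matching maximizing the TP count (augmenting-path bipartite
#' matching; candidate partners are tried closest-first, then leftmost, so
#' the result is deterministic).  Records outside `[sizemin, sizemax]` are
#' excluded before matching.  Unmatched calls are FP, unmatched truth FN.
#'
#' @param calls,truth `GRanges` with `svtype` (or `svtype_raw`) and size
#'   metadata ([resolvedSV()], [readBenchmarkVcf()], [readCallerVcf()]).
#' @param params [matchParams()].
#' @param sub_strict Disable SUB <-> INS/DEL cross-type matching.
#' @return An [EvalResult-class].
#' @export
matchCalls <- function(calls, truth, params = matchParams("strict"),
                       sub_strict = FALSE) {
  ca <- .ev_table(calls)
  tr <- .ev_table(truth)
  ca_keep <- which(ca$size >= params$sizemin & ca$size <= params$sizemax)
  tr_keep <- which(tr$size >= params$sizemin & tr$size <= params$sizemax)
  ca <- ca[ca_keep, , drop = FALSE]
  tr <- tr[tr_keep, , drop = FALSE]
  nc <- nrow(ca); nt <- nrow(tr)
  # adjacency: for each call, eligible truths sorted by distance, position
  adj <- vector("list", nc)
  if (nc && nt) {
    for (i in seq_len(nc)) {
      cand <- integer(0); dist <- numeric(0)
      for (j in seq_len(nt)) {
        if (.eligible(ca[i, ], tr[j, ], params, sub_strict)) {
          cand <- c(cand, j)
          dist <- c(dist, abs(ca$start[i] - tr$start[j]))
        }
      }
      adj[[i]] <- cand[order(dist, tr$start[cand])]
    }
  }
  match_t <- rep(NA_integer_, nt)     # truth j -> call i
  match_c <- rep(NA_integer_, nc)
  # augmenting path from call i; `seen` marks truths visited in this pass
  seen <- logical(nt)
  try_aug <- function(i) {
    for (j in adj[[i]]) {
      if (seen[j]) next
      seen[j] <<- TRUE
      if (is.na(match_t[j]) || try_aug(match_t[j])) {
        match_t[j] <<- i; match_c[i] <<- j
        return(TRUE)
      }
    }
    FALSE
  }
  order_calls <- order(ca$chrom, ca$start)
  for (i in order_calls) {
    if (length(adj[[i]])) {
      seen <- logical(nt)
      try_aug(i)
    }
  }
  tp <- sum(!is.na(match_c))
  fp <- nc - tp
  fn <- nt - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  pairs <- data.frame(
    call = ca_keep[which(!is.na(match_c))],
    truth = tr_keep[match_c[!is.na(match_c)]],
    distance = abs(ca$start[!is.na(match_c)] -
                     tr$start[match_c[!is.na(match_c)]]))
  new("EvalResult", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), precision = precision, recall = recall,
      f1 = f1, pairs = pairs, params = params)
}

#' Regional relative rate of SV breakpoints
#'
#' For each genomic class c, `rate(c) = (breakpoints in c / total
#' breakpoints) / (bp of c / genome bp)`; values above 1 indicate
#' enrichment.  Every breakpoint is assigned to exactly one class
#' (precedence genic > regulatory > intergenic is already baked into the
#' [AnnotationTrack-class] partition).
#'
#' @param svs Resolved-SV `GRanges` (canonical reference start positions
#'   are used as breakpoints).
#' @param annotation An [AnnotationTrack-class].
#' @return Named numeric vector of rates (NA for a class with zero bp).
#' @export
relativeRate <- function(svs, annotation) {
  iv <- classIntervals(annotation)
  totals <- classTotals(annotation)
  n <- length(svs)
  cls_names <- c("genic", "regulatory", "intergenic")
  if (n == 0L) return(setNames(rep(NA_real_, 3), cls_names))
  bp <- GRanges(seqnames(svs), IRanges(start(svs), width = 1L))
  hits <- findOverlaps(bp, iv)
  cls <- rep(NA_character_, n)
  cls[queryHits(hits)] <- mcols(iv)$region_class[subjectHits(hits)]
  counts <- vapply(cls_names, function(cl) sum(cls == cl, na.rm = TRUE),
                   numeric(1))
  gsize <- sum(totals)
  rates <- vapply(cls_names, function(cl) {
    if (totals[[cl]] == 0) return(NA_real_)
    (counts[[cl]] / n) / (totals[[cl]] / gsize)
  }, numeric(1))
  attr(rates, "counts") <- counts
  rates
}

#' AT content of breakpoint contexts
#'
#' Per-SV AT fraction of the window around the canonical breakpoint,
#' genome-background AT fraction, and their ratio.  Contexts truncated at
#' a sequence end are flagged.
#'
#' @param svs Resolved-SV `GRanges`.
#' @param genome Reference [Genome-class].
#' @param window Half-window in bp (default 50: a 101-bp context).
#' @param fasta Optional path; contexts are exported as FASTA for external
#'   motif tools.
#' @return A list: `per_sv` data.frame (`at_fraction`, `truncated`),
#'   `mean_at`, `background_at`, `ratio`.
#' @export
breakpointContext <- function(svs, genome, window = 50L, fasta = NULL) {
  n <- length(svs)
  at <- numeric(n); trunc <- logical(n); ctx <- character(n)
  sl <- seqLengths(genome)
  for (i in seq_len(n)) {
    chrom <- as.character(seqnames(svs)[i])
    p <- start(svs)[i]
    a <- p - window; b <- p + window
    trunc[i] <- a < 1L || b > sl[[chrom]]
    s <- genomeSeq(genome, chrom, a, b)
    ctx[i] <- s
    f <- letterFrequency(DNAString(s), c("A", "T", "G", "C"))
    denom <- sum(f)
    at[i] <- if (denom > 0) (f[["A"]] + f[["T"]]) / denom else NA_real_
  }
  all_f <- colSums(letterFrequency(seqs(genome), c("A", "T", "G", "C")))
  background <- (all_f[["A"]] + all_f[["T"]]) / sum(all_f)
  if (!is.null(fasta) && n > 0L) {
    writeLines(paste0(">", mcols(svs)$id, "\n", ctx), fasta)
  }
  list(per_sv = data.frame(at_fraction = at, truncated = trunc),
       mean_at = mean(at, na.rm = TRUE), background_at = background,
       ratio = mean(at, na.rm = TRUE) / background)
}
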