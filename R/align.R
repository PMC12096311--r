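# Desk-scale pairwise and self alignment: exact k-mer seeding (data.table
# join), colinear chaining, and gapped identity computation through
# Biostrings' affine-gap aligner.  This is the substrate that stands in for
# whole-genome aligners on region-scale sequences; external PAF alignments
# can replace it end to end.

#' Aligner parameter set
#'
#' @param k Seed length (>= 8; default 15).
#' @param min_len Minimum segment span in bp (default 45).
#' @param min_identity Minimum segment identity (default 0.8).
#' @param match,mismatch,gap_open,gap_ext Affine scoring (1 / -2 / 4 / 1).
#' @param max_join_gap Maximum gap bridged when chaining anchors (bp).
#' @param max_indel Maximum gap (on either sequence) bridged inside one
#'   chained segment; larger gaps - indels or balanced diverged stretches -
#'   split segments so that SV-scale junctions fall between segments
#'   (default 50, the SV size floor).
#' @param max_anchors Cap on anchors entering the O(n^2) chain DP.
#' @param max_dp_cells Above this matrix size the gapped aligner is skipped
#'   and identity is estimated from anchor coverage.
#' @return Named list.
#' @export
alignerParams <- function(k = 15L, min_len = 45L, min_identity = 0.8,
                          match = 1, mismatch = -2, gap_open = 4,
                          gap_ext = 1, max_join_gap = 3000L,
                          max_indel = 50L,
                          max_anchors = 4000L, max_dp_cells = 3e8) {
  stopifnot(k >= 8L)
  list(k = as.integer(k), min_len = as.integer(min_len),
       min_identity = min_identity, match = match, mismatch = mismatch,
       gap_open = gap_open, gap_ext = gap_ext,
       max_join_gap = as.integer(max_join_gap),
       max_indel = as.integer(max_indel),
       max_anchors = as.integer(max_anchors), max_dp_cells = max_dp_cells)
}

#' Precompute a k-mer position index for a sequence
#'
#' Reused across many [seedAnchors()] calls against the same target (e.g. a
#' whole genome during UAS anchoring).  K-mers containing N are excluded.
#'
#' @param seq Character string.
#' @param k Seed length.
#' @return Keyed `data.table` (kmer, pos).
#' @export
kmerIndex <- function(seq, k = 15L) {
  n <- nchar(seq)
  if (n < k) {
    dt <- data.table(kmer = character(), pos = integer())
    setkey(dt, kmer)
    return(dt)
  }
  km <- substring(seq, 1:(n - k + 1L), k:n)
  dt <- data.table(kmer = km, pos = seq_len(n - k + 1L))
  dt <- dt[!grepl("N", kmer, fixed = TRUE)]
  setkey(dt, kmer)
  dt
}

#' Exact k-mer seed anchors between two sequences
#'
#' Reports every maximal exact match of length >= k on both strands
#' (adjacent k-mer hits on the same diagonal are collapsed into one maximal
#' anchor).  Coordinates are 1-based inclusive on the forward strand of both
#' sequences; a reverse-strand anchor means the query interval matches the
#' reverse complement of the target interval.
#'
#' @param a,b Character strings (query, target).
#' @param k Seed length (>= 8).
#' @param both_strands Also search the reverse strand (default TRUE).
#' @param b_index,b_rc_index Optional precomputed [kmerIndex()] of `b` and of
#'   its reverse complement.
#' @return `data.table` with columns `qpos`, `tpos`, `len`, `strand`.
#' @export
seedAnchors <- function(a, b, k = 15L, both_strands = TRUE,
                        b_index = NULL, b_rc_index = NULL) {
  stopifnot(k >= 8L, nchar(a) > 0L, nchar(b) > 0L)
  ka <- kmerIndex(a, k)
  nb <- nchar(b)
  out <- list()
  collapse <- function(pairs, k) {
    # pairs: data.table(qpos, tpos); collapse same-diagonal runs
    if (nrow(pairs) == 0L) {
      return(data.table(qpos = integer(), tpos = integer(), len = integer()))
    }
    pairs[, diag := tpos - qpos]
    data.table::setorder(pairs, diag, qpos)
    pairs[, run := cumsum(c(1L, diff(qpos) != 1L | diff(diag) != 0L))]
    pairs[, .(qpos = qpos[1L], tpos = tpos[1L],
              len = qpos[.N] - qpos[1L] + k), by = run][, run := NULL][]
  }
  if (is.null(b_index)) b_index <- kmerIndex(b, k)
  fwd <- ka[b_index, on = "kmer", nomatch = NULL,
            allow.cartesian = TRUE][, .(qpos = pos, tpos = i.pos)]
  fwd <- collapse(fwd, k)
  if (nrow(fwd)) fwd[, strand := "+"]
  out$fwd <- fwd
  if (both_strands) {
    if (is.null(b_rc_index)) b_rc_index <- kmerIndex(revcomp(b), k)
    rev <- ka[b_rc_index, on = "kmer", nomatch = NULL,
              allow.cartesian = TRUE][, .(qpos = pos, tpos = i.pos)]
    rev <- collapse(rev, k)   # tpos in reverse-complement coordinates
    if (nrow(rev)) {
      rev[, tpos := nb - (tpos + len - 1L) + 1L]  # map to forward strand
      rev[, strand := "-"]
    }
    out$rev <- rev
  }
  res <- rbindlist(out, fill = TRUE)
  if (!nrow(res)) {
    res <- data.table(qpos = integer(), tpos = integer(), len = integer(),
                      strand = character())
  }
  res[]
}

#' @noRd
.submat <- function(params) {
  nucleotideSubstitutionMatrix(match = params$match,
                               mismatch = params$mismatch)
}

# Global affine-gap alignment statistics of two subsequences.
#' @noRd
.align_stats <- function(sa, sb, params) {
  la <- nchar(sa); lb <- nchar(sb)
  if (la == 0L || lb == 0L) return(list(matches = 0, blocklen = max(la, lb)))
  if (as.numeric(la) * lb > params$max_dp_cells) {
    # too large for DP: estimate from anchor coverage
    anc <- seedAnchors(sa, sb, params$k, both_strands = FALSE)
    m <- if (nrow(anc)) sum(anc[strand == "+", len]) else 0
    return(list(matches = min(m, min(la, lb)), blocklen = max(la, lb)))
  }
  aln <- pairwiseAlignment(DNAString(sa), DNAString(sb),
                           substitutionMatrix = .submat(params),
                           gapOpening = params$gap_open,
                           gapExtension = params$gap_ext, type = "global")
  # alignment columns including gap columns (nchar() omits insertions)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)[[1L]]))
  list(matches = nmatch(aln), blocklen = cols)
}

# Colinear chain DP over anchors in ascending working coordinates.
# Returns a list of chains; each chain is an integer vector of anchor rows.
#' @noRd
.chain_anchors <- function(qpos, tpos, len, params) {
  n <- length(qpos)
  if (n == 0L) return(list())
  if (n > params$max_anchors) {
    keep <- order(len, decreasing = TRUE)[seq_len(params$max_anchors)]
    keep <- sort(keep)
    map <- keep
    qpos <- qpos[keep]; tpos <- tpos[keep]; len <- len[keep]
    n <- length(qpos)
  } else map <- seq_len(n)
  o <- order(qpos, tpos)
  qpos <- qpos[o]; tpos <- tpos[o]; len <- len[o]; map <- map[o]
  qend <- qpos + len - 1L; tend <- tpos + len - 1L
  dp <- as.numeric(len); parent <- integer(n)
  for (i in seq_len(n)) {
    j <- i - 1L
    while (j >= 1L) {
      if (qpos[i] - qend[j] > params$max_join_gap) break
      if (tpos[i] > tpos[j] && qpos[i] > qpos[j] &&
          tend[j] - tpos[i] < len[i] && qend[j] - qpos[i] < len[i]) {
        dq <- qpos[i] - qend[j] - 1L
        dt <- tpos[i] - tend[j] - 1L
        if (dt <= params$max_join_gap &&
            max(dq, dt) <= params$max_indel &&
            abs(dq - dt) <= params$max_indel) {
          ov <- max(0L, -min(dq, dt))     # overlap between anchors
          cost <- 0.01 * max(dq, dt, 0) + 0.5 * abs(dq - dt) + ov
          cand <- dp[j] + len[i] - cost
          if (cand > dp[i]) { dp[i] <- cand; parent[i] <- j }
        }
      }
      j <- j - 1L
    }
  }
  used <- logical(n)
  chains <- list()
  for (i in order(dp, decreasing = TRUE)) {
    if (used[i]) next
    ch <- integer(0)
    j <- i
    while (j >= 1L && !used[j]) {
      ch <- c(j, ch)
      used[j] <- TRUE
      j <- parent[j]
    }
    chains[[length(chains) + 1L]] <- map[ch]
  }
  chains
}

#' Chain seed anchors and compute gapped alignment segments
#'
#' Anchors are chained colinearly per strand (affine gap cost), each chain's
#' spanning intervals are re-aligned globally, and segments shorter than
#' `min_len` or below `min_identity` are dropped.
#'
#' @param anchors Output of [seedAnchors()].
#' @param a,b The two sequences (character strings).
#' @param params [alignerParams()].
#' @param qname,tname Names stamped on the output rows.
#' @return Alignment-segment `data.frame` (see [readPaf()] for columns),
#'   sorted by (strand, qstart, tstart).
#' @export
chainAndExtend <- function(anchors, a, b, params = alignerParams(),
                           qname = "q", tname = "t") {
  nb <- nchar(b)
  res <- list()
  for (str in c("+", "-")) {
    anc <- anchors[anchors$strand == str, , drop = FALSE]
    if (nrow(anc) == 0L) next
    if (str == "+") {
      wq <- anc$qpos; wt <- anc$tpos
      bwork <- b
    } else {
      # work in reverse-complement coordinates so chains ascend in both
      wq <- anc$qpos; wt <- nb - (anc$tpos + anc$len - 1L) + 1L
      bwork <- revcomp(b)
    }
    chains <- .chain_anchors(wq, wt, anc$len, params)
    for (ch in chains) {
      qs <- min(wq[ch]); qe <- max(wq[ch] + anc$len[ch] - 1L)
      ts <- min(wt[ch]); te <- max(wt[ch] + anc$len[ch] - 1L)
      if (min(qe - qs, te - ts) + 1L < params$min_len) next
      st <- .align_stats(substr(a, qs, qe), substr(bwork, ts, te), params)
      ident <- if (st$blocklen > 0) st$matches / st$blocklen else 0
      if (ident < params$min_identity) next
      if (str == "-") {
        t1 <- nb - te + 1L; t2 <- nb - ts + 1L
      } else {
        t1 <- ts; t2 <- te
      }
      res[[length(res) + 1L]] <- data.frame(
        qname = qname, qstart = qs, qend = qe,
        tname = tname, tstart = t1, tend = t2,
        strand = str, matches = st$matches, blocklen = st$blocklen,
        identity = ident, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(emptySegments())
  out <- do.call(rbind, res)
  out[order(out$strand, out$qstart, out$tstart), , drop = FALSE]
}

#' Align two sequences (seed, chain, extend)
#'
#' @param a,b Character strings.
#' @param params [alignerParams()].
#' @param both_strands Search both strands (default TRUE).
#' @param b_index,b_rc_index Optional precomputed [kmerIndex()] of `b`.
#' @inheritParams chainAndExtend
#' @return Alignment-segment `data.frame`.
#' @export
alignPair <- function(a, b, params = alignerParams(), both_strands = TRUE,
                      qname = "q", tname = "t",
                      b_index = NULL, b_rc_index = NULL) {
  anc <- seedAnchors(a, b, params$k, both_strands = both_strands,
                     b_index = b_index, b_rc_index = b_rc_index)
  chainAndExtend(as.data.frame(anc), a, b, params, qname = qname,
                 tname = tname)
}

#' Self-alignment of a sequence
#'
#' The trivial full-length main diagonal is excluded; symmetric duplicates
#' are reduced to `qstart <= tstart`.  Off-diagonal forward segments signal
#' tandem/dispersed repeats; reverse segments signal fold-back structure.
#'
#' @param seq Character string.
#' @param params [alignerParams()].
#' @return Alignment-segment `data.frame`.
#' @export
selfAlign <- function(seq, params = alignerParams()) {
  anc <- seedAnchors(seq, seq, params$k, both_strands = TRUE)
  anc <- anc[!(anc$strand == "+" & anc$qpos == anc$tpos), ]
  anc <- anc[!(anc$strand == "+" & anc$qpos > anc$tpos), ]      # symmetric dup
  anc <- anc[!(anc$strand == "-" & anc$qpos > anc$tpos), ]
  if (nrow(anc) == 0L) return(emptySegments())
  segs <- chainAndExtend(as.data.frame(anc), seq, seq, params,
                         qname = "self", tname = "self")
  segs[!(segs$strand == "+" & segs$qstart == segs$tstart &
           segs$qend == segs$tend), , drop = FALSE]
}

#' End-to-end identity between two copies
#'
#' Identity of the global (end-to-end) affine-gap alignment, defined as
#' matches divided by alignment columns (gap columns count in the
#' denominator).  With `orientation = "best"` both orientations are tried
#' and the better one is returned, with the chosen orientation recorded in
#' `attr(, "orientation")`.
#'
#' @param a,b Character strings.
#' @param orientation "best", "forward" or "reverse".
#' @param params [alignerParams()].
#' @return Identity in `[0, 1]`.
#' @export
copySimilarity <- function(a, b, orientation = c("best", "forward",
                                                 "reverse"),
                           params = alignerParams()) {
  orientation <- match.arg(orientation)
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  idf <- function(bb) {
    st <- .align_stats(a, bb, params)
    if (st$blocklen > 0) st$matches / st$blocklen else 0
  }
  if (orientation == "forward") {
    out <- idf(b); attr(out, "orientation") <- "forward"; return(out)
  }
  if (orientation == "reverse") {
    out <- idf(revcomp(b)); attr(out, "orientation") <- "reverse"
    return(out)
  }
  f <- idf(b); r <- idf(revcomp(b))
  out <- max(f, r)
  attr(out, "orientation") <- if (f >= r) "forward" else "reverse"
  out
}
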