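# Breakpoint resolution inside an anchored SV region: catalogue repeat
# segments and copies, pair orthologous copies by similarity, lay a colinear
# chain skeleton across the region pair, and place base-pair breakpoints at
# the junctions, with canonical (leftmost) placement and an exhaustively
# shifted ambiguity interval.

#' Detect the tandem-repeat unit of a sequence
#'
#' Finds the smallest period p such that the sequence matches itself
#' shifted by p at identity >= `min_identity` (and spans at least two
#' units).  Returns `NULL` for aperiodic input.
#'
#' @param seq Character string.
#' @param min_identity Shift-identity threshold between adjacent units
#'   (default 0.9).
#' @param max_unit Largest period searched (default `floor(n/2)`).
#' @return `list(unit_len, copy_count)` or `NULL`.
#' @export
detectTandemUnit <- function(seq, min_identity = 0.9, max_unit = NULL) {
  n <- nchar(seq)
  if (n < 2L) return(NULL)
  v <- utf8ToInt(seq)
  pmax_ <- min(max_unit %||% (n %/% 2L), n %/% 2L)
  for (p in seq_len(pmax_)) {
    idm <- mean(v[seq_len(n - p)] == v[(p + 1L):n])
    if (idm >= min_identity) {
      return(list(unit_len = p, copy_count = n %/% p))
    }
  }
  NULL
}

# Maximal extent of period-p structure around [s, e] in seq (exact runs of
# v[i] == v[i + p]); returns the enclosing interval.
#' @noRd
.tandem_extent <- function(seq, s, e, p) {
  v <- utf8ToInt(seq)
  n <- length(v)
  lb <- max(1L, s)
  while (lb - 1L >= 1L && lb - 1L + p <= n && v[lb - 1L] == v[lb - 1L + p]) {
    lb <- lb - 1L
  }
  ub <- min(n, e)
  while (ub + 1L <= n && ub + 1L - p >= 1L && v[ub + 1L] == v[ub + 1L - p]) {
    ub <- ub + 1L
  }
  c(lb, ub)
}

# Count distinct loci at which `probe` occurs in `seq` (chained hits
# covering >= min_cov of the probe at identity >= floor; overlapping hit
# loci merged).
#' @noRd
.count_occurrences <- function(probe, seq, params, min_cov = 0.6,
                               floor_id = 0.8) {
  if (nchar(probe) < params$k || nchar(seq) < params$k) return(0L)
  p2 <- params
  p2$min_identity <- floor_id
  p2$min_len <- max(15L, min(p2$min_len, as.integer(0.5 * nchar(probe))))
  segs <- alignPair(probe, seq, p2, both_strands = FALSE)
  if (!nrow(segs)) return(0L)
  # diverged copies split into colinear pieces: merge into hit loci first
  loci <- mergeHitLoci(segs, flank_len = nchar(probe),
                       max_gap = as.integer(0.3 * nchar(probe)))
  loci <- loci[loci$identity >= floor_id & loci$coverage >= min_cov, ,
               drop = FALSE]
  nrow(loci)
}

#' Decompose an anchored region pair into repeat segments and copies
#'
#' Self- and cross-alignment segments are clustered into segment families
#' (connected components under reciprocal interval overlap >= 0.8 and
#' alignment linkage); every family's occurrences are enumerated in both
#' genomes; copies >= 95% contained within another copy of the same genome
#' are collapsed as sub-segments.  Tandem blocks get unit length and copy
#' count.  Families whose copies are 1:1 (no repetition) are not repeat
#' families and are dropped; with no self-similarity at all the catalog is
#' empty (unique-context region).
#'
#' @param ref_seq,qry_seq Anchored region sequences (character strings).
#' @param params [alignerParams()].
#' @param max_copies Cap on catalogued copies per family and genome
#'   (longest kept; default 8).  Capping per side keeps the two genomes'
#'   copy lists balanced.
#' @return A [CopyCatalog-class].
#' @export
decomposeSegments <- function(ref_seq, qry_seq, params = alignerParams(),
                              max_copies = 8L) {
  self_r <- selfAlign(ref_seq, params)
  self_q <- selfAlign(qry_seq, params)
  cross <- alignPair(ref_seq, qry_seq, params, qname = "ref", tname = "qry")
  cap <- function(x, n = 200L) {
    if (nrow(x) <= n) return(x)
    x[order(x$qend - x$qstart, decreasing = TRUE)[seq_len(n)], , drop = FALSE]
  }
  self_r <- cap(self_r); self_q <- cap(self_q); cross <- cap(cross)

  # tandem blocks: overlapping-diagonal forward self segments
  tandem <- NULL
  for (gen in c("ref", "qry")) {
    sa <- if (gen == "ref") self_r else self_q
    sq <- if (gen == "ref") ref_seq else qry_seq
    sa <- sa[sa$strand == "+" & sa$tstart > sa$qstart &
               sa$tstart <= sa$qend, , drop = FALSE]
    if (!nrow(sa)) next
    sa$period <- sa$tstart - sa$qstart
    sa <- sa[order(sa$qstart, sa$period), , drop = FALSE]
    claimed <- integer(0)
    for (i in seq_len(nrow(sa))) {
      if (sa$qstart[i] %in% claimed) next
      ext <- .tandem_extent(sq, sa$qstart[i], sa$tend[i], sa$period[i])
      span <- substr(sq, ext[1], ext[2])
      tu <- detectTandemUnit(span)
      if (is.null(tu) || tu$copy_count < 2L) next
      tandem <- rbind(tandem, data.frame(
        genome = gen, start = ext[1], end = ext[2],
        unit_len = tu$unit_len, copy_count = tu$copy_count,
        stringsAsFactors = FALSE))
      claimed <- c(claimed, seq(ext[1], ext[2]))
    }
  }
  if (is.null(tandem)) {
    tandem <- data.frame(genome = character(), start = integer(),
                         end = integer(), unit_len = integer(),
                         copy_count = integer(), stringsAsFactors = FALSE)
  } else {
    tandem <- unique(tandem)
  }

  # candidate copy intervals from all alignment evidence
  iv <- rbind(
    if (nrow(self_r)) data.frame(genome = "ref", start = self_r$qstart,
                                 end = self_r$qend, strand = self_r$strand,
                                 link = paste0("sr", seq_len(nrow(self_r)))),
    if (nrow(self_r)) data.frame(genome = "ref", start = self_r$tstart,
                                 end = self_r$tend, strand = self_r$strand,
                                 link = paste0("sr", seq_len(nrow(self_r)))),
    if (nrow(self_q)) data.frame(genome = "qry", start = self_q$qstart,
                                 end = self_q$qend, strand = self_q$strand,
                                 link = paste0("sq", seq_len(nrow(self_q)))),
    if (nrow(self_q)) data.frame(genome = "qry", start = self_q$tstart,
                                 end = self_q$tend, strand = self_q$strand,
                                 link = paste0("sq", seq_len(nrow(self_q)))),
    if (nrow(cross)) data.frame(genome = "ref", start = cross$qstart,
                                end = cross$qend, strand = cross$strand,
                                link = paste0("x", seq_len(nrow(cross)))),
    if (nrow(cross)) data.frame(genome = "qry", start = cross$tstart,
                                end = cross$tend, strand = cross$strand,
                                link = paste0("x", seq_len(nrow(cross)))))
  empty_cat <- new("CopyCatalog",
                   copies = data.frame(family = integer(),
                                       genome = character(),
                                       start = integer(), end = integer(),
                                       strand = character(),
                                       seq = character(),
                                       sub_of = integer(),
                                       stringsAsFactors = FALSE),
                   similarity = matrix(numeric(), 0, 0), tandem = tandem)
  if (is.null(iv) || nrow(iv) == 0L) return(empty_cat)

  # cluster intervals per genome (greedy against cluster representatives,
  # reciprocal overlap >= 0.8)
  iv$cluster <- NA_integer_
  ncl <- 0L
  for (gen in c("ref", "qry")) {
    idx <- which(iv$genome == gen)
    idx <- idx[order(iv$start[idx], iv$end[idx])]
    reps <- integer(0)                 # representative row per cluster
    for (i in idx) {
      for (r in reps) {
        if (reciprocal_overlap(iv$start[i], iv$end[i],
                               iv$start[r], iv$end[r]) >= 0.8) {
          iv$cluster[i] <- iv$cluster[r]
          break
        }
      }
      if (is.na(iv$cluster[i])) {
        ncl <- ncl + 1L
        iv$cluster[i] <- ncl
        reps <- c(reps, i)
      }
    }
  }

  # families: connected components of clusters linked by shared alignments
  parent <- seq_len(ncl)
  findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  unite <- function(a, b) {
    ra <- findp(a); rb <- findp(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (lk in unique(iv$link)) {
    cl <- unique(iv$cluster[iv$link == lk])
    if (length(cl) == 2L) unite(cl[1], cl[2])
  }
  fam_of_cluster <- vapply(seq_len(ncl), findp, integer(1))

  # one copy per cluster: the median interval of its members
  rows <- NULL
  for (cl in seq_len(ncl)) {
    mem <- iv[iv$cluster == cl, , drop = FALSE]
    s <- as.integer(round(median(mem$start)))
    e <- as.integer(round(median(mem$end)))
    gen <- mem$genome[1]
    strand <- if (any(mem$strand == "-")) "-" else "+"
    sq <- if (gen == "ref") ref_seq else qry_seq
    rows <- rbind(rows, data.frame(
      family = fam_of_cluster[cl], genome = gen, start = s, end = e,
      strand = strand, seq = substr(sq, s, e), sub_of = NA_integer_,
      stringsAsFactors = FALSE))
  }
  # renumber families compactly, order copies by (family, genome, start)
  rows$family <- as.integer(factor(rows$family))
  rows <- rows[order(rows$family, rows$genome, rows$start), , drop = FALSE]
  rownames(rows) <- NULL

  # drop non-repeat families (single copy in each genome)
  keep_fam <- vapply(unique(rows$family), function(f) {
    rc <- sum(rows$family == f & rows$genome == "ref")
    qc <- sum(rows$family == f & rows$genome == "qry")
    rc >= 2L || qc >= 2L
  }, logical(1))
  rows <- rows[rows$family %in% unique(rows$family)[keep_fam], ,
               drop = FALSE]
  if (nrow(rows) == 0L) return(empty_cat)
  rows$family <- as.integer(factor(rows$family))
  rownames(rows) <- NULL

  # sub-segment collapse: >= 95% contained in a same-genome sibling
  for (i in seq_len(nrow(rows))) {
    for (j in seq_len(nrow(rows))) {
      if (i == j || rows$genome[i] != rows$genome[j]) next
      if (!is.na(rows$sub_of[j])) next
      wi <- rows$end[i] - rows$start[i] + 1L
      wj <- rows$end[j] - rows$start[j] + 1L
      if (wi >= wj) next
      ov <- ovl_width(rows$start[i], rows$end[i], rows$start[j], rows$end[j])
      if (ov >= 0.95 * wi) {
        rows$sub_of[i] <- j
        break
      }
    }
  }
  keep_rows <- unlist(lapply(split(seq_len(nrow(rows)),
                                   paste(rows$family, rows$genome)),
                             function(idx) {
    if (length(idx) <= max_copies) return(idx)
    o <- order(rows$end[idx] - rows$start[idx], decreasing = TRUE)
    sort(idx[o[seq_len(max_copies)]])
  }))
  rows <- rows[sort(keep_rows), , drop = FALSE]
  rownames(rows) <- NULL
  active <- which(is.na(rows$sub_of))
  sm <- diag(nrow = nrow(rows))
  for (ii in seq_along(active)) {
    for (jj in seq_len(ii - 1L)) {
      i <- active[ii]; j <- active[jj]
      if (rows$family[i] != rows$family[j]) next
      sim <- as.numeric(copySimilarity(rows$seq[i], rows$seq[j],
                                       params = params))
      sm[i, j] <- sim; sm[j, i] <- sim
    }
  }
  new("CopyCatalog", copies = rows, similarity = sm, tandem = tandem)
}

# ---- optimal assignment ---------------------------------------------------

# Exhaustive maximum-weight one-to-one assignment; rows <= cols assumed.
# Ties resolved toward the lexicographically smallest assignment vector
# (rows and columns arrive sorted by genomic position: leftmost wins).
#' @noRd
.assign_exhaustive <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_score <- -Inf
  for (p in perms(seq_len(nc))) {
    sel <- p[seq_len(nr)]
    sc <- sum(w[cbind(seq_len(nr), sel)])
    if (sc > best_score + 1e-12) {
      best_score <- sc; best <- sel
    }
  }
  best
}

# Hungarian algorithm (potentials + augmenting paths) on a square cost
# matrix, minimization.  Index 1 of p/v/minv/used/way is the column
# sentinel; u has a row sentinel at index 1.
#' @noRd
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L)                 # u[i + 1]: row potential
  v <- numeric(n + 1L)                 # v[j + 1]: column potential
  p <- integer(n + 1L)                 # p[j + 1]: row matched to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

# Maximum-weight assignment dispatcher: exhaustive for small instances,
# Hungarian otherwise.  Returns, per row, the assigned column (NA if
# unassigned because nc < nr).
#' @noRd
.max_assignment <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  if (nr == 0L || nc == 0L) return(rep(NA_integer_, nr))
  flip <- nr > nc
  if (flip) w <- t(w)
  n1 <- nrow(w); n2 <- ncol(w)
  sel <- if (n2 <= 6L) .assign_exhaustive(w) else {
    # pad to square, convert to cost
    n <- max(n1, n2)
    cost <- matrix(max(w) + 1, n, n)
    cost[seq_len(n1), seq_len(n2)] <- max(w) - w
    full <- .hungarian(cost)
    sel <- full[seq_len(n1)]
    sel[sel > n2] <- NA_integer_       # padded (dummy) column
    sel
  }
  if (!flip) {
    out <- rep(NA_integer_, nr)
    out[seq_len(n1)] <- sel
    out
  } else {
    out <- rep(NA_integer_, nr)      # nr original rows = n2 columns here
    out[sel] <- seq_len(n1)
    out
  }
}

#' Pair orthologous repeat copies by similarity
#'
#' One-to-one pairing of reference to query copies of each segment family
#' maximizing total similarity (exhaustive assignment for up to six copies
#' per side, Hungarian beyond), ties broken toward genomic order
#' (leftmost-to-leftmost).  Unpaired copies are the variant material.
#'
#' @param catalog A [CopyCatalog-class].
#' @param family Optional single family id to restrict to.
#' @return `data.frame` with columns `family`, `ref`, `qry` (row indices
#'   into `copies(catalog)`) and `similarity`; attribute `unpaired` lists
#'   unmatched copy rows.
#' @export
matchCopies <- function(catalog, family = NULL) {
  cp <- copies(catalog)
  sm <- copySimilarityMatrix(catalog)
  fams <- if (is.null(family)) unique(cp$family) else family
  out <- NULL
  unpaired <- integer(0)
  for (f in fams) {
    ir <- which(cp$family == f & cp$genome == "ref" & is.na(cp$sub_of))
    iq <- which(cp$family == f & cp$genome == "qry" & is.na(cp$sub_of))
    ir <- ir[order(cp$start[ir])]
    iq <- iq[order(cp$start[iq])]
    if (length(ir) == 0L || length(iq) == 0L) {
      unpaired <- c(unpaired, ir, iq)
      next
    }
    w <- sm[ir, iq, drop = FALSE]
    sel <- .max_assignment(w)
    for (i in seq_along(ir)) {
      if (is.na(sel[i])) {
        unpaired <- c(unpaired, ir[i])
      } else {
        out <- rbind(out, data.frame(family = f, ref = ir[i],
                                     qry = iq[sel[i]],
                                     similarity = w[i, sel[i]]))
      }
    }
    unpaired <- c(unpaired, setdiff(iq, iq[sel[!is.na(sel)]]))
  }
  if (is.null(out)) {
    out <- data.frame(family = integer(), ref = integer(), qry = integer(),
                      similarity = numeric())
  }
  attr(out, "unpaired") <- sort(unpaired)
  out
}

# ---- breakpoint placement -------------------------------------------------

# Colinear skeleton: subset of forward segments maximizing total matches
# under strict colinearity; small overlaps trimmed from the later segment.
#' @noRd
.chain_skeleton <- function(segs) {
  segs <- segs[segs$strand == "+", , drop = FALSE]
  if (!nrow(segs)) return(segs)
  segs <- segs[order(segs$qstart, segs$tstart), , drop = FALSE]
  n <- nrow(segs)
  dp <- segs$matches
  parent <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ovq <- segs$qend[j] - segs$qstart[i] + 1L
      ovt <- segs$tend[j] - segs$tstart[i] + 1L
      maxov <- 0.5 * min(segs$qend[i] - segs$qstart[i],
                         segs$qend[j] - segs$qstart[j]) + 1
      if (segs$qstart[i] > segs$qstart[j] && segs$tstart[i] > segs$tstart[j] &&
          ovq < maxov && ovt < maxov) {
        trim <- max(0L, ovq, ovt)
        cand <- dp[j] + segs$matches[i] - trim
        if (cand > dp[i]) { dp[i] <- cand; parent[i] <- j }
      }
    }
  }
  i <- which.max(dp)
  sel <- integer(0)
  while (i > 0L) { sel <- c(i, sel); i <- parent[i] }
  out <- segs[sel, , drop = FALSE]
  # trim residual overlaps between consecutive blocks
  if (nrow(out) > 1L) {
    for (i in 2:nrow(out)) {
      dq <- out$qend[i - 1L] - out$qstart[i] + 1L
      dt <- out$tend[i - 1L] - out$tstart[i] + 1L
      cut <- max(0L, dq, dt)
      if (cut > 0L) {
        out$qstart[i] <- out$qstart[i] + cut
        out$tstart[i] <- out$tstart[i] + cut
      }
    }
    out <- out[out$qstart <= out$qend & out$tstart <= out$tend, ,
               drop = FALSE]
  }
  out
}

# Left-shift a deletion (in x) / insertion (in the carrying sequence) to its
# leftmost equivalent placement and count equivalent placements.
# x: the sequence carrying the extra material; a..b its interval.
#' @noRd
.normalize_indel <- function(x, a, b, lo = 1L) {
  shifts_left <- 0L
  while (a - 1L >= lo && substr(x, a - 1L, a - 1L) == substr(x, b, b)) {
    a <- a - 1L; b <- b - 1L
    shifts_left <- shifts_left + 1L
  }
  n <- nchar(x)
  s <- 0L
  while (b + s + 1L <= n &&
         substr(x, a + s, a + s) == substr(x, b + s + 1L, b + s + 1L)) {
    s <- s + 1L
  }
  list(a = a, b = b, shifts_left = shifts_left, ambig_len = s + 1L)
}

#' Infer the breakpoint-pattern category of variant material
#'
#' Classifies the repeat context of a junction into the four categories:
#' `unique` (no repeat involvement), `cat1` (single-segment copy present
#' once in one genome, multiply in the other, or unique sequence joining
#' copies), `cat2` (multi-segment copy present once in one genome, multiply
#' in the other) and `cat3` (multiple distinct copies in both genomes,
#' typically tandem arrays).
#'
#' @param variant Variant (unpaired residual) sequence.
#' @param ref_ctx,qry_ctx Region sequences of the two genomes.
#' @param ref_at,qry_at Junction position in each context (1-based start).
#' @param params [alignerParams()].
#' @return Pattern string.
#' @export
inferPattern <- function(variant, ref_ctx, qry_ctx, ref_at, qry_at,
                         params = alignerParams()) {
  if (nchar(variant) == 0L) return("unique")
  tu <- detectTandemUnit(variant)
  tandem <- !is.null(tu) && tu$unit_len >= 10L && tu$copy_count >= 2L
  if (tandem) {
    p <- tu$unit_len
    er <- .tandem_extent(ref_ctx, ref_at, min(nchar(ref_ctx),
                                              ref_at + nchar(variant) - 1L), p)
    eq <- .tandem_extent(qry_ctx, qry_at, min(nchar(qry_ctx),
                                              qry_at + nchar(variant) - 1L), p)
    refC <- (er[2] - er[1] + 1L) %/% p
    qryC <- (eq[2] - eq[1] + 1L) %/% p
  } else {
    probe <- variant
    if (nchar(probe) < params$k) return("unique")
    refC <- .count_occurrences(probe, ref_ctx, params)
    qryC <- .count_occurrences(probe, qry_ctx, params)
  }
  if (refC <= 1L && qryC <= 1L) return("unique")
  if (min(refC, qryC) >= 2L) return("cat3")
  multiseg <- FALSE
  if (!tandem) {
    sa <- selfAlign(variant, params)
    multiseg <- nrow(sa) > 0L
  }
  if (multiseg) "cat2" else "cat1"
}

#' Place base-pair breakpoints across an anchored region pair
#'
#' Lays a colinear forward chain skeleton over the two region sequences,
#' trims every junction to its minimal unmatched residuals, normalizes
#' indels to their leftmost placement, enumerates the equivalent-placement
#' (ambiguity) interval, and tags each call with its breakpoint-pattern
#' category.  Junctions whose residuals still align in forward orientation
#' above `sub_max_identity` are decomposed further with finer seeds before
#' being accepted as substitutions.
#'
#' @param ref_seq,qry_seq Anchored region sequences (character strings).
#' @param catalog Optional [CopyCatalog-class] (computed when needed).
#' @param pairing Optional [matchCopies()] result (currently only the
#'   catalog's context is used for pattern inference).
#' @param params [alignerParams()].
#' @param sub_max_identity Forward identity above which residual pairs are
#'   decomposed rather than typed as SUB (default 0.8).
#' @param max_depth Recursion depth for further decomposition (default 2).
#' @return `data.frame` of breakpoint calls with region-local coordinates:
#'   `ref_start`, `ref_end` (zero-width for pure insertions:
#'   `ref_end = ref_start - 1`), `qry_start`, `qry_end` (zero-width for
#'   deletions), `ambig_len`, `pattern`, `fwd_identity`, `rev_identity`,
#'   and the residual sequences `ref_res`, `qry_res`.
#' @export
placeBreakpoints <- function(ref_seq, qry_seq, catalog = NULL,
                             pairing = NULL, params = alignerParams(),
                             sub_max_identity = 0.8, max_depth = 2L) {
  empty <- data.frame(ref_start = integer(), ref_end = integer(),
                      qry_start = integer(), qry_end = integer(),
                      ambig_len = integer(), pattern = character(),
                      fwd_identity = numeric(), rev_identity = numeric(),
                      ref_res = character(), qry_res = character(),
                      stringsAsFactors = FALSE)
  if (identical(ref_seq, qry_seq)) return(empty)
  nR <- nchar(ref_seq); nQ <- nchar(qry_seq)
  segs <- alignPair(ref_seq, qry_seq, params, qname = "ref", tname = "qry")
  skel <- .chain_skeleton(segs)
  if (nrow(skel) == 0L) {
    gaps_r <- data.frame(a = 1L, b = nR)
    gaps_q <- data.frame(c = 1L, d = nQ)
  } else {
    a <- c(1L, skel$qend + 1L)
    b <- c(skel$qstart - 1L, nR)
    cc <- c(1L, skel$tend + 1L)
    d <- c(skel$tstart - 1L, nQ)
    gaps_r <- data.frame(a = a, b = b)
    gaps_q <- data.frame(c = cc, d = d)
  }

  calls <- empty
  for (g in seq_len(nrow(gaps_r))) {
    a <- gaps_r$a[g]; b <- gaps_r$b[g]
    cc <- gaps_q$c[g]; d <- gaps_q$d[g]
    # character-level trim (the chain may be shy of the true junction)
    while (a <= b && cc <= d &&
           substr(ref_seq, a, a) == substr(qry_seq, cc, cc)) {
      a <- a + 1L; cc <- cc + 1L
    }
    while (b >= a && d >= cc &&
           substr(ref_seq, b, b) == substr(qry_seq, d, d)) {
      b <- b - 1L; d <- d - 1L
    }
    ref_empty <- b < a; qry_empty <- d < cc
    if (ref_empty && qry_empty) next
    if (!ref_empty && !qry_empty) {
      rres <- substr(ref_seq, a, b); qres <- substr(qry_seq, cc, d)
      fwd <- as.numeric(copySimilarity(rres, qres, "forward", params))
      rev <- as.numeric(copySimilarity(rres, qres, "reverse", params))
      if (fwd >= sub_max_identity && max_depth > 0L) {
        p2 <- params
        p2$k <- max(8L, params$k - 4L)
        p2$min_len <- max(15L, params$min_len %/% 3L)
        sub <- placeBreakpoints(rres, qres, params = p2,
                                sub_max_identity = sub_max_identity,
                                max_depth = max_depth - 1L)
        if (nrow(sub)) {
          sub$ref_start <- sub$ref_start + a - 1L
          sub$ref_end <- sub$ref_end + a - 1L
          sub$qry_start <- sub$qry_start + cc - 1L
          sub$qry_end <- sub$qry_end + cc - 1L
          # re-derive patterns in the full context
          for (i in seq_len(nrow(sub))) {
            varseq <- if (nchar(sub$ref_res[i]) >= nchar(sub$qry_res[i]))
              sub$ref_res[i] else sub$qry_res[i]
            sub$pattern[i] <- inferPattern(varseq, ref_seq, qry_seq,
                                           sub$ref_start[i],
                                           sub$qry_start[i], params)
          }
          calls <- rbind(calls, sub)
          next
        }
      }
      pat <- inferPattern(if (nchar(rres) >= nchar(qres)) rres else qres,
                          ref_seq, qry_seq, a, cc, params)
      calls <- rbind(calls, data.frame(
        ref_start = a, ref_end = b, qry_start = cc, qry_end = d,
        ambig_len = 1L, pattern = pat, fwd_identity = fwd,
        rev_identity = rev, ref_res = rres, qry_res = qres,
        stringsAsFactors = FALSE))
    } else if (qry_empty) {
      # deletion of ref_seq[a..b]; normalize leftmost over the reference
      nm <- .normalize_indel(ref_seq, a, b)
      shift <- a - nm$a
      qanchor <- cc - shift            # zero-width query anchor
      rres <- substr(ref_seq, nm$a, nm$b)
      pat <- inferPattern(rres, ref_seq, qry_seq, nm$a, qanchor, params)
      calls <- rbind(calls, data.frame(
        ref_start = nm$a, ref_end = nm$b, qry_start = qanchor,
        qry_end = qanchor - 1L, ambig_len = nm$ambig_len, pattern = pat,
        fwd_identity = 0, rev_identity = 0, ref_res = rres, qry_res = "",
        stringsAsFactors = FALSE))
    } else {
      # insertion of qry_seq[cc..d]; normalize leftmost over the query
      nm <- .normalize_indel(qry_seq, cc, d)
      shift <- cc - nm$a
      ranchor <- a - shift
      qres <- substr(qry_seq, nm$a, nm$b)
      pat <- inferPattern(qres, ref_seq, qry_seq, ranchor, nm$a, params)
      calls <- rbind(calls, data.frame(
        ref_start = ranchor, ref_end = ranchor - 1L, qry_start = nm$a,
        qry_end = nm$b, ambig_len = nm$ambig_len, pattern = pat,
        fwd_identity = 0, rev_identity = 0, ref_res = "", qry_res = qres,
        stringsAsFactors = FALSE))
    }
  }
  calls[order(calls$ref_start), , drop = FALSE]
}
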