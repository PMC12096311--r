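# Seeded genome-pair simulator: a reference with configurable repeat
# landscapes (tandem arrays, dispersed copies, inverted repeats, fold-back
# clusters), N-gap runs and AT-rich blocks; planted SVs with truth records
# whose canonical breakpoints and ambiguity intervals are derived by
# exhaustive equivalent-placement enumeration (independently of the
# resolver's shift logic); and simulated noisy caller VCFs.

#' Describe a repeat landscape element
#'
#' @param kind One of "tandem_array", "dispersed_copy", "inverted_repeat",
#'   "foldback_cluster", "multiseg_block" (a block of overlapping segments:
#'   sA + sB + the first half of sA, giving internal self-similarity).
#' @param unit_len Repeat-unit length in bp (>= 10; fold-back units are
#'   short, up to ~250 bp, mirroring dense fold-back clusters at reduced
#'   scale).
#' @param copy_count Number of copies (>= 2).
#' @param divergence Per-copy substitution rate in `[0, 0.2]`.
#' @param at Optional placement start(s) (1-based); random when NULL.
#' @return Named list.
#' @export
repeatSpec <- function(kind = c("tandem_array", "dispersed_copy",
                                "inverted_repeat", "foldback_cluster",
                                "multiseg_block"),
                       unit_len = 100L, copy_count = 3L, divergence = 0,
                       at = NULL) {
  kind <- match.arg(kind)
  stopifnot(unit_len >= 10L, copy_count >= 2L,
            divergence >= 0, divergence <= 0.2)
  list(kind = kind, unit_len = as.integer(unit_len),
       copy_count = as.integer(copy_count), divergence = divergence,
       at = at)
}

#' Generate a seeded reference genome
#'
#' I.i.d. background nucleotides at the given GC content; repeat specs
#' instantiated without unintended overlap (each construct replaces a
#' background slice, so coordinates are exact); N-gap runs and AT-rich
#' blocks placed on request.
#'
#' @param seed Integer seed fixing all randomness.
#' @param length Sequence length in bp (>= 10 kb recommended for pipeline
#'   tests).
#' @param gc Background GC fraction (default 0.36, a plant-like genome).
#' @param repeat_specs List of [repeatSpec()]s.
#' @param gap_spec Optional `data.frame(at, len)` of N runs.
#' @param at_rich_blocks Optional `data.frame(at, len)` (AT fraction 0.9).
#' @param name Sequence name (default "chr1").
#' @return A [Genome-class]; `metadata()` holds the instantiated repeat
#'   table (`repeats`: kind, start, end, unit_len, copy_count, unit).
#' @export
makeReference <- function(seed, length = 200000L, gc = 0.36,
                          repeat_specs = list(), gap_spec = NULL,
                          at_rich_blocks = NULL, name = "chr1") {
  set.seed(seed)
  length <- as.integer(length)
  s <- random_seq(length, gc)
  placed <- data.frame(kind = character(), start = integer(),
                       end = integer(), unit_len = integer(),
                       copy_count = integer(), unit = character(),
                       stringsAsFactors = FALSE)
  occupied <- NULL   # matrix of placed intervals, margin enforced
  margin <- 1000L
  reserve <- function(len, at) {
    if (!is.null(at)) {
      st <- as.integer(at)
    } else {
      for (try in 1:200) {
        st <- sample.int(length - len - margin, 1L) + margin %/% 2L
        free <- TRUE
        if (!is.null(occupied)) {
          free <- all(st > occupied[, 2] + margin |
                        st + len - 1L < occupied[, 1] - margin)
        }
        if (free) break
        st <- NA_integer_
      }
      if (is.na(st)) stopf("could not place a %d bp construct; increase length", len)
    }
    if (st < 1L || st + len - 1L > length) {
      stopf("construct [%d, %d] outside sequence (length %d)",
            st, st + len - 1L, length)
    }
    if (!is.null(occupied) &&
        any(st <= occupied[, 2] & st + len - 1L >= occupied[, 1])) {
      stopf("construct at %d overlaps an earlier placement", st)
    }
    occupied <<- rbind(occupied, c(st, st + len - 1L))
    st
  }
  for (sp in repeat_specs) {
    unit <- random_seq(sp$unit_len, gc)
    if (sp$kind == "tandem_array") {
      block <- paste(vapply(seq_len(sp$copy_count), function(i) {
        mutate_seq(unit, sp$divergence)
      }, character(1)), collapse = "")
      st <- reserve(nchar(block), sp$at)
      substr(s, st, st + nchar(block) - 1L) <- block
      placed <- rbind(placed, data.frame(
        kind = sp$kind, start = st, end = st + nchar(block) - 1L,
        unit_len = sp$unit_len, copy_count = sp$copy_count, unit = unit))
    } else if (sp$kind == "dispersed_copy") {
      ats <- sp$at
      for (i in seq_len(sp$copy_count)) {
        cp <- mutate_seq(unit, sp$divergence * (i - 1L))
        st <- reserve(nchar(cp), if (is.null(ats)) NULL else ats[i])
        substr(s, st, st + nchar(cp) - 1L) <- cp
        placed <- rbind(placed, data.frame(
          kind = sp$kind, start = st, end = st + nchar(cp) - 1L,
          unit_len = sp$unit_len, copy_count = sp$copy_count, unit = unit))
      }
    } else if (sp$kind == "inverted_repeat") {
      spacer <- random_seq(200L, gc)
      block <- paste0(unit, spacer, revcomp(mutate_seq(unit, sp$divergence)))
      st <- reserve(nchar(block), sp$at)
      substr(s, st, st + nchar(block) - 1L) <- block
      placed <- rbind(placed, data.frame(
        kind = sp$kind, start = st, end = st + nchar(block) - 1L,
        unit_len = sp$unit_len, copy_count = 2L, unit = unit))
    } else if (sp$kind == "multiseg_block") {
      sA <- unit
      sB <- random_seq(as.integer(0.75 * sp$unit_len), gc)
      block <- paste0(sA, sB, substr(sA, 1L, sp$unit_len %/% 2L))
      st <- reserve(nchar(block), sp$at)
      substr(s, st, st + nchar(block) - 1L) <- block
      placed <- rbind(placed, data.frame(
        kind = sp$kind, start = st, end = st + nchar(block) - 1L,
        unit_len = sp$unit_len, copy_count = sp$copy_count, unit = unit))
    } else {  # foldback_cluster: independent short inverted pairs
      pieces <- character(0)
      for (i in seq_len(sp$copy_count)) {
        u <- random_seq(sp$unit_len, gc)
        pieces <- c(pieces, u, random_seq(sample(160:240, 1L), gc),
                    revcomp(mutate_seq(u, sp$divergence)),
                    random_seq(sample(160:240, 1L), gc))
      }
      block <- paste(pieces, collapse = "")
      st <- reserve(nchar(block), sp$at)
      substr(s, st, st + nchar(block) - 1L) <- block
      placed <- rbind(placed, data.frame(
        kind = sp$kind, start = st, end = st + nchar(block) - 1L,
        unit_len = sp$unit_len, copy_count = sp$copy_count, unit = unit))
    }
  }
  if (!is.null(at_rich_blocks)) {
    for (i in seq_len(nrow(at_rich_blocks))) {
      st <- at_rich_blocks$at[i]; ln <- at_rich_blocks$len[i]
      substr(s, st, st + ln - 1L) <- random_seq(ln, gc = 0.1)
    }
  }
  if (!is.null(gap_spec)) {
    for (i in seq_len(nrow(gap_spec))) {
      st <- gap_spec$at[i]; ln <- gap_spec$len[i]
      substr(s, st, st + ln - 1L) <- strrep("N", ln)
    }
  }
  Genome(setNames(s, name),
         metadata = list(seed = seed, gc = gc, repeats = placed,
                         gap_spec = gap_spec))
}

# Exhaustively enumerate equivalent placements of a deletion of
# x[a..a+d-1] within [lo, hi]; returns c(leftmost, rightmost) starts.
# Placements are equivalent iff removing the d bases there yields the same
# string; checked by direct subsequence comparison.
#' @noRd
.enum_del_placements <- function(x, a, d, lo, hi) {
  v <- utf8ToInt(x)
  n <- length(v)
  valid <- a
  p <- a - 1L
  while (p >= max(1L, lo)) {
    # removal at p equals removal at a iff x[p..a-1] == x[p+d..a+d-1]
    if (all(v[p:(a - 1L)] == v[(p + d):(a + d - 1L)])) {
      valid <- c(valid, p)
      p <- p - 1L
    } else break
  }
  p <- a + 1L
  while (p + d - 1L <= min(n, hi + d - 1L) && p <= hi) {
    if (all(v[a:(p - 1L)] == v[(a + d):(p + d - 1L)])) {
      valid <- c(valid, p)
      p <- p + 1L
    } else break
  }
  c(min(valid), max(valid))
}

#' Plant SVs into a reference and derive exact truth records
#'
#' Supported plant types: unique-context `ins`/`del`/`inv`/`sub`;
#' `tandem_cn` (copy-number change of a tandem array from the reference's
#' repeat table); `copy_gain` (single-segment copy gained adjacent to a
#' reference segment, category cat1); `block_gain` (extra copy of a
#' multi-segment block, category cat2); `sub_recurrent` (heavily edited
#' segment, unalignable residuals).  Truth canonical breakpoints are
#' leftmost; ambiguity intervals come from exhaustive equivalent-placement
#' enumeration.  Overlapping plants (within 100 bp) are refused.
#'
#' Plant spec fields: `type`; `at` (ref position); `len`; `alt` (optional
#' explicit query-side sequence); `qry_len` (sub); `context` (row of the
#' repeat table for `tandem_cn`); `delta` (unit-count change); `pattern`
#' (optional explicit truth label).
#'
#' @param ref A [Genome-class] from [makeReference()].
#' @param specs List of plant-spec lists.
#' @param seed Integer seed.
#' @return `list(qry = Genome, truth = resolved-SV GRanges)`.
#' @export
plantSVs <- function(ref, specs, seed) {
  set.seed(seed)
  chrom <- names(seqs(ref))[1]
  s <- genomeSeq(ref, chrom)
  n <- nchar(s)
  gc <- metadata_field(ref, "gc", 0.36)
  reps <- metadata_field(ref, "repeats",
                         data.frame(kind = character(), start = integer()))

  edits <- NULL
  add_edit <- function(start, end, alt, svtype, pattern) {
    edits <<- rbind(edits, data.frame(
      start = as.integer(start), end = as.integer(end), alt = alt,
      svtype = svtype, pattern = pattern, stringsAsFactors = FALSE))
  }
  for (sp in specs) {
    ty <- sp$type
    if (ty == "ins") {
      alt <- sp$alt %||% random_seq(sp$len, gc)
      add_edit(sp$at + 1L, sp$at, alt, "INS", sp$pattern %||% "unique")
    } else if (ty == "del") {
      add_edit(sp$at, sp$at + sp$len - 1L, "", "DEL",
               sp$pattern %||% "unique")
    } else if (ty == "inv") {
      seg <- substr(s, sp$at, sp$at + sp$len - 1L)
      add_edit(sp$at, sp$at + sp$len - 1L, revcomp(seg), "INV",
               sp$pattern %||% "unique")
    } else if (ty == "sub") {
      alt <- sp$alt %||% random_seq(sp$qry_len, gc)
      add_edit(sp$at, sp$at + sp$len - 1L, alt, "SUB",
               sp$pattern %||% "unique")
    } else if (ty == "sub_recurrent") {
      seg <- substr(s, sp$at, sp$at + sp$len - 1L)
      # accumulated recurrent edits (dense substitutions plus small
      # indels): no window of the two sides stays alignable, so the
      # residuals remain unaligned end to end
      cs <- chars(seg)
      alt <- character(0)
      for (ch in cs) {
        u <- runif(1)
        if (u < 0.32) {                      # substitution
          alt <- c(alt, sample(setdiff(c("A", "C", "G", "T"), ch), 1L))
        } else if (u < 0.37) {               # deletion of this base
          next
        } else if (u < 0.41) {               # short insertion after it
          alt <- c(alt, ch, random_seq(sample(1:8, 1L), gc))
        } else {
          alt <- c(alt, ch)
        }
      }
      alt <- paste(alt, collapse = "")
      add_edit(sp$at, sp$at + sp$len - 1L, alt, "SUB",
               sp$pattern %||% "unique")
    } else if (ty == "tandem_cn") {
      ctx <- reps[sp$context, ]
      stopifnot(ctx$kind == "tandem_array")
      u <- ctx$unit_len
      if (sp$delta < 0L) {
        d <- -sp$delta * u
        add_edit(ctx$end - d + 1L, ctx$end, "", "DEL",
                 sp$pattern %||%
                   (if (ctx$copy_count + sp$delta >= 2L) "cat3" else "cat1"))
      } else {
        unit_str <- substr(s, ctx$end - u + 1L, ctx$end)
        add_edit(ctx$end + 1L, ctx$end, strrep(unit_str, sp$delta), "INS",
                 sp$pattern %||% "cat3")
      }
    } else if (ty == "copy_gain") {
      # duplicate the reference segment [at - len + 1, at] right after it
      seg <- substr(s, sp$at - sp$len + 1L, sp$at)
      add_edit(sp$at + 1L, sp$at, seg, "INS", sp$pattern %||% "cat1")
    } else if (ty == "block_gain") {
      seg <- substr(s, sp$at - sp$len + 1L, sp$at)
      add_edit(sp$at + 1L, sp$at, seg, "INS", sp$pattern %||% "cat2")
    } else stopf("unknown plant type '%s'", ty)
  }
  if (is.null(edits) || nrow(edits) == 0L) {
    return(list(qry = Genome(setNames(s, chrom)), truth = resolvedSV()))
  }
  edits <- edits[order(edits$start, edits$end), , drop = FALSE]
  # refuse overlapping plants (100 bp guard band)
  if (nrow(edits) > 1L) {
    conflicts <- which(edits$start[-1] - pmax(edits$end[-nrow(edits)],
                                              edits$start[-nrow(edits)]) <
                         100L)
    if (length(conflicts)) {
      stopf("overlapping plants at rows: %s",
            paste(conflicts, collapse = ", "))
    }
  }

  # build the query
  pieces <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(edits))) {
    pieces <- c(pieces, substr(s, cursor, edits$start[i] - 1L),
                edits$alt[i])
    cursor <- max(edits$end[i], edits$start[i] - 1L) + 1L
  }
  pieces <- c(pieces, substr(s, cursor, n))
  q <- paste(pieces, collapse = "")
  qchrom <- chrom

  # truth with canonical (leftmost) placement and exhaustive ambiguity
  rows <- NULL
  delta <- 0L
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    lo <- if (i > 1L) edits$end[i - 1L] + 2L else 1L
    hi <- if (i < nrow(edits)) edits$start[i + 1L] - 2L else n
    ref_len <- max(0L, e$end - e$start + 1L)
    alt_len <- nchar(e$alt)
    if (e$svtype == "DEL") {
      pl <- .enum_del_placements(s, e$start, ref_len, lo, hi)
      a <- pl[1]
      rows <- rbind(rows, data.frame(
        ref_start = a, ref_end = a + ref_len - 1L,
        qry_start = a + delta, qry_end = a + delta - 1L,
        svtype = "DEL", pattern = e$pattern,
        ambig_len = pl[2] - pl[1] + 1L, alt_seq = NA_character_))
    } else if (e$svtype == "INS") {
      # enumerate over the query: deleting the insert from q must give s
      qa <- e$start + delta          # first inserted base in q
      qlo <- lo + delta; qhi <- hi + delta
      pl <- .enum_del_placements(q, qa, alt_len, qlo, qhi)
      qa_L <- pl[1]
      a_L <- qa_L - delta            # back to ref coordinates
      rows <- rbind(rows, data.frame(
        ref_start = a_L, ref_end = a_L - 1L,
        qry_start = qa_L, qry_end = qa_L + alt_len - 1L,
        svtype = "INS", pattern = e$pattern,
        ambig_len = pl[2] - pl[1] + 1L,
        alt_seq = substr(q, qa_L, qa_L + alt_len - 1L)))
    } else {  # SUB or INV: unique placement; trim shared prefix/suffix
      seg <- substr(s, e$start, e$end)
      alt <- e$alt
      p0 <- 0L
      while (p0 < min(nchar(seg), nchar(alt)) &&
             substr(seg, p0 + 1L, p0 + 1L) == substr(alt, p0 + 1L, p0 + 1L)) {
        p0 <- p0 + 1L
      }
      s0 <- 0L
      while (s0 < min(nchar(seg), nchar(alt)) - p0 &&
             substr(seg, nchar(seg) - s0, nchar(seg) - s0) ==
               substr(alt, nchar(alt) - s0, nchar(alt) - s0)) {
        s0 <- s0 + 1L
      }
      alt_trim <- substr(alt, p0 + 1L, nchar(alt) - s0)
      rows <- rbind(rows, data.frame(
        ref_start = e$start + p0, ref_end = e$end - s0,
        qry_start = e$start + delta + p0,
        qry_end = e$start + delta + nchar(alt) - s0 - 1L,
        svtype = e$svtype, pattern = e$pattern, ambig_len = 1L,
        alt_seq = alt_trim))
    }
    delta <- delta + alt_len - ref_len
  }
  truth <- resolvedSV(chrom = rep(chrom, nrow(rows)),
                      ref_start = rows$ref_start, ref_end = rows$ref_end,
                      svtype = rows$svtype, qry_chrom = qchrom,
                      qry_start = rows$qry_start, qry_end = rows$qry_end,
                      pattern = rows$pattern, ambig_len = rows$ambig_len,
                      alt_seq = rows$alt_seq,
                      id = sprintf("truth_%02d", seq_len(nrow(rows))))
  list(qry = Genome(setNames(q, qchrom),
                    metadata = list(derived_from = chrom, seed = seed)),
       truth = truth)
}

#' @noRd
metadata_field <- function(g, field, default) {
  md <- g@metadata
  md[[field]] %||% default
}

#' Reconstruct the query genome from truth records
#'
#' Applies every truth SV (splice insertions, drop deletions, replace
#' substitutions/inversions) to the reference.  By construction of the
#' simulator this must reproduce the query byte-exactly; the reconstruction
#' identity is the simulator's core invariant.
#'
#' @param ref Reference [Genome-class].
#' @param truth Resolved-SV `GRanges`.
#' @return Named character vector of reconstructed sequences.
#' @export
applyTruth <- function(ref, truth) {
  out <- character(0)
  for (chrom in names(seqs(ref))) {
    s <- genomeSeq(ref, chrom)
    tr <- truth[as.character(seqnames(truth)) == chrom]
    tr <- tr[order(start(tr))]
    pieces <- character(0)
    cursor <- 1L
    for (i in seq_along(tr)) {
      st <- start(tr)[i]; en <- end(tr)[i]
      alt <- mcols(tr)$alt_seq[i]
      if (mcols(tr)$svtype[i] == "DEL") alt <- ""
      pieces <- c(pieces, substr(s, cursor, st - 1L), alt)
      cursor <- max(en, st - 1L) + 1L
    }
    pieces <- c(pieces, substr(s, cursor, nchar(s)))
    out[[chrom]] <- paste(pieces, collapse = "")
  }
  out
}

#' Simulate noisy caller call sets from truth
#'
#' Breakpoint jitter is Gaussian (rounded); false calls arrive at a Poisson
#' rate per Mb with random positions, lengths and types.  All records are
#' flagged PASS.
#'
#' @param truth Resolved-SV `GRanges`.
#' @param ref Reference [Genome-class].
#' @param seed Integer seed.
#' @param jitter_sd Breakpoint jitter standard deviation in bp (default 0).
#' @param fp_per_mb False-call rate per Mb (default 0).
#' @param callers Caller names (one call set each).
#' @return Named list of loci `GRanges`.
#' @export
simulateCalls <- function(truth, ref, seed, jitter_sd = 0,
                          fp_per_mb = 0, callers = c("simA", "simB")) {
  set.seed(seed)
  gsize <- sum(seqLengths(ref))
  out <- list()
  for (cal in callers) {
    chroms <- as.character(seqnames(truth))
    st <- start(truth); en <- end(truth)
    ty <- mcols(truth)$svtype
    ql <- mcols(truth)$qry_len
    svlen <- ifelse(ty == "INS", ql,
                    ifelse(ty == "SUB", pmax(width(truth), ql),
                           width(truth)))
    if (jitter_sd > 0) {
      j1 <- as.integer(round(rnorm(length(truth), 0, jitter_sd)))
      j2 <- as.integer(round(rnorm(length(truth), 0, jitter_sd)))
      st <- pmax(2L, st + j1)
      en <- ifelse(ty == "INS", st - 1L, pmax(st, en + j2))
    }
    chrom_v <- chroms; st_v <- st; en_v <- en; ty_v <- ty; len_v <- svlen
    nfp <- rpois(1L, fp_per_mb * gsize / 1e6)
    if (nfp > 0L) {
      for (k in seq_len(nfp)) {
        chromf <- sample(names(seqLengths(ref)), 1L)
        lenf <- sample(60:500, 1L)
        stf <- sample.int(seqLengths(ref)[[chromf]] - lenf - 100L, 1L) + 50L
        tyf <- sample(c("DEL", "INS"), 1L)
        chrom_v <- c(chrom_v, chromf)
        st_v <- c(st_v, if (tyf == "INS") stf + 1L else stf)
        en_v <- c(en_v, if (tyf == "INS") stf else stf + lenf - 1L)
        ty_v <- c(ty_v, tyf)
        len_v <- c(len_v, lenf)
      }
    }
    gr <- svLoci(chrom_v, st_v, en_v, caller = cal, svtype_raw = ty_v,
                 svlen = len_v, filter = "PASS")
    out[[cal]] <- gr[order(as.character(seqnames(gr)), start(gr))]
  }
  out
}

#' Write simulated loci as a symbolic-ALT caller VCF
#'
#' Generic-dialect conventions: for DEL/INV/SUB, POS is the first affected
#' base and INFO END the last; for INS, POS is the anchor base before the
#' insertion with INFO SVLEN.  Round-trips through
#' `readCallerVcf(dialect = "generic")`.
#'
#' @param loci Loci `GRanges` ([svLoci()]).
#' @param ref Reference [Genome-class] (contig header lines).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeLociVcf <- function(loci, ref, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svrefine-simulator",
           sprintf("##contig=<ID=%s,length=%d>", names(seqs(ref)),
                   width(seqs(ref))),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  mc <- mcols(loci)
  lines <- character(length(loci))
  for (i in seq_along(loci)) {
    ty <- mc$svtype_raw[i]
    chrom <- as.character(seqnames(loci)[i])
    if (ty == "INS") {
      pos <- start(loci)[i] - 1L
      info <- sprintf("SVTYPE=INS;SVLEN=%d", mc$svlen[i])
    } else {
      pos <- start(loci)[i]
      info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", ty, end(loci)[i],
                      mc$svlen[i])
    }
    lines[i] <- paste(chrom, pos, mc$id[i], "N", sprintf("<%s>", ty), ".",
                      mc$filter[i], info, sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
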