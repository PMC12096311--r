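# VCF ingestion and benchmark emission.
#
# Caller VCFs come in incompatible dialects: some put coordinates in INFO
# END/SVLEN with symbolic ALTs, some emit fully sequence-resolved REF/ALT
# pairs, and they disagree on whether POS is the padding base before the
# event or the first affected base.  Dialects are declared, not sniffed.

#' Registry of caller VCF dialects
#'
#' A dialect states where type/length/end live and whether POS includes the
#' conventional padding base.
#'
#' * `generic`: INFO `SVTYPE`/`END`/`SVLEN`, symbolic ALTs; for symbolic
#'   records POS is the first affected base (interval `[POS, END]`);
#'   sequence-resolved records use the padding-base convention.
#' * `seqres`: fully sequence-resolved REF/ALT with a leading padding base;
#'   type and length derived from allele lengths.
#' * `svrefine`: this package's own benchmark output; padding base always
#'   present, INFO carries `QRY_*`, `PATTERN`, `AMBIG`, `UAS_*`.
#'
#' @return Named list of dialect descriptors.
#' @export
vcfDialects <- function() {
  list(
    generic  = list(pos_padding_symbolic = FALSE, pos_padding_seq = TRUE),
    seqres   = list(pos_padding_symbolic = TRUE,  pos_padding_seq = TRUE),
    svrefine = list(pos_padding_symbolic = TRUE,  pos_padding_seq = TRUE)
  )
}

#' @noRd
.info_field <- function(info, key) {
  m <- regexpr(sprintf("(?:^|;)%s=([^;]*)", key), info, perl = TRUE)
  out <- rep(NA_character_, length(info))
  hit <- m != -1L
  txt <- substring(info[hit], m[hit],
                   m[hit] + attr(m, "match.length")[hit] - 1L)
  out[hit] <- sub(sprintf("^;?%s=", key), "", txt)
  out
}

#' Construct an SV-locus GRanges
#'
#' Loci are plain `GRanges` (1-based inclusive; insertions are zero-width
#' ranges anchored after the base `start - 1`) with metadata columns
#' `caller`, `svtype_raw`, `svlen`, `filter` and `alt_seq`.
#'
#' @param chrom,start,end Interval vectors (1-based inclusive; for an
#'   insertion after base p use `start = p + 1, end = p`).
#' @param caller Caller name (recycled).
#' @param svtype_raw Caller's raw type label.
#' @param svlen Absolute length in bp.
#' @param filter Semicolon-separated FILTER string ("" when the caller emits
#'   none).
#' @param alt_seq Inserted/substituted sequence or `NA`.
#' @return `GRanges`.
#' @export
svLoci <- function(chrom, start, end, caller = "caller", svtype_raw = "DEL",
                   svlen = abs(end - start + 1L), filter = "PASS",
                   alt_seq = NA_character_) {
  n <- length(start)
  gr <- GRanges(rep_len(chrom, n), IRanges(start = start, end = end))
  mcols(gr)$caller <- rep_len(caller, n)
  mcols(gr)$svtype_raw <- rep_len(svtype_raw, n)
  mcols(gr)$svlen <- rep_len(as.integer(svlen), n)
  mcols(gr)$filter <- rep_len(filter, n)
  mcols(gr)$alt_seq <- rep_len(alt_seq, n)
  mcols(gr)$id <- sprintf("%s_%d", mcols(gr)$caller, seq_len(n))
  gr
}

#' Read a caller VCF into SV loci
#'
#' Converts VCF positions to the internal 1-based inclusive convention,
#' resolves symbolic ALTs, keeps DUP as a raw label (reclassified later),
#' and drops records lacking usable coordinates (and unmated breakends) with
#' a logged count.
#'
#' @param path VCF file.
#' @param caller_name Name recorded on every locus.
#' @param dialect One of `names(vcfDialects())` or a dialect descriptor list.
#' @return `GRanges` of loci; `metadata()` holds `dropped` counts
#'   (`no_coords`, `unmated_bnd`) and `svlen_end_conflicts`.
#' @export
readCallerVcf <- function(path, caller_name = "caller", dialect = "generic") {
  if (is.character(dialect)) {
    reg <- vcfDialects()
    if (!dialect %in% names(reg)) {
      stopf("unknown VCF dialect '%s' (known: %s)", dialect,
            paste(names(reg), collapse = ", "))
    }
    dia <- reg[[dialect]]
  } else if (is.list(dialect)) {
    dia <- dialect
  } else stopf("dialect must be a name or a descriptor list")

  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  empty <- svLoci(character(), integer(), integer())[0]
  if (nrow(fx) == 0L) {
    metadata(empty) <- list(dropped = c(no_coords = 0L, unmated_bnd = 0L),
                            svlen_end_conflicts = 0L)
    return(empty)
  }
  pos <- suppressWarnings(as.integer(fx$POS))
  info <- fx$INFO %||% rep("", nrow(fx))
  info[is.na(info)] <- ""
  svtype <- .info_field(info, "SVTYPE")
  iend <- suppressWarnings(as.integer(.info_field(info, "END")))
  islen <- suppressWarnings(as.integer(.info_field(info, "SVLEN")))
  ref <- fx$REF; alt <- fx$ALT
  ids <- fx$ID

  is_bnd <- (!is.na(svtype) & svtype == "BND") |
    grepl("\\[|\\]", alt %||% "")
  mateid <- .info_field(info, "MATEID")
  unmated <- is_bnd & (is.na(mateid) | !(mateid %in% ids))
  n_unmated <- sum(unmated)

  keep_rows <- list()
  n_no_coord <- 0L
  n_conflict <- 0L
  for (i in seq_len(nrow(fx))) {
    if (is_bnd[i]) next  # translocations out of scope; unmated counted above
    if (is.na(pos[i])) { n_no_coord <- n_no_coord + 1L; next }
    symbolic <- grepl("^<", alt[i] %||% "")
    st <- if (!is.na(svtype[i])) svtype[i]
          else if (symbolic) gsub("[<>]", "", alt[i])
          else NA_character_
    if (symbolic || (!is.na(st) && is.na(alt[i]))) {
      # coordinates from INFO
      if (!is.na(st) && st == "INS") {
        ln <- abs(islen[i])
        if (is.na(ln)) { n_no_coord <- n_no_coord + 1L; next }
        keep_rows[[length(keep_rows) + 1L]] <- data.frame(
          chrom = fx$CHROM[i], start = pos[i] + 1L, end = pos[i],
          svtype_raw = st, svlen = ln, alt_seq = NA_character_,
          filter = fx$FILTER[i] %||% "", id = ids[i],
          stringsAsFactors = FALSE)
        next
      }
      if (is.na(iend[i])) { n_no_coord <- n_no_coord + 1L; next }
      s <- if (isTRUE(dia$pos_padding_symbolic)) pos[i] + 1L else pos[i]
      e <- iend[i]
      ln <- e - s + 1L
      if (!is.na(islen[i]) && abs(islen[i]) != ln) n_conflict <- n_conflict + 1L
      if (e < s) { n_no_coord <- n_no_coord + 1L; next }
      keep_rows[[length(keep_rows) + 1L]] <- data.frame(
        chrom = fx$CHROM[i], start = s, end = e,
        svtype_raw = st %||% "NA", svlen = ln, alt_seq = NA_character_,
        filter = fx$FILTER[i] %||% "", id = ids[i], stringsAsFactors = FALSE)
    } else {
      # sequence-resolved
      if (is.na(ref[i]) || is.na(alt[i])) { n_no_coord <- n_no_coord + 1L; next }
      rl <- nchar(ref[i]); al <- nchar(alt[i])
      if (rl == 1L && al > 1L) {            # insertion after POS
        keep_rows[[length(keep_rows) + 1L]] <- data.frame(
          chrom = fx$CHROM[i], start = pos[i] + 1L, end = pos[i],
          svtype_raw = if (!is.na(st)) st else "INS", svlen = al - 1L,
          alt_seq = substr(alt[i], 2L, al),
          filter = fx$FILTER[i] %||% "", id = ids[i], stringsAsFactors = FALSE)
      } else if (al == 1L && rl > 1L) {     # deletion of POS+1 .. POS+rl-1
        keep_rows[[length(keep_rows) + 1L]] <- data.frame(
          chrom = fx$CHROM[i], start = pos[i] + 1L, end = pos[i] + rl - 1L,
          svtype_raw = if (!is.na(st)) st else "DEL", svlen = rl - 1L,
          alt_seq = NA_character_,
          filter = fx$FILTER[i] %||% "", id = ids[i], stringsAsFactors = FALSE)
      } else if (rl > 1L && al > 1L) {      # substitution (padded)
        keep_rows[[length(keep_rows) + 1L]] <- data.frame(
          chrom = fx$CHROM[i], start = pos[i] + 1L, end = pos[i] + rl - 1L,
          svtype_raw = if (!is.na(st)) st else "SUB",
          svlen = max(rl - 1L, al - 1L),
          alt_seq = substr(alt[i], 2L, al),
          filter = fx$FILTER[i] %||% "", id = ids[i], stringsAsFactors = FALSE)
      } else {                              # SNV or empty: not an SV locus
        n_no_coord <- n_no_coord + 1L
      }
    }
  }
  dropped <- c(no_coords = n_no_coord, unmated_bnd = n_unmated)
  if (sum(dropped) > 0L) {
    message(sprintf("readCallerVcf(%s): dropped %d record(s) (%d no coords, %d unmated BND)",
                    basename(path), sum(dropped), n_no_coord, n_unmated))
  }
  if (length(keep_rows) == 0L) {
    metadata(empty) <- list(dropped = dropped, svlen_end_conflicts = n_conflict)
    return(empty)
  }
  df <- do.call(rbind, keep_rows)
  gr <- svLoci(df$chrom, df$start, df$end, caller = caller_name,
               svtype_raw = df$svtype_raw, svlen = df$svlen,
               filter = df$filter, alt_seq = df$alt_seq)
  mcols(gr)$id <- ifelse(is.na(df$id) | df$id == ".",
                         paste0(caller_name, "_", seq_along(gr)), df$id)
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  metadata(gr) <- list(dropped = dropped, svlen_end_conflicts = n_conflict)
  gr
}

#' Write resolved SVs as a benchmark VCF 4.2
#'
#' Records use the padding-base convention (POS is the base before the
#' event).  INFO carries `SVTYPE`, `SVLEN`, `END`, query-genome coordinates
#' (`QRY_CHROM`, `QRY_START`, `QRY_END`), the breakpoint-pattern category
#' (`PATTERN`), the ambiguity-interval length (`AMBIG`) and the flanking UAS
#' intervals (`UAS_UP`, `UAS_DOWN`).  Output round-trips through
#' [readCallerVcf()] with `dialect = "svrefine"`.
#'
#' @param svs Resolved-SV `GRanges` (see [resolvedSV()]).
#' @param ref Reference [Genome-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeBenchmarkVcf <- function(svs, ref, path) {
  stopifnot(is(ref, "Genome"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svrefine",
    sprintf("##contig=<ID=%s,length=%d>", names(seqs(ref)), width(seqs(ref))),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type (INS/DEL/INV/SUB)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of reference interval\">",
    "##INFO=<ID=QRY_CHROM,Number=1,Type=String,Description=\"Query sequence\">",
    "##INFO=<ID=QRY_START,Number=1,Type=Integer,Description=\"Query interval start (1-based)\">",
    "##INFO=<ID=QRY_END,Number=1,Type=Integer,Description=\"Query interval end (inclusive)\">",
    "##INFO=<ID=PATTERN,Number=1,Type=String,Description=\"Breakpoint pattern category\">",
    "##INFO=<ID=AMBIG,Number=1,Type=Integer,Description=\"Ambiguity interval length\">",
    "##INFO=<ID=UAS_UP,Number=1,Type=String,Description=\"Upstream UAS ref|qry interval\">",
    "##INFO=<ID=UAS_DOWN,Number=1,Type=String,Description=\"Downstream UAS ref|qry interval\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- character(length(svs))
  sl <- seqLengths(ref)
  mc <- mcols(svs)
  for (i in seq_along(svs)) {
    chrom <- as.character(seqnames(svs)[i])
    s <- start(svs)[i]; e <- end(svs)[i]
    svt <- mc$svtype[i]
    if (!chrom %in% names(sl) || max(s - 1L, 1L) < 1L || e > sl[[chrom]]) {
      stopf("record %s outside sequence bounds of '%s'",
            mc$id[i] %||% i, chrom)
    }
    alt_seq <- mc$alt_seq[i]
    if (svt == "INS") {
      p <- s - 1L                       # insertion after base p
      pad <- genomeSeq(ref, chrom, p, p)
      refA <- pad; altA <- paste0(pad, alt_seq)
      pos <- p; endv <- p; svlen <- nchar(alt_seq)
    } else if (svt == "DEL") {
      pos <- s - 1L
      pad <- genomeSeq(ref, chrom, pos, pos)
      refA <- paste0(pad, genomeSeq(ref, chrom, s, e)); altA <- pad
      endv <- e; svlen <- e - s + 1L
    } else if (svt == "SUB") {
      pos <- s - 1L
      pad <- genomeSeq(ref, chrom, pos, pos)
      refA <- paste0(pad, genomeSeq(ref, chrom, s, e))
      altA <- paste0(pad, alt_seq)
      endv <- e; svlen <- max(e - s + 1L, nchar(alt_seq))
    } else if (svt == "INV") {
      pos <- s - 1L
      refA <- genomeSeq(ref, chrom, pos, pos); altA <- "<INV>"
      endv <- e; svlen <- e - s + 1L
    } else stopf("record %s: unknown svtype '%s'", mc$id[i] %||% i, svt)
    if (pos < 1L) stopf("record %s outside sequence bounds", mc$id[i] %||% i)
    info <- sprintf(
      "SVTYPE=%s;SVLEN=%d;END=%d;QRY_CHROM=%s;QRY_START=%d;QRY_END=%d;PATTERN=%s;AMBIG=%d",
      svt, svlen, endv,
      mc$qry_chrom[i] %||% ".", mc$qry_start[i], mc$qry_end[i],
      mc$pattern[i] %||% "unique", mc$ambig_len[i] %||% 1L)
    if (!is.null(mc$uas_up) && !is.na(mc$uas_up[i])) {
      info <- paste0(info, ";UAS_UP=", mc$uas_up[i],
                     ";UAS_DOWN=", mc$uas_down[i])
    }
    lines[i] <- paste(chrom, pos, mc$id[i] %||% paste0("sv", i),
                      refA, altA, ".", "PASS", info, sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a benchmark VCF written by [writeBenchmarkVcf()]
#'
#' Restores the full resolved-SV `GRanges`, including query coordinates,
#' pattern category and ambiguity length.
#'
#' @param path VCF file.
#' @return Resolved-SV `GRanges`.
#' @export
readBenchmarkVcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fx) == 0L) return(resolvedSV())
  pos <- as.integer(fx$POS)
  info <- fx$INFO
  svt <- .info_field(info, "SVTYPE")
  endv <- as.integer(.info_field(info, "END"))
  qs <- as.integer(.info_field(info, "QRY_START"))
  qe <- as.integer(.info_field(info, "QRY_END"))
  qc <- .info_field(info, "QRY_CHROM")
  pat <- .info_field(info, "PATTERN")
  amb <- as.integer(.info_field(info, "AMBIG"))
  alt <- fx$ALT
  alt_seq <- rep(NA_character_, nrow(fx))
  s <- integer(nrow(fx)); e <- integer(nrow(fx))
  for (i in seq_len(nrow(fx))) {
    if (svt[i] == "INS") {
      s[i] <- pos[i] + 1L; e[i] <- pos[i]
      alt_seq[i] <- substr(alt[i], 2L, nchar(alt[i]))
    } else if (svt[i] == "DEL") {
      s[i] <- pos[i] + 1L; e[i] <- endv[i]
    } else if (svt[i] == "SUB") {
      s[i] <- pos[i] + 1L; e[i] <- endv[i]
      alt_seq[i] <- substr(alt[i], 2L, nchar(alt[i]))
    } else {  # INV
      s[i] <- pos[i] + 1L; e[i] <- endv[i]
    }
  }
  resolvedSV(chrom = fx$CHROM, ref_start = s, ref_end = e, svtype = svt,
             qry_chrom = qc, qry_start = qs, qry_end = qe,
             pattern = pat, ambig_len = amb, alt_seq = alt_seq,
             id = fx$ID)
}
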