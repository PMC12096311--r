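# PAF ingestion/export: lets users bring minimap2/MUMmer alignments in place
# of the internal aligner.  PAF intervals are 0-based half-open and are
# converted to the internal 1-based inclusive convention here.

#' Read a PAF file into alignment segments
#'
#' @param path PAF file (12+ columns).
#' @return Alignment-segment `data.frame` with columns `qname`, `qstart`,
#'   `qend`, `tname`, `tstart`, `tend`, `strand`, `matches`, `blocklen`,
#'   `identity` (1-based inclusive coordinates; `identity = matches /
#'   blocklen`).
#' @export
readPaf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0L) return(emptySegments())
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  if (!length(ln)) return(emptySegments())
  parts <- strsplit(ln, "\t", fixed = TRUE)
  ncols <- vapply(parts, length, integer(1))
  if (any(ncols < 12L)) {
    stopf("PAF parse error: line %d has %d columns (need >= 12)",
          which(ncols < 12L)[1], min(ncols))
  }
  m <- t(vapply(parts, function(p) p[1:12], character(12)))
  data.frame(
    qname = m[, 1],
    qstart = as.integer(m[, 3]) + 1L,
    qend = as.integer(m[, 4]),
    tname = m[, 6],
    tstart = as.integer(m[, 8]) + 1L,
    tend = as.integer(m[, 9]),
    strand = m[, 5],
    matches = as.numeric(m[, 10]),
    blocklen = as.numeric(m[, 11]),
    identity = as.numeric(m[, 10]) / as.numeric(m[, 11]),
    stringsAsFactors = FALSE)
}

#' Write alignment segments as PAF
#'
#' @param segments Alignment-segment `data.frame` (see [readPaf()]).
#' @param qlens,tlens Named integer vectors of sequence lengths.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writePaf <- function(segments, qlens, tlens, path) {
  rows <- vapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    paste(s$qname, qlens[[s$qname]], s$qstart - 1L, s$qend, s$strand,
          s$tname, tlens[[s$tname]], s$tstart - 1L, s$tend,
          round(s$matches), round(s$blocklen), 255L, sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' @noRd
emptySegments <- function() {
  data.frame(qname = character(), qstart = integer(), qend = integer(),
             tname = character(), tstart = integer(), tend = integer(),
             strand = character(), matches = numeric(), blocklen = numeric(),
             identity = numeric(), stringsAsFactors = FALSE)
}
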