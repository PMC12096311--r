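#' Read a FASTA file into a Genome
#'
#' Sequences are uppercased and runs of at least `gapMinN` consecutive 'N'
#' bases are recorded as assembly-gap runs.
#'
#' @param path FASTA file.
#' @param gapMinN Minimum N-run length that constitutes an assembly gap
#'   (default 10).
#' @return A [Genome-class].
#' @export
readGenome <- function(path, gapMinN = 10L) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0L) stopf("empty FASTA file: %s", path)
  ss <- tryCatch(readDNAStringSet(path),
                 error = function(e) stopf("malformed FASTA '%s': %s",
                                           path, conditionMessage(e)))
  if (length(ss) == 0L) stopf("no records in FASTA file: %s", path)
  # keep only the first whitespace-delimited token of each header
  names(ss) <- sub("\\s.*$", "", names(ss))
  Genome(ss, gapMinN = gapMinN, metadata = list(source = path))
}

#' Write a Genome to FASTA
#'
#' @param x A [Genome-class].
#' @param path Output file.
#' @param width Line width (default 70).
#' @return `path`, invisibly.
#' @export
writeGenome <- function(x, path, width = 70L) {
  stopifnot(is(x, "Genome"))
  writeXStringSet(x@seqs, filepath = path, width = width)
  invisible(path)
}
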