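# Genome annotation for breakpoint-context statistics: partition each
# annotated sequence into genic / regulatory / intergenic classes.
# Regulatory = fixed window upstream of the TSS (strand-aware), truncated at
# sequence bounds; overlaps resolved by precedence genic > regulatory >
# intergenic.

#' Read a gene annotation and build a genomic-class partition
#'
#' Accepts GFF3 (gene features; column 7 strand used to place the
#' regulatory window upstream of the TSS) or 4-column BED
#' (`chrom start end class`, 0-based half-open, classes among
#' genic/regulatory; remainder becomes intergenic).
#'
#' @param path GFF3 or BED file (extension decides).
#' @param seqlens Named integer vector of sequence lengths, or a
#'   [Genome-class].
#' @param regulatory_window Width in bp of the upstream regulatory window
#'   (default 3000; GFF input only).
#' @return An [AnnotationTrack-class].
#' @export
readAnnotation <- function(path, seqlens, regulatory_window = 3000L) {
  if (is(seqlens, "Genome")) seqlens <- seqLengths(seqlens)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3", "gtf")) {
    tb <- read.table(path, sep = "\t", comment.char = "#", quote = "",
                     stringsAsFactors = FALSE)
    tb <- tb[tb[[3]] == "gene", , drop = FALSE]
    genes <- data.frame(chrom = tb[[1]], start = as.integer(tb[[4]]),
                        end = as.integer(tb[[5]]), strand = tb[[7]],
                        stringsAsFactors = FALSE)
  } else if (ext == "bed") {
    tb <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(tb) < 4L) stopf("BED annotation needs 4 columns (class label)")
    cls <- tb[[4]]
    genes <- data.frame(chrom = tb[[1]], start = as.integer(tb[[2]]) + 1L,
                        end = as.integer(tb[[3]]),
                        strand = "+", class = cls, stringsAsFactors = FALSE)
    return(.build_track_from_classes(genes, seqlens))
  } else stopf("unsupported annotation format: .%s", ext)

  # GFF path: derive regulatory windows from TSS
  reg <- data.frame(chrom = genes$chrom,
                    start = ifelse(genes$strand == "-",
                                   genes$end + 1L,
                                   genes$start - regulatory_window),
                    end = ifelse(genes$strand == "-",
                                 genes$end + regulatory_window,
                                 genes$start - 1L),
                    stringsAsFactors = FALSE)
  reg$start <- pmax(reg$start, 1L)
  reg$end <- pmin(reg$end, seqlens[reg$chrom])
  reg <- reg[reg$end >= reg$start, , drop = FALSE]
  df <- data.frame(
    chrom = c(genes$chrom, reg$chrom),
    start = c(genes$start, reg$start),
    end = c(genes$end, reg$end),
    strand = rep("+", nrow(genes) + nrow(reg)),
    class = c(rep("genic", nrow(genes)), rep("regulatory", nrow(reg))),
    stringsAsFactors = FALSE)
  .build_track_from_classes(df, seqlens)
}

#' @noRd
.build_track_from_classes <- function(df, seqlens) {
  out <- GRanges()
  for (chrom in names(seqlens)) {
    L <- seqlens[[chrom]]
    genic <- reduce(IRanges(
      start = df$start[df$class == "genic" & df$chrom == chrom],
      end = df$end[df$class == "genic" & df$chrom == chrom]))
    reg <- reduce(IRanges(
      start = df$start[df$class == "regulatory" & df$chrom == chrom],
      end = df$end[df$class == "regulatory" & df$chrom == chrom]))
    full <- IRanges(1L, L)
    reg <- IRanges::setdiff(reg, genic)          # precedence genic > regulatory
    inter <- IRanges::setdiff(IRanges::setdiff(full, genic), reg)
    add <- function(ir, cls) {
      if (!length(ir)) return(GRanges())
      g <- GRanges(chrom, ir); mcols(g)$region_class <- cls; g
    }
    out <- c(out, add(genic, "genic"), add(reg, "regulatory"),
             add(inter, "intergenic"))
  }
  totals <- vapply(c("genic", "regulatory", "intergenic"), function(cl) {
    sum(width(out[mcols(out)$region_class == cl]))
  }, numeric(1))
  new("AnnotationTrack", intervals = out, totals = totals)
}

#' Build an AnnotationTrack directly from interval tables
#'
#' Convenience for simulations and tests: supply genic (and optionally
#' regulatory) intervals in 1-based inclusive coordinates.
#'
#' @param seqlens Named integer vector (or [Genome-class]).
#' @param genic,regulatory `data.frame`s with columns `chrom`, `start`,
#'   `end`.
#' @return An [AnnotationTrack-class].
#' @export
annotationTrack <- function(seqlens, genic,
                            regulatory = genic[0, , drop = FALSE]) {
  if (is(seqlens, "Genome")) seqlens <- seqLengths(seqlens)
  df <- data.frame(
    chrom = c(genic$chrom, regulatory$chrom),
    start = c(genic$start, regulatory$start),
    end = c(genic$end, regulatory$end),
    class = c(rep("genic", nrow(genic)), rep("regulatory", nrow(regulatory))),
    strand = rep("+", nrow(genic) + nrow(regulatory)),
    stringsAsFactors = FALSE)
  .build_track_from_classes(df, seqlens)
}
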