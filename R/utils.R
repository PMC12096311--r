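# Small shared helpers.  Sequences move around as plain uppercase character
# strings; Biostrings objects are built only where an alignment is computed.

#' @noRd
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(reverseComplement(DNAString(x)))
}

#' @noRd
substr_safe <- function(x, start, end) {
  if (end < start) return("")
  substr(x, max(1L, start), min(nchar(x), end))
}

# Split a string into single characters (fast path via raw bytes).
#' @noRd
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# 1-based closed interval overlap width
#' @noRd
ovl_width <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2) + 1L)

#' @noRd
reciprocal_overlap <- function(s1, e1, s2, e2) {
  w <- ovl_width(s1, e1, s2, e2)
  if (w == 0L) return(0)
  min(w / (e1 - s1 + 1), w / (e2 - s2 + 1))
}

# Random DNA string with a given GC fraction
#' @noRd
random_seq <- function(n, gc = 0.4) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Apply i.i.d. substitutions at the given rate (never to the same base)
#' @noRd
mutate_seq <- function(x, rate) {
  if (rate <= 0 || nchar(x) == 0L) return(x)
  cs <- chars(x)
  hit <- which(runif(length(cs)) < rate)
  for (i in hit) {
    cs[i] <- sample(setdiff(c("A", "C", "G", "T"), cs[i]), 1L)
  }
  paste(cs, collapse = "")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
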