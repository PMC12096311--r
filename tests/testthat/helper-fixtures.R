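# Shared fixtures, generated once per test run (helpers persist across
# test files within one test_dir process).

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

.fixture_env <- new.env(parent = emptyenv())

suite_fixtures <- function() {
  if (is.null(.fixture_env$suite)) {
    .fixture_env$suite <- scenarioSuite(42)
  }
  .fixture_env$suite
}

combined_curated <- function() {
  if (is.null(.fixture_env$cc)) {
    fx <- suite_fixtures()$combined
    .fixture_env$cc <- curate(fx$ref, fx$qry, fx$calls)
  }
  .fixture_env$cc
}

# deterministic random DNA for local constructions
rand_dna <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
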