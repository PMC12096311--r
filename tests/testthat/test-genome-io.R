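test_that("Genome records N-gap runs and normalizes case", {
  g <- Genome(c(c1 = "ACGT"))
  expect_length(gapRuns(g), 0)
  expect_equal(genomeSeq(g, "c1"), "ACGT")

  g <- Genome(c(c1 = paste0("AC", strrep("N", 12), "GT")))
  expect_equal(start(gapRuns(g)), 3)
  expect_equal(end(gapRuns(g)), 14)
  expect_true(hasGap(g, "c1", 10, 20))
  expect_false(hasGap(g, "c1", 15, 16))

  # below the gap_min_n threshold no run is recorded
  g <- Genome(c(c1 = paste0("AC", strrep("N", 9), "GT")))
  expect_length(gapRuns(g), 0)

  g <- Genome(c(c1 = "acgt"))
  expect_equal(genomeSeq(g, "c1"), "ACGT")
})

test_that("FASTA round-trips and readGenome rejects bad input", {
  tmp <- tempfile(fileext = ".fa")
  set.seed(11)
  g <- Genome(c(chrA = rand_dna(500), chrB = paste0(rand_dna(100),
                                                    strrep("N", 20),
                                                    rand_dna(80))))
  writeGenome(g, tmp)
  g2 <- readGenome(tmp)
  expect_equal(names(seqs(g2)), c("chrA", "chrB"))
  expect_equal(genomeSeq(g2, "chrA"), genomeSeq(g, "chrA"))
  expect_equal(start(gapRuns(g2)), 101)

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(readGenome(empty), "empty")
  expect_error(readGenome(tempfile()), "not found")
})

test_that("PAF reading computes identity and maps strands", {
  tmp <- tempfile(fileext = ".paf")
  writeLines(c(
    paste("q1", 1000, 0, 1000, "+", "t1", 2000, 100, 1100, 900, 1000, 60,
          sep = "\t"),
    paste("q2", 500, 10, 400, "-", "t1", 2000, 500, 890, 350, 390, 60,
          sep = "\t")), tmp)
  segs <- readPaf(tmp)
  expect_equal(segs$identity[1], 0.90)
  expect_equal(segs$qstart[1], 1)          # 0-based half-open -> 1-based
  expect_equal(segs$tstart[1], 101)
  expect_equal(segs$strand[2], "-")

  # empty file -> empty list
  empty <- tempfile(fileext = ".paf")
  file.create(empty)
  expect_equal(nrow(readPaf(empty)), 0)

  bad <- tempfile(fileext = ".paf")
  writeLines("q1\t100\t0\t50", bad)
  expect_error(readPaf(bad), "12")

  # write-then-read round trip
  out <- tempfile(fileext = ".paf")
  writePaf(segs, c(q1 = 1000L, q2 = 500L), c(t1 = 2000L), out)
  segs2 <- readPaf(out)
  expect_equal(segs2$qstart, segs$qstart)
  expect_equal(segs2$tend, segs$tend)
  expect_equal(segs2$identity, segs$identity, tolerance = 1e-9)
})

test_that("annotation partition arithmetic and precedence", {
  # one 1-kb gene on a 10-kb chromosome, 3-kb regulatory window
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "src", "gene", 5001, 6000, ".", "+", ".",
                     "ID=g1", sep = "\t")), gff)
  tr <- readAnnotation(gff, c(chr1 = 10000L))
  expect_equal(unname(classTotals(tr)[c("genic", "regulatory",
                                        "intergenic")]),
               c(1000, 3000, 6000))

  # gene at chromosome start: regulatory window truncated at 1
  gff2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "src", "gene", 1, 1000, ".", "+", ".",
                     "ID=g1", sep = "\t")), gff2)
  tr2 <- readAnnotation(gff2, c(chr1 = 10000L))
  expect_equal(unname(classTotals(tr2)[["regulatory"]]), 0)
  expect_equal(unname(classTotals(tr2)[["genic"]]), 1000)

  # two overlapping genes: genic bp counted once (interval-union oracle)
  gff3 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "src", "gene", 5001, 6000, ".", "+", ".",
                     "ID=g1", sep = "\t"),
               paste("chr1", "src", "gene", 5500, 6500, ".", "+", ".",
                     "ID=g2", sep = "\t")), gff3)
  tr3 <- readAnnotation(gff3, c(chr1 = 10000L))
  union_bp <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(c(5001, 5500), c(6000, 6500)))))
  expect_equal(unname(classTotals(tr3)[["genic"]]), union_bp)
  # classes still partition the chromosome
  expect_equal(sum(classTotals(tr3)), 10000)
})
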