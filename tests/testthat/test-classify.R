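test_that("residual material maps to the four types", {
  expect_equal(classifySV("", "ACGTACGT"), "INS")
  expect_equal(classifySV("ACGTACGT", ""), "DEL")
  expect_equal(classifySV("ACG", strrep("T", 504), fwd_identity = 0.01),
               "SUB")
  expect_equal(classifySV("ACGTT", "ACGTA", fwd_identity = 0.9),
               "decompose")
  expect_equal(classifySV("", ""), "none")
  # inversion takes precedence when sides are equal and criteria passed
  expect_equal(classifySV("ACGTACGT", "ACGTACGT", fwd_identity = 0.2,
                          rev_identity = 0.99, inv_ok = TRUE), "INV")
})

test_that("the three inversion criteria accept and reject correctly", {
  fx <- suite_fixtures()

  # planted clean inversion with unique flanks: all criteria pass
  f <- fx$unique_inv
  tr <- f$truth
  ok <- checkInversion(
    list(chrom = "chr1", start = start(tr)[1], end = end(tr)[1]),
    list(chrom = "chr1", start = mcols(tr)$qry_start[1],
         end = mcols(tr)$qry_end[1]),
    f$ref, f$qry)
  expect_true(as.logical(ok))

  # an N-gap run inside the interval vetoes the call (criterion 3)
  f2 <- fx$inv_gap_fail
  tr2 <- f2$truth
  ok2 <- checkInversion(
    list(chrom = "chr1", start = start(tr2)[1], end = end(tr2)[1]),
    list(chrom = "chr1", start = mcols(tr2)$qry_start[1],
         end = mcols(tr2)$qry_end[1]),
    f2$ref, f2$qry)
  expect_false(as.logical(ok2))
  expect_equal(unname(attr(ok2, "detail")[["gap"]]), 1)

  # a better forward alternative beats the reverse match (criterion 2)
  f3 <- fx$inv_reject_fwd
  reg <- f3$region
  ok3 <- checkInversion(
    list(chrom = "chr1", start = start(reg), end = end(reg)),
    list(chrom = "chr1", start = start(reg), end = end(reg)),
    f3$ref, f3$qry)
  expect_false(as.logical(ok3))
  d <- attr(ok3, "detail")
  expect_gt(d[["fwd"]], d[["rev"]])
})

test_that("gap-spanning and forward-dominated candidates emit no INV", {
  fx <- suite_fixtures()
  for (nm in c("inv_gap_fail", "inv_reject_fwd")) {
    f <- fx[[nm]]
    res <- curate(f$ref, f$qry, f$calls)
    expect_equal(sum(mcols(res$benchmark)$svtype == "INV"), 0, label = nm)
  }
})

test_that("resolved-SV type invariants validate", {
  ok <- resolvedSV(chrom = "chr1", ref_start = 100L, ref_end = 199L,
                   svtype = "DEL", qry_chrom = "chr1", qry_start = 100L,
                   qry_end = 99L)
  expect_true(isTRUE(validateResolvedSV(ok)))
  bad <- resolvedSV(chrom = "chr1", ref_start = 100L, ref_end = 120L,
                    svtype = "DEL", qry_chrom = "chr1", qry_start = 100L,
                    qry_end = 99L)          # only 21 bp
  expect_false(isTRUE(validateResolvedSV(bad)))
  inv <- resolvedSV(chrom = "chr1", ref_start = 100L, ref_end = 400L,
                    svtype = "INV", qry_chrom = "chr1", qry_start = 100L,
                    qry_end = 399L)         # unequal sides
  expect_false(isTRUE(validateResolvedSV(inv)))
})

test_that("swapping reference and query exchanges INS and DEL", {
  fx <- suite_fixtures()
  f <- fx$unique_del
  fwd <- curate(f$ref, f$qry, f$calls)
  # swapped comparison: the deletion becomes an insertion
  calls_sw <- svLoci("chr1", mcols(f$truth)$qry_start[1],
                     mcols(f$truth)$qry_start[1] - 1L,
                     svtype_raw = "INS", svlen = width(f$truth)[1])
  sw <- curate(f$qry, f$ref, list(calls_sw))
  expect_equal(mcols(fwd$benchmark)$svtype, "DEL")
  expect_equal(mcols(sw$benchmark)$svtype, "INS")
  expect_equal(mcols(sw$benchmark)$qry_len, mcols(fwd$benchmark)$ref_len)

  # SUB stays SUB with the side lengths exchanged
  f2 <- fx$unique_sub
  fwd2 <- curate(f2$ref, f2$qry, f2$calls)
  calls_sw2 <- svLoci("chr1", mcols(f2$truth)$qry_start[1],
                      mcols(f2$truth)$qry_end[1],
                      svtype_raw = "SUB",
                      svlen = mcols(f2$truth)$qry_len[1])
  sw2 <- curate(f2$qry, f2$ref, list(calls_sw2))
  expect_equal(mcols(sw2$benchmark)$svtype, "SUB")
  expect_equal(mcols(sw2$benchmark)$ref_len, mcols(fwd2$benchmark)$qry_len)
  expect_equal(mcols(sw2$benchmark)$qry_len, mcols(fwd2$benchmark)$ref_len)
})

test_that("benchmark emission counts types and attaches flanking UAS", {
  cc <- combined_curated()
  fx <- suite_fixtures()$combined
  em <- emitBenchmark(cc$benchmark, fx$ref, fx$qry)
  tc <- em$type_counts
  expect_equal(unname(tc[["total"]]),
               unname(tc[["INS"]] + tc[["DEL"]] + tc[["INV"]] +
                        tc[["SUB"]]))
  expect_true(all(nchar(mcols(em$records)$uas_seq_up) == 500))
  expect_equal(sum(em$pattern_counts), unname(tc[["total"]]))
  # empty input still writes a full-header VCF
  tmp <- tempfile(fileext = ".vcf")
  em0 <- emitBenchmark(resolvedSV(), fx$ref, fx$qry, path = tmp)
  expect_equal(unname(em0$type_counts[["total"]]), 0)
  expect_true(any(grepl("^#CHROM", readLines(tmp))))
})
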