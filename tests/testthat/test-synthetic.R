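test_that("reference generation is deterministic and honors GC", {
  g1 <- makeReference(7, 50000L)
  g2 <- makeReference(7, 50000L)
  expect_identical(genomeSeq(g1, "chr1"), genomeSeq(g2, "chr1"))

  g3 <- makeReference(8, 100000L, gc = 0.4)
  f <- Biostrings::letterFrequency(seqs(g3), c("G", "C"))
  gc_obs <- sum(f) / 100000
  expect_lt(abs(gc_obs - 0.4), 3 * sqrt(0.4 * 0.6 / 100000))

  # a planted perfect tandem array closes the loop with the detector
  g4 <- makeReference(9, 30000L, repeat_specs = list(
    repeatSpec("tandem_array", unit_len = 100L, copy_count = 5L,
               at = 10000L)))
  span <- genomeSeq(g4, "chr1", 10000, 10499)
  tu <- detectTandemUnit(span)
  expect_equal(tu, list(unit_len = 100L, copy_count = 5L))

  # an oversized construct is refused
  expect_error(makeReference(10, 5000L, repeat_specs = list(
    repeatSpec("tandem_array", unit_len = 1000L, copy_count = 10L,
               at = 1000L))), "outside|place")
})

test_that("planted SVs carry exhaustively enumerated ambiguity", {
  # engineered boundaries so the unique-context deletion has ambiguity 1
  set.seed(81)
  left <- paste0(rand_dna(4999), "C")
  mid <- paste0("A", rand_dna(148), "G")
  right <- paste0("T", rand_dna(4999))
  ref <- Genome(c(chr1 = paste0(left, mid, right)))
  pl <- plantSVs(ref, list(list(type = "del", at = 5001L, len = 150L)), 82)
  expect_equal(mcols(pl$truth)$ambig_len, 1L)
  expect_equal(start(pl$truth), 5001L)

  # removing 2 units from a perfect 5 x 100 bp array: DEL 200, ambiguity 301
  unit <- paste0("A", rand_dna(98), "G")
  arr <- strrep(unit, 5)
  ref2 <- Genome(c(chr1 = paste0(left, arr, right)))
  md <- list(seed = 0, gc = 0.4,
             repeats = data.frame(kind = "tandem_array", start = 5001L,
                                  end = 5500L, unit_len = 100L,
                                  copy_count = 5L, unit = unit))
  ref2@metadata <- md
  pl2 <- plantSVs(ref2, list(list(type = "tandem_cn", context = 1L,
                                  delta = -2L)), 83)
  expect_equal(mcols(pl2$truth)$svtype, "DEL")
  expect_equal(width(pl2$truth), 200L)
  expect_equal(mcols(pl2$truth)$ambig_len, 301L)
  expect_equal(start(pl2$truth), 5001L)          # canonical leftmost
  # the fully exhaustive reconstruction oracle agrees
  plc <- oracle_del_placements(genomeSeq(ref2, "chr1"), 5001L, 200L)
  expect_equal(range(plc), c(5001L, 5301L))

  # the 3 bp / 504 bp substitution worked case reconstructs
  ref3 <- makeReference(84, 20000L)
  pl3 <- plantSVs(ref3, list(list(type = "sub", at = 10000L, len = 3L,
                                  qry_len = 504L)), 85)
  expect_equal(applyTruth(ref3, pl3$truth)[["chr1"]],
               genomeSeq(pl3$qry, "chr1"))
  expect_lte(width(pl3$truth), 3L)      # shared edge bases trimmed off
  expect_gte(mcols(pl3$truth)$qry_len, 502L)
})

test_that("overlapping plants are refused with the conflict rows", {
  ref <- makeReference(86, 20000L)
  expect_error(plantSVs(ref, list(
    list(type = "del", at = 10000L, len = 150L),
    list(type = "del", at = 10050L, len = 150L)), 87), "overlap")
})

test_that("reconstruction holds for every generated fixture", {
  fx <- suite_fixtures()
  for (nm in names(fx)) {
    f <- fx[[nm]]
    if (length(f$truth) == 0) next
    expect_identical(applyTruth(f$ref, f$truth)[["chr1"]],
                     genomeSeq(f$qry, "chr1"), label = nm)
  }
})

test_that("identical seeds give identical fixtures", {
  a <- scenarioSuite(123)
  b <- scenarioSuite(123)
  expect_identical(genomeSeq(a$combined$ref, "chr1"),
                   genomeSeq(b$combined$ref, "chr1"))
  expect_identical(as.data.frame(a$combined$truth),
                   as.data.frame(b$combined$truth))
  expect_identical(start(a$combined$calls[[1]]),
                   start(b$combined$calls[[1]]))
})

test_that("caller simulation jitters breakpoints and adds false calls", {
  fx <- suite_fixtures()$combined
  set.seed(88)
  calls <- simulateCalls(fx$truth, fx$ref, 89, jitter_sd = 20,
                         fp_per_mb = 25)
  c1 <- calls[[1]]
  expect_gt(length(c1), length(fx$truth))     # spurious calls present
  # jitter moved most non-FP breakpoints
  n <- length(fx$truth)
  expect_gt(sum(start(c1)[seq_len(n)] != start(fx$truth)), n / 2)
})

test_that("fixtures write as plain-text files and read back", {
  dir <- tempfile()
  suite <- scenarioSuite(31, dir = dir)
  d <- file.path(dir, "unique_del")
  expect_true(file.exists(file.path(d, "ref.fa")))
  ref <- readGenome(file.path(d, "ref.fa"))
  expect_identical(genomeSeq(ref, "chr1"),
                   genomeSeq(suite$unique_del$ref, "chr1"))
  truth <- readBenchmarkVcf(file.path(d, "truth.vcf"))
  expect_equal(start(truth), start(suite$unique_del$truth))
  calls <- readCallerVcf(file.path(d, "calls_simA.vcf"), "simA")
  expect_equal(length(calls), length(suite$unique_del$calls$simA))
})
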