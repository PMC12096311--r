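test_that("matching presets carry the published parameter sets", {
  s <- matchParams("strict")
  expect_equal(s[c("refdist", "pctsize", "pctovl", "pctseq", "sizemin",
                   "sizemax")],
               list(refdist = 0L, pctsize = 1, pctovl = 1, pctseq = 0,
                    sizemin = 1L, sizemax = 30000000L))
  r <- matchParams("relaxed")
  expect_equal(r[c("refdist", "pctsize", "pctovl")],
               list(refdist = 50L, pctsize = 0.9, pctovl = 0.9))
  r1k <- matchParams("relaxed1k")
  expect_equal(r1k$refdist, 1000L)
})

test_that("matching handles identity, shifts and hand-computed metrics", {
  truth <- resolvedSV(chrom = "chr1",
                      ref_start = c(1000L, 5000L, 9000L),
                      ref_end = c(1199L, 5299L, 8999L),
                      svtype = c("DEL", "DEL", "INS"),
                      qry_chrom = "chr1",
                      qry_start = c(1000L, 5000L, 9000L),
                      qry_end = c(999L, 4999L, 9149L))
  # calls == truth: perfect under strict
  ev <- matchCalls(truth, truth, matchParams("strict"))
  expect_equal(unname(metrics(ev)[c("precision", "recall", "f1")]),
               c(1, 1, 1))

  # +10 bp shift: no strict match, relaxed match
  shifted <- GenomicRanges::shift(truth[1], 10L)
  expect_equal(matchCalls(shifted, truth[1], matchParams("strict"))@tp, 0L)
  expect_equal(matchCalls(shifted, truth[1], matchParams("relaxed"))@tp, 1L)

  # constructed tp=2 fp=1 fn=3: P=2/3, R=2/5, F1=0.5
  truth5 <- resolvedSV(chrom = "chr1",
                       ref_start = c(1000L, 3000L, 5000L, 7000L, 9000L),
                       ref_end = c(1199L, 3199L, 5199L, 7199L, 9199L),
                       svtype = "DEL", qry_chrom = "chr1",
                       qry_start = 1L, qry_end = 0L)
  calls3 <- resolvedSV(chrom = "chr1",
                       ref_start = c(1000L, 3000L, 20000L),
                       ref_end = c(1199L, 3199L, 20199L),
                       svtype = "DEL", qry_chrom = "chr1",
                       qry_start = 1L, qry_end = 0L)
  ev3 <- matchCalls(calls3, truth5, matchParams("strict"))
  expect_equal(ev3@tp, 2L); expect_equal(ev3@fp, 1L)
  expect_equal(ev3@fn, 3L)
  expect_equal(ev3@precision, 2 / 3)
  expect_equal(ev3@recall, 2 / 5)
  expect_equal(ev3@f1, 0.5)
  # harmonic-mean identity
  expect_equal(ev3@f1, 2 * ev3@precision * ev3@recall /
                 (ev3@precision + ev3@recall))
})

test_that("one-to-one matching equals the exhaustive oracle", {
  set.seed(71)
  for (rep in 1:6) {
    nt <- sample(4:10, 1); nc <- sample(4:10, 1)
    ts <- sort(sample.int(50000L, nt))
    truth <- resolvedSV(chrom = "chr1", ref_start = ts, ref_end = ts + 150L,
                        svtype = sample(c("DEL", "INS", "SUB"), nt, TRUE),
                        qry_chrom = "chr1", qry_start = ts,
                        qry_end = ts + 150L)
    cs <- sort(sample.int(50000L, nc))
    # half the calls are jittered copies of truths, half random
    take <- sample(nt, min(nc, nt) %/% 2)
    cs[seq_along(take)] <- ts[take] + sample(-60:60, length(take), TRUE)
    calls <- resolvedSV(chrom = "chr1", ref_start = cs, ref_end = cs + 150L,
                        svtype = sample(c("DEL", "INS", "SUB"), nc, TRUE),
                        qry_chrom = "chr1", qry_start = cs,
                        qry_end = cs + 150L)
    for (preset in c("strict", "relaxed", "relaxed1k")) {
      p <- matchParams(preset)
      ev <- matchCalls(calls, truth, p)
      expect_equal(ev@tp, oracle_match_tp(calls, truth, p),
                   label = preset)
    }
  }
})

test_that("every strict match pair is also a relaxed match pair", {
  set.seed(72)
  for (rep in 1:4) {
    n <- 12
    ts <- sort(sample.int(80000L, n))
    truth <- resolvedSV(chrom = "chr1", ref_start = ts, ref_end = ts + 200L,
                        svtype = "DEL", qry_chrom = "chr1",
                        qry_start = ts, qry_end = ts - 1L)
    cs <- ts + sample(c(0L, 0L, 10L, 100L), n, TRUE)
    calls <- resolvedSV(chrom = "chr1", ref_start = cs, ref_end = cs + 200L,
                        svtype = "DEL", qry_chrom = "chr1",
                        qry_start = cs, qry_end = cs - 1L)
    evs <- matchCalls(calls, truth, matchParams("strict"))
    evr <- matchCalls(calls, truth, matchParams("relaxed"))
    ks <- with(matchPairs(evs), paste(call, truth))
    kr <- with(matchPairs(evr), paste(call, truth))
    expect_true(all(ks %in% kr))
    # permuting the input changes nothing
    perm <- sample(n)
    evp <- matchCalls(calls[perm], truth, matchParams("strict"))
    expect_equal(evp@tp, evs@tp)
  }
})

test_that("SUB records cross-match INS/DEL truth on the allele side", {
  truth <- resolvedSV(chrom = "chr1", ref_start = 1000L, ref_end = 999L,
                      svtype = "INS", qry_chrom = "chr1",
                      qry_start = 1000L, qry_end = 1503L)   # 504-bp INS
  sub <- resolvedSV(chrom = "chr1", ref_start = 1000L, ref_end = 1002L,
                    svtype = "SUB", qry_chrom = "chr1",
                    qry_start = 1000L, qry_end = 1503L)     # 3 vs 504
  expect_equal(matchCalls(sub, truth, matchParams("relaxed"))@tp, 1L)
  expect_equal(matchCalls(sub, truth, matchParams("relaxed"),
                          sub_strict = TRUE)@tp, 0L)
})

test_that("relative rates recover hand-computed and null values", {
  # 10-kb genome: genic 1 kb, regulatory 3 kb, intergenic 6 kb;
  # breakpoints {2, 6, 2} -> rates {2.0, 2.0, 1/3}
  tr <- annotationTrack(c(chr1 = 10000L),
                        genic = data.frame(chrom = "chr1", start = 4001L,
                                           end = 5000L),
                        regulatory = data.frame(chrom = "chr1",
                                                start = 1001L, end = 4000L))
  bp <- c(4100L, 4500L,                       # genic (2)
          1100L, 1500L, 2000L, 2500L, 3000L, 3500L,   # regulatory (6)
          6000L, 9000L)                       # intergenic (2)
  svs <- resolvedSV(chrom = "chr1", ref_start = bp, ref_end = bp + 99L,
                    svtype = "DEL", qry_chrom = "chr1", qry_start = bp,
                    qry_end = bp - 1L)
  rates <- relativeRate(svs, tr)
  expect_equal(as.numeric(rates), c(2.0, 2.0, 1 / 3))

  # uniform null: all rates ~ 1 within 3 sigma of binomial sampling
  set.seed(73)
  n <- 1000L
  bp2 <- sample.int(10000L, n, replace = TRUE)
  svs2 <- resolvedSV(chrom = "chr1", ref_start = bp2, ref_end = bp2,
                     svtype = "DEL", qry_chrom = "chr1", qry_start = bp2,
                     qry_end = bp2 - 1L)
  rates2 <- relativeRate(svs2, tr)
  for (cl in names(rates2)) {
    p <- classTotals(tr)[[cl]] / 10000
    sigma <- sqrt(p * (1 - p) / n) / p       # relative sampling error
    expect_lt(abs(rates2[[cl]] - 1), 3 * sigma)
  }

  # all breakpoints in one class: the others are exactly zero
  svs3 <- resolvedSV(chrom = "chr1", ref_start = c(4100L, 4200L),
                     ref_end = c(4100L, 4200L), svtype = "DEL",
                     qry_chrom = "chr1", qry_start = 1L, qry_end = 0L)
  rates3 <- relativeRate(svs3, tr)
  expect_equal(as.numeric(rates3[["regulatory"]]), 0)
  expect_equal(unname(rates3[["intergenic"]]), 0)
})

test_that("breakpoint context reports AT fractions against background", {
  g <- Genome(c(chr1 = paste0(strrep("AT", 200), strrep("GC", 200))))
  sv_at <- resolvedSV(chrom = "chr1", ref_start = 200L, ref_end = 250L,
                      svtype = "DEL", qry_chrom = "chr1", qry_start = 1L,
                      qry_end = 0L)
  ctx <- breakpointContext(sv_at, g)
  expect_equal(ctx$per_sv$at_fraction, 1.0)
  sv_gc <- resolvedSV(chrom = "chr1", ref_start = 600L, ref_end = 650L,
                      svtype = "DEL", qry_chrom = "chr1", qry_start = 1L,
                      qry_end = 0L)
  expect_equal(breakpointContext(sv_gc, g)$per_sv$at_fraction, 0.0)

  # seeded 40%-GC genome: mean AT fraction ~ 0.6 within binomial error
  set.seed(74)
  g2 <- Genome(c(chr1 = rand_dna(100000, gc = 0.4)))
  bp <- sample(200:99800, 300)
  svs <- resolvedSV(chrom = "chr1", ref_start = bp, ref_end = bp + 10L,
                    svtype = "DEL", qry_chrom = "chr1", qry_start = 1L,
                    qry_end = 0L)
  ctx2 <- breakpointContext(svs, g2)
  expect_lt(abs(ctx2$mean_at - 0.6), 3 * sqrt(0.6 * 0.4 / (300 * 101)))
  expect_equal(ctx2$background_at, 0.6, tolerance = 0.01)
  # truncation flag at a contig end
  sv_edge <- resolvedSV(chrom = "chr1", ref_start = 10L, ref_end = 20L,
                        svtype = "DEL", qry_chrom = "chr1", qry_start = 1L,
                        qry_end = 0L)
  expect_true(breakpointContext(sv_edge, g2)$per_sv$truncated)
})
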