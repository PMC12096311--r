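test_that("tandem units are detected with and without divergence", {
  expect_equal(detectTandemUnit(strrep("ACGTT", 8)),
               list(unit_len = 5L, copy_count = 8L))
  # one SNP in one copy still detects (oracle: brute-force period scan)
  x <- strrep("ACGTT", 8)
  substr(x, 13, 13) <- "G"
  oracle_period <- function(s, min_id = 0.9) {
    v <- strsplit(s, "")[[1]]
    for (p in 1:(length(v) %/% 2)) {
      if (mean(v[1:(length(v) - p)] == v[(p + 1):length(v)]) >= min_id) {
        return(p)
      }
    }
    NULL
  }
  tu <- detectTandemUnit(x)
  expect_equal(tu$unit_len, oracle_period(x))
  expect_equal(tu$copy_count, 8L)
  set.seed(61)
  expect_null(detectTandemUnit(rand_dna(300, gc = 0.5)))
})

test_that("copy matching is the optimal assignment with leftmost ties", {
  mk_catalog <- function(sim, ref_seqs, qry_seqs) {
    nr <- length(ref_seqs); nq <- length(qry_seqs)
    cp <- data.frame(
      family = 1L, genome = c(rep("ref", nr), rep("qry", nq)),
      start = c(seq(1, by = 1000, length.out = nr),
                seq(1, by = 1000, length.out = nq)),
      end = c(seq(500, by = 1000, length.out = nr),
              seq(500, by = 1000, length.out = nq)),
      strand = "+", seq = c(ref_seqs, qry_seqs), sub_of = NA_integer_,
      stringsAsFactors = FALSE)
    sm <- diag(nrow(cp))
    sm[seq_len(nr), nr + seq_len(nq)] <- sim
    sm[nr + seq_len(nq), seq_len(nr)] <- t(sim)
    new("CopyCatalog", copies = cp, similarity = sm,
        tandem = data.frame())
  }
  # the greedy trap: (r1,q1)+(r2,q2) = 1.97 beats (r1,q2)+(r2,q1) = 1.85
  sim <- matrix(c(0.99, 0.92, 0.93, 0.98), 2, 2, byrow = TRUE)
  cat1 <- mk_catalog(sim, c("A", "B"), c("C", "D"))
  pair <- matchCopies(cat1)
  expect_equal(pair$ref, c(1L, 2L))
  expect_equal(pair$qry, c(3L, 4L))
  expect_equal(sum(pair$similarity), 0.99 + 0.98)

  # 1 ref copy, 2 identical qry copies: leftmost paired, rightmost unpaired
  cat2 <- mk_catalog(matrix(c(0.99, 0.99), 1, 2), "A", c("C", "C"))
  pair2 <- matchCopies(cat2)
  expect_equal(pair2$qry, 2L)       # leftmost qry copy (row 2)
  expect_equal(attr(pair2, "unpaired"), 3L)

  # equal-copy perfect catalog: everyone pairs, nothing unpaired
  cat3 <- mk_catalog(diag(3) * 0.2 + 0.8, c("A", "B", "C"),
                     c("A", "B", "C"))
  pair3 <- matchCopies(cat3)
  expect_equal(nrow(pair3), 3)
  expect_length(attr(pair3, "unpaired"), 0)
})

test_that("assignment equals the exhaustive oracle (both code paths)", {
  set.seed(62)
  for (i in 1:5) {
    w <- matrix(runif(20), 4, 5)       # exhaustive path (nc <= 6)
    sel <- svrefine:::.max_assignment(w)
    expect_equal(sum(w[cbind(1:4, sel)]), oracle_assignment(w),
                 tolerance = 1e-9)
  }
  for (i in 1:3) {
    w <- matrix(runif(56), 7, 8)       # Hungarian path (nc > 6)
    sel <- svrefine:::.max_assignment(w)
    expect_equal(sum(w[cbind(1:7, sel)]), oracle_assignment(w),
                 tolerance = 1e-9)
  }
})

test_that("segment decomposition catalogues dispersed copies", {
  set.seed(63)
  unit <- rand_dna(500)
  sp <- function() rand_dna(1200)
  refr <- paste0(sp(), unit, sp(), unit, sp())
  qryr <- paste0(sp(), unit, sp(), unit, sp(), unit, sp())
  cat <- decomposeSegments(refr, qryr)
  cp <- copies(cat)
  expect_equal(length(unique(cp$family)), 1)
  expect_equal(nrow(cp), 5)                 # 2 ref + 3 qry copies
  expect_equal(sum(cp$genome == "ref"), 2)
  expect_equal(sum(cp$genome == "qry"), 3)

  # no self-similarity: empty catalog marks a unique-context region
  r2 <- rand_dna(3000)
  q2 <- paste0(substr(r2, 1, 1500), rand_dna(200), substr(r2, 1501, 3000))
  expect_equal(nrow(copies(decomposeSegments(r2, q2))), 0)
})

test_that("breakpoints are leftmost with exhaustively equal ambiguity", {
  set.seed(64)
  # engineered boundaries: no accidental shift
  unit <- paste0("A", rand_dna(98), "G")
  left <- paste0(rand_dna(299), "C")
  right <- paste0("T", rand_dna(299))
  R <- paste0(left, strrep(unit, 5), right)
  Q <- paste0(left, strrep(unit, 4), right)
  calls <- placeBreakpoints(R, Q)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$ref_start, 301)
  expect_equal(calls$ambig_len, 401)
  # the exhaustive string-reconstruction oracle agrees
  plc <- oracle_del_placements(R, calls$ref_start, 100L)
  expect_equal(min(plc), calls$ref_start)
  expect_equal(length(plc), calls$ambig_len)

  # unique-context deletion with engineered non-shifting edges
  R2 <- paste0(left, "A", rand_dna(98), "G", right)
  Q2 <- paste0(left, right)
  calls2 <- placeBreakpoints(R2, Q2)
  expect_equal(calls2$ambig_len,
               length(oracle_del_placements(R2, calls2$ref_start, 100L)))

  # left-shift normalization: one more left shift must break equality
  a <- calls$ref_start; b <- calls$ref_start + 99L
  expect_false(substr(R, a - 1, a - 1) == substr(R, b, b))
})

test_that("junction calls reconstruct the query and carry patterns", {
  fx <- suite_fixtures()
  for (nm in c("unique_ins", "tandem_loss", "copy_gain_cat1",
               "block_gain_cat2")) {
    f <- fx[[nm]]
    tr <- f$truth
    win <- 3000L
    rs <- max(1L, start(tr)[1] - win)
    re <- min(seqLengths(f$ref)[["chr1"]], end(tr)[1] + win)
    qs <- max(1L, mcols(tr)$qry_start[1] - win)
    qe <- min(seqLengths(f$qry)[["chr1"]], mcols(tr)$qry_end[1] + win)
    R <- genomeSeq(f$ref, "chr1", rs, re)
    Q <- genomeSeq(f$qry, "chr1", qs, qe)
    calls <- placeBreakpoints(R, Q)
    expect_equal(nrow(calls), 1, label = nm)
    expect_equal(calls$pattern, mcols(tr)$pattern[1], label = nm)
    # splicing the residuals back reproduces the query window exactly
    rec <- paste0(substr(R, 1, calls$ref_start - 1), calls$qry_res,
                  substr(R, calls$ref_end + 1, nchar(R)))
    expect_equal(rec, Q, label = nm)
  }
})
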