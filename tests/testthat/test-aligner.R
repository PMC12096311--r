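test_that("seed anchors report maximal exact matches on both strands", {
  set.seed(31)
  s <- rand_dna(400)
  anc <- seedAnchors(s, s, k = 15)
  main <- anc[anc$strand == "+" & anc$qpos == 1 & anc$tpos == 1, ]
  expect_equal(main$len, 400L)              # full main diagonal

  # sequence vs its reverse complement: anchors only on the reverse strand
  anc2 <- seedAnchors(s, revcomp_chr(s), k = 15)
  expect_true(all(anc2$strand == "-"))
  expect_true(any(anc2$len == 400L))

  # homopolymer: anchor content equals the brute-force k-mer pair count
  hp <- strrep("A", 50)
  anc3 <- seedAnchors(hp, hp, k = 15, both_strands = FALSE)
  expect_equal(sum(anc3$len - 15L + 1L), oracle_kmer_pairs(hp, hp, 15))

  # N-containing k-mers are excluded
  withN <- paste0(rand_dna(30), strrep("N", 15), rand_dna(30))
  anc4 <- seedAnchors(withN, withN, k = 15, both_strands = FALSE)
  expect_true(all(anc4$qpos + anc4$len - 1 <= 30 | anc4$qpos >= 46))
})

test_that("chaining yields expected segment structure", {
  set.seed(32)
  a <- rand_dna(1000)
  b <- a
  substr(b, 500, 500) <- if (substr(b, 500, 500) == "A") "C" else "A"
  segs <- alignPair(a, b)
  expect_equal(nrow(segs), 1)
  expect_gte(max(segs$identity), 0.999)

  # 100-bp central deletion: one or two segments whose t-span deficit is 100
  b2 <- paste0(substr(a, 1, 450), substr(a, 551, 1000))
  segs2 <- alignPair(a, b2)
  segs2 <- segs2[segs2$strand == "+", ]
  expect_lte(nrow(segs2), 2)
  # the colinear layout is 100 bp shorter on the deleted side
  qextent <- max(segs2$qend) - min(segs2$qstart) + 1
  textent <- max(segs2$tend) - min(segs2$tstart) + 1
  expect_equal(qextent - textent, 100)

  # unrelated random sequences: no segment at min_len
  u <- rand_dna(800); v <- rand_dna(800)
  expect_equal(nrow(alignPair(u, v)), 0)
})

test_that("self-alignment sees tandem offsets and fold-backs", {
  set.seed(33)
  unit <- rand_dna(100)
  s <- paste0(rand_dna(150), strrep(unit, 3), rand_dna(150))
  sa <- selfAlign(s)
  offs <- sa$tstart - sa$qstart
  expect_true(any(offs == 100) || any(offs == 200))

  # palindromic construct gives a reverse-strand fold-back segment
  p <- rand_dna(200)
  s2 <- paste0(rand_dna(150), p, rand_dna(60), revcomp_chr(p),
               rand_dna(150))
  sa2 <- selfAlign(s2)
  expect_true(any(sa2$strand == "-"))

  # random sequence: nothing
  expect_equal(nrow(selfAlign(rand_dna(1000))), 0)
})

test_that("copy similarity equals matches over alignment columns", {
  set.seed(34)
  x <- rand_dna(100)
  expect_equal(as.numeric(copySimilarity(x, x)), 1.0)
  y <- strsplit(x, "")[[1]]
  flip <- c(3, 20, 40, 60, 80)
  y[flip] <- ifelse(y[flip] == "A", "C", "A")
  y <- paste(y, collapse = "")
  expect_equal(as.numeric(copySimilarity(x, y, "forward")), 0.95)
  expect_equal(as.numeric(copySimilarity(x, y, "forward")),
               oracle_global_align(x, y)$identity, tolerance = 1e-9)

  # orientation preference: forward 0.99-style beats reverse
  z <- svrefine:::mutate_seq(x, 0.01)
  best <- copySimilarity(x, z, "best")
  expect_equal(attr(best, "orientation"), "forward")
  bestr <- copySimilarity(x, revcomp_chr(z), "best")
  expect_equal(attr(bestr, "orientation"), "reverse")
  expect_equal(as.numeric(copySimilarity("", x)), 0)
})

test_that("segment identities agree with the DP oracle on small pairs", {
  set.seed(35)
  for (i in 1:6) {
    a <- rand_dna(sample(100:250, 1))
    b <- svrefine:::mutate_seq(a, runif(1, 0, 0.08))
    pkg <- as.numeric(copySimilarity(a, b, "forward"))
    ora <- oracle_global_align(a, b)$identity
    expect_lt(abs(pkg - ora), 0.01)
  }
})

test_that("strand symmetry and determinism hold", {
  set.seed(36)
  a <- rand_dna(600)
  b <- paste0(rand_dna(100), svrefine:::mutate_seq(a, 0.02), rand_dna(100))
  f <- alignPair(a, b)
  r <- alignPair(a, revcomp_chr(b))
  f <- f[order(f$qstart), ]; r <- r[order(r$qstart), ]
  expect_equal(nrow(f), nrow(r))
  expect_true(all(f$strand == "+") && all(r$strand == "-"))
  # coordinates map under the reverse-complement involution
  nb <- nchar(b)
  expect_equal(sort(nb - r$tend + 1), sort(f$tstart))
  expect_equal(sort(nb - r$tstart + 1), sort(f$tend))
  # identical inputs, identical outputs
  expect_identical(alignPair(a, b), alignPair(a, b))
})
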