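write_vcf_lines <- function(body, path,
                            contig = "##contig=<ID=chr1,length=100000>") {
  writeLines(c("##fileformat=VCFv4.2", contig,
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
               "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
               "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"m\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", body),
             path)
}

test_that("caller VCF coordinates convert per dialect", {
  tmp <- tempfile(fileext = ".vcf")
  write_vcf_lines(c(
    "chr1\t101\td1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=200",
    paste0("chr1\t50\ti1\tA\tA", strrep("T", 500), "\t.\tPASS\tSVTYPE=INS")),
    tmp)
  loci <- readCallerVcf(tmp, "c", dialect = "generic")
  del <- loci[mcols(loci)$svtype_raw == "DEL"]
  ins <- loci[mcols(loci)$svtype_raw == "INS"]
  # symbolic DEL: interval length END - POS + 1 = 100
  expect_equal(mcols(del)$svlen, 100L)
  expect_equal(width(del), 100L)
  # sequence-resolved INS: zero-width post-base anchor after POS
  expect_equal(start(ins), 51L)
  expect_equal(end(ins), 50L)
  expect_equal(mcols(ins)$svlen, 500L)
  expect_equal(nchar(mcols(ins)$alt_seq), 500L)

  expect_error(readCallerVcf(tmp, "c", dialect = "nope"), "dialect")
})

test_that("unmated breakends are dropped and counted", {
  tmp <- tempfile(fileext = ".vcf")
  write_vcf_lines(c(
    "chr1\t100\tb1\tN\tN[chr2:500[\t.\tPASS\tSVTYPE=BND;MATEID=b2",
    "chr1\t900\tb3\tN\tN[chr2:700[\t.\tPASS\tSVTYPE=BND;MATEID=missing",
    "chr1\t2000\td1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=2100"), tmp)
  expect_message(loci <- readCallerVcf(tmp, "c"), "dropped")
  expect_length(loci, 1)
  # b1's mate b2 is absent from the file too, so both BNDs are unmated
  expect_equal(unname(metadata(loci)$dropped[["unmated_bnd"]]), 2L)
})

test_that("benchmark VCF alleles follow the padding convention", {
  set.seed(21)
  ref <- Genome(c(chr1 = rand_dna(3000)))
  svs <- resolvedSV(chrom = "chr1", ref_start = 1001L, ref_end = 1003L,
                    svtype = "SUB", qry_chrom = "chr1", qry_start = 1001L,
                    qry_end = 1504L, alt_seq = rand_dna(504))
  tmp <- tempfile(fileext = ".vcf")
  writeBenchmarkVcf(svs, ref, tmp)
  body <- readLines(tmp)
  rec <- strsplit(body[!grepl("^#", body)], "\t")[[1]]
  # SUB ref_len 3 / qry_len 504: REF = padding + 3 bases, ALT = 505 bases
  expect_equal(nchar(rec[4]), 4L)
  expect_equal(nchar(rec[5]), 505L)
  expect_equal(as.integer(rec[2]), 1000L)

  # out-of-bounds record refused with its id
  bad <- resolvedSV(chrom = "chr1", ref_start = 2901L, ref_end = 3200L,
                    svtype = "DEL", qry_chrom = "chr1", qry_start = 2901L,
                    qry_end = 2900L, id = "oops")
  expect_error(writeBenchmarkVcf(bad, ref, tempfile()), "oops")
})

test_that("benchmark records round-trip through VCF", {
  set.seed(22)
  ref <- Genome(c(chr1 = rand_dna(60000)))
  n <- 30
  starts <- seq(2000L, 59000L, length.out = n)
  types <- rep(c("DEL", "INS", "SUB"), length.out = n)
  rows <- lapply(seq_len(n), function(i) {
    s <- as.integer(starts[i])
    if (types[i] == "DEL") {
      data.frame(rs = s, re = s + 99L, qs = s, qe = s - 1L,
                 alt = NA_character_)
    } else if (types[i] == "INS") {
      data.frame(rs = s, re = s - 1L, qs = s, qe = s + 149L,
                 alt = rand_dna(150))
    } else {
      data.frame(rs = s, re = s + 59L, qs = s, qe = s + 79L,
                 alt = rand_dna(80))
    }
  })
  df <- do.call(rbind, rows)
  svs <- resolvedSV(chrom = "chr1", ref_start = df$rs, ref_end = df$re,
                    svtype = types, qry_chrom = "chr1", qry_start = df$qs,
                    qry_end = df$qe, alt_seq = df$alt,
                    pattern = rep(c("unique", "cat1", "cat3"),
                                  length.out = n),
                    ambig_len = rep(c(1L, 7L), length.out = n))
  tmp <- tempfile(fileext = ".vcf")
  writeBenchmarkVcf(svs, ref, tmp)
  back <- readBenchmarkVcf(tmp)
  expect_equal(length(back), n)
  expect_equal(start(back), start(svs))
  expect_equal(end(back), end(svs))
  expect_equal(mcols(back)$svtype, mcols(svs)$svtype)
  expect_equal(mcols(back)$qry_start, mcols(svs)$qry_start)
  expect_equal(mcols(back)$qry_end, mcols(svs)$qry_end)
  expect_equal(mcols(back)$pattern, mcols(svs)$pattern)
  expect_equal(mcols(back)$ambig_len, mcols(svs)$ambig_len)
  # and through the caller-VCF reader with the svrefine dialect
  loci <- suppressMessages(readCallerVcf(tmp, "bench",
                                         dialect = "svrefine"))
  expect_equal(length(loci), n)
  expect_equal(start(loci), start(svs))
})

test_that("simulated loci VCF round-trips through the generic dialect", {
  set.seed(23)
  ref <- Genome(c(chr1 = rand_dna(20000)))
  loci <- svLoci("chr1", c(1000L, 5001L, 9000L), c(1199L, 5000L, 9599L),
                 caller = "simA", svtype_raw = c("DEL", "INS", "INV"),
                 svlen = c(200L, 300L, 600L))
  tmp <- tempfile(fileext = ".vcf")
  writeLociVcf(loci, ref, tmp)
  back <- readCallerVcf(tmp, "simA", dialect = "generic")
  expect_equal(start(back), start(loci))
  expect_equal(end(back), end(loci))
  expect_equal(mcols(back)$svtype_raw, mcols(loci)$svtype_raw)
  expect_equal(mcols(back)$svlen, mcols(loci)$svlen)
})
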