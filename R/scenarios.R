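# Named scenario fixtures: each one engineers a genome pair that satisfies
# exactly one boundary-scenario or breakpoint-pattern definition, plus one
# combined ~200 kb pair with ~20 planted SVs used for end-to-end closure.

#' Generate the scenario fixture suite
#'
#' Returns a named list of fixtures.  Each fixture is a list with `ref`,
#' `qry` ([Genome-class]), `truth` (resolved-SV `GRanges`, possibly empty),
#' `calls` (named list of simulated caller loci), `region` (a `GRanges`
#' marking the diagnostic region, when the fixture targets scenario
#' diagnosis), `diagnosis` (expected scenario label or NA), `in_closure`
#' (whether the fixture's truth takes part in exact-recovery closure), and
#' `manifest`.
#'
#' Scenarios: `unique_del`, `unique_ins`, `unique_inv`, `unique_sub`,
#' `tandem_loss`, `tandem_gain`, `copy_gain_cat1`, `block_gain_cat2`,
#' `inv_reject_fwd` (reverse alignment beaten by a forward alternative),
#' `inv_gap_fail` (inversion-like event spanning an N-gap run),
#' `copy_number_bias`, `copy_misalignment`, `foldback_cluster`,
#' `sub_recurrent`, and `combined` (~200 kb, ~20 SVs, all contexts).
#'
#' @param seed Integer seed.
#' @param dir Optional directory; fixtures are written as `ref.fa`,
#'   `qry.fa`, `truth.vcf`, `calls_<caller>.vcf`, `manifest.json` per
#'   scenario.
#' @param jitter_sd Breakpoint jitter of the simulated calls (default 0).
#' @param fp_per_mb False-call rate of the simulated calls (default 0).
#' @param callers Simulated caller names.
#' @return Named list of fixtures.
#' @export
scenarioSuite <- function(seed, dir = NULL, jitter_sd = 0, fp_per_mb = 0,
                          callers = c("simA", "simB")) {
  fixtures <- list()
  fid <- 0L
  nseed <- function() {
    fid <<- fid + 1L
    (seed + fid * 1009L) %% 2147483647L
  }
  mk <- function(name, ref, qry, truth, in_closure = TRUE,
                 region = NULL, diagnosis = NA_character_, calls = NULL) {
    if (is.null(calls)) {
      calls <- simulateCalls(truth, ref, nseed(), jitter_sd = jitter_sd,
                             fp_per_mb = fp_per_mb, callers = callers)
    }
    fixtures[[name]] <<- list(
      name = name, ref = ref, qry = qry, truth = truth, calls = calls,
      region = region, diagnosis = diagnosis, in_closure = in_closure,
      manifest = list(scenario = name, seed = seed,
                      n_truth = length(truth)))
  }
  plant1 <- function(ref, spec) plantSVs(ref, list(spec), nseed())

  # --- unique contexts -----------------------------------------------------
  r <- makeReference(nseed(), 20000L)
  pl <- plant1(r, list(type = "del", at = 9000L, len = 150L))
  mk("unique_del", r, pl$qry, pl$truth)

  r <- makeReference(nseed(), 20000L)
  pl <- plant1(r, list(type = "ins", at = 11000L, len = 200L))
  mk("unique_ins", r, pl$qry, pl$truth)

  r <- makeReference(nseed(), 25000L)
  pl <- plant1(r, list(type = "inv", at = 10000L, len = 4000L))
  mk("unique_inv", r, pl$qry, pl$truth)

  r <- makeReference(nseed(), 20000L)
  pl <- plant1(r, list(type = "sub", at = 10000L, len = 3L,
                       qry_len = 504L))
  mk("unique_sub", r, pl$qry, pl$truth)

  # --- tandem copy-number changes (cat3) -----------------------------------
  r <- makeReference(nseed(), 25000L, repeat_specs = list(
    repeatSpec("tandem_array", unit_len = 100L, copy_count = 5L,
               at = 10000L)))
  pl <- plant1(r, list(type = "tandem_cn", context = 1L, delta = -2L))
  mk("tandem_loss", r, pl$qry, pl$truth)

  r <- makeReference(nseed(), 25000L, repeat_specs = list(
    repeatSpec("tandem_array", unit_len = 120L, copy_count = 3L,
               at = 10000L)))
  pl <- plant1(r, list(type = "tandem_cn", context = 1L, delta = 2L))
  mk("tandem_gain", r, pl$qry, pl$truth)

  # --- single-segment copy gain (cat1) -------------------------------------
  r <- makeReference(nseed(), 20000L)
  pl <- plant1(r, list(type = "copy_gain", at = 10000L, len = 300L))
  mk("copy_gain_cat1", r, pl$qry, pl$truth)

  # --- multi-segment block gain (cat2) -------------------------------------
  r <- makeReference(nseed(), 25000L, repeat_specs = list(
    repeatSpec("multiseg_block", unit_len = 400L, at = 10000L)))
  blk <- metadata_field(r, "repeats", NULL)
  pl <- plant1(r, list(type = "block_gain", at = blk$end[1],
                       len = blk$end[1] - blk$start[1] + 1L))
  mk("block_gain_cat2", r, pl$qry, pl$truth)

  # --- inversion rejection: forward alternative beats the reverse match ----
  set.seed(nseed())
  r <- makeReference(nseed(), 20000L)
  s <- genomeSeq(r, "chr1")
  A <- random_seq(800L, 0.36)
  X <- paste0(A, revcomp(mutate_seq(A, 0.1)))        # reverse-alignable
  substr(s, 10000L, 10000L + nchar(X) - 1L) <- X
  r <- Genome(setNames(s, "chr1"), metadata = r@metadata)
  q <- s
  substr(q, 10000L, 10000L + nchar(X) - 1L) <- mutate_seq(X, 0.01)
  fake <- svLoci("chr1", 10000L, 10000L + nchar(X) - 1L,
                 caller = callers[1], svtype_raw = "INV",
                 svlen = nchar(X), filter = "PASS")
  mk("inv_reject_fwd", r, Genome(setNames(q, "chr1")), resolvedSV(),
     in_closure = FALSE,
     region = GRanges("chr1", IRanges(10000L, 10000L + nchar(X) - 1L)),
     calls = setNames(list(fake), callers[1]))

  # --- inversion rejected by an assembly gap (typed SUB) -------------------
  r <- makeReference(nseed(), 25000L,
                     gap_spec = data.frame(at = 11400L, len = 50L))
  seg <- genomeSeq(r, "chr1", 10000L, 12999L)
  pl <- plant1(r, list(type = "sub", at = 10000L, len = 3000L,
                       alt = revcomp(seg)))
  mk("inv_gap_fail", r, pl$qry, pl$truth)

  # --- boundary-scenario fixtures ------------------------------------------
  # copy-number bias: equal copy counts, all query copies best-hit copy 1
  r <- makeReference(nseed(), 22000L, repeat_specs = list(
    repeatSpec("dispersed_copy", unit_len = 800L, copy_count = 2L,
               divergence = 0.1, at = c(10000L, 12000L))))
  reps <- metadata_field(r, "repeats", NULL)
  q <- genomeSeq(r, "chr1")
  substr(q, reps$start[2], reps$end[2]) <- reps$unit[2]   # copy2 := copy1
  fake <- svLoci("chr1", reps$start[2], reps$end[2],
                 caller = callers[1], svtype_raw = "DEL",
                 svlen = 800L, filter = "PASS")
  mk("copy_number_bias", r, Genome(setNames(q, "chr1")), resolvedSV(),
     in_closure = FALSE,
     region = GRanges("chr1", IRanges(reps$start[2], reps$end[2])),
     diagnosis = "copy_number_discrepancy",
     calls = setNames(list(fake), callers[1]))

  # copy misalignment: three diverged copies, the middle one deleted
  r <- makeReference(nseed(), 30000L, repeat_specs = list(
    repeatSpec("dispersed_copy", unit_len = 700L, copy_count = 3L,
               divergence = 0.04, at = c(10000L, 12200L, 14400L))))
  reps <- metadata_field(r, "repeats", NULL)
  pl <- plant1(r, list(type = "del", at = reps$start[2], len = 700L,
                       pattern = "cat3"))
  mk("copy_misalignment", r, pl$qry, pl$truth,
     region = GRanges("chr1", IRanges(reps$start[1], reps$end[3])),
     diagnosis = "copy_misalignment")

  # fold-back cluster: many dispersed reverse self-hits, plus a clean
  # deletion downstream of the cluster
  r <- makeReference(nseed(), 30000L, repeat_specs = list(
    repeatSpec("foldback_cluster", unit_len = 180L, copy_count = 12L,
               divergence = 0.05, at = 10000L)))
  reps <- metadata_field(r, "repeats", NULL)
  pl <- plant1(r, list(type = "del", at = reps$end[1] + 500L, len = 120L))
  mk("foldback_cluster", r, pl$qry, pl$truth,
     region = GRanges("chr1", IRanges(reps$start[1], reps$end[1])),
     diagnosis = "reverse_artifact")

  # --- recurrent-indel substitution ----------------------------------------
  r <- makeReference(nseed(), 20000L)
  pl <- plant1(r, list(type = "sub_recurrent", at = 10000L, len = 600L))
  mk("sub_recurrent", r, pl$qry, pl$truth)

  # --- combined closure fixture (~200 kb, ~20 SVs) -------------------------
  r <- makeReference(nseed(), 200000L, repeat_specs = list(
    repeatSpec("tandem_array", unit_len = 100L, copy_count = 5L,
               at = 30000L),
    repeatSpec("tandem_array", unit_len = 150L, copy_count = 4L,
               at = 60000L),
    repeatSpec("dispersed_copy", unit_len = 700L, copy_count = 3L,
               divergence = 0.04, at = c(90000L, 92200L, 94400L)),
    repeatSpec("multiseg_block", unit_len = 400L, at = 120000L),
    repeatSpec("foldback_cluster", unit_len = 180L, copy_count = 10L,
               at = 150000L, divergence = 0.05)),
    gap_spec = data.frame(at = 176000L, len = 60L),
    at_rich_blocks = data.frame(at = 45000L, len = 2000L))
  reps <- metadata_field(r, "repeats", NULL)
  blk <- which(reps$kind == "multiseg_block")[1]
  disp2 <- which(reps$kind == "dispersed_copy")[2]
  specs <- list(
    list(type = "del", at = 10000L, len = 180L),
    list(type = "ins", at = 15000L, len = 250L),
    list(type = "del", at = 20000L, len = 300L),
    list(type = "ins", at = 25000L, len = 520L),
    list(type = "tandem_cn", context = 1L, delta = -2L),
    list(type = "tandem_cn", context = 2L, delta = 1L),
    list(type = "del", at = 40000L, len = 130L),
    list(type = "ins", at = 46000L, len = 200L),      # inside AT-rich block
    list(type = "sub", at = 50000L, len = 3L, qry_len = 504L),
    list(type = "inv", at = 70000L, len = 3000L),
    list(type = "del", at = reps$start[disp2], len = 700L,
         pattern = "cat3"),
    list(type = "ins", at = 100000L, len = 300L),
    list(type = "del", at = 105000L, len = 90L),
    list(type = "del", at = 105400L, len = 70L),
    list(type = "copy_gain", at = 110000L, len = 300L),
    list(type = "block_gain", at = reps$end[blk],
         len = reps$end[blk] - reps$start[blk] + 1L),
    list(type = "sub_recurrent", at = 130000L, len = 600L),
    list(type = "ins", at = 140000L, len = 400L),
    list(type = "del", at = 160000L, len = 150L),
    list(type = "ins", at = 170000L, len = 220L),
    list(type = "del", at = 185000L, len = 500L))
  pl <- plantSVs(r, specs, nseed())
  mk("combined", r, pl$qry, pl$truth)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (fx in fixtures) {
      d <- file.path(dir, fx$name)
      dir.create(d, showWarnings = FALSE)
      writeGenome(fx$ref, file.path(d, "ref.fa"))
      writeGenome(fx$qry, file.path(d, "qry.fa"))
      writeBenchmarkVcf(fx$truth, fx$ref, file.path(d, "truth.vcf"))
      for (cal in names(fx$calls)) {
        writeLociVcf(fx$calls[[cal]], fx$ref,
                     file.path(d, sprintf("calls_%s.vcf", cal)))
      }
      write_json(fx$manifest, file.path(d, "manifest.json"),
                 auto_unbox = TRUE, pretty = TRUE)
    }
  }
  fixtures
}
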