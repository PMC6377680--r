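test_that("error-free reads inside the reference align as one ungapped block", {
  ref <- make_reference(4000, seed = 10)
  reads <- c(a = substr(ref$sequence, 500, 649),
             b = mtbreak:::revcomp(substr(ref$sequence, 1200, 1349)))
  aln <- split_align(reads, ref)
  expect_identical(nrow(aln), 2L)
  expect_true(all(aln$n_gaps == 0L))
  expect_true(all(aln$mismatches == 0L))
  expect_identical(aln$b1_start, c(500L, 1200L))
  expect_identical(aln$strand, c("+", "-"))
})

test_that("reads crossing the circular origin align ungapped, not gapped", {
  ref <- make_reference(4000, seed = 11)
  r <- paste0(substr(ref$sequence, 3951, 4000), substr(ref$sequence, 1, 50))
  aln <- split_align(c(x = r), ref)
  expect_identical(aln$n_gaps, 0L)
  expect_identical(aln$b1_start, 3951L)
  expect_identical(aln$b1_end, 4050L)  # unwrapped on the doubled reference
  # the same read against a linear reference cannot align full-length
  lin <- circular_reference(ref$sequence, circular = FALSE)
  aln_lin <- split_align(c(x = r), lin)
  expect_true(nrow(aln_lin) == 0L || aln_lin$n_gaps[1L] > 0L)
})

test_that("reads with substitution errors still align (anchored extension)", {
  ref <- make_reference(4000, seed = 12)
  r <- substr(ref$sequence, 800, 949)
  ch <- strsplit(r, "")[[1L]]
  ch[70] <- setdiff(c("A", "C", "G", "T"), ch[70])[1L]
  aln <- split_align(c(e = paste(ch, collapse = "")), ref)
  expect_identical(aln$n_gaps, 0L)
  expect_identical(aln$b1_start, 800L)
  expect_identical(aln$mismatches, 1L)
})

test_that("split alignment is deterministic and junction-normalized", {
  co <- make_cohort(seed = 31)
  ev <- co$events[[1L]]
  mol <- mtbreak:::deleted_sequence(co$ref, ev)
  canon <- canonical_event(ev, co$ref)
  # several junction reads with different flank geometries must normalize to
  # the same breakpoints (leftmost placement is read-independent)
  starts <- ev$d_start - 1L - c(20L, 35L, 50L, 64L)
  reads <- stats::setNames(
    vapply(starts, function(s) substr(mol, s, s + 99L), character(1)),
    paste0("j", seq_along(starts)))
  a1 <- split_align(reads, co$ref)
  a2 <- split_align(reads, co$ref)
  expect_identical(a1, a2)
  expect_true(all(a1$n_gaps == 1L))
  expect_true(all(a1$d_start == canon[["d_start"]]))
  expect_true(all(a1$d_end == canon[["d_end"]]))
  # sliding equals the planted repeat length for perfect-repeat junctions
  expect_true(all(a1$sliding == 13L))
  # implied deleted interval length equals gap_length
  expect_true(all(a1$d_end - a1$d_start + 1L == a1$gap_length))
})

test_that("reads shorter than seed_len are skipped with a log record", {
  ref <- make_reference(1000, seed = 13)
  aln <- split_align(c(tiny = "ACGTACGT",
                       ok = substr(ref$sequence, 10, 80)), ref)
  expect_identical(attr(aln, "skipped"), "tiny")
  expect_identical(nrow(aln), 1L)
})

test_that("SAM ingest converts CIGAR gaps and normalizes junctions", {
  rp <- repeat_plan("ACCTCCCTCACCA", 8470, 13447)
  ref <- make_reference(16569, repeat_plans = list(rp), seed = 1)
  # build the SAM from reference-derived sequences so blocks genuinely match
  mol <- mtbreak:::deleted_sequence(
    ref, plant_copy_choice_deletion(ref, rp, "five_prime"))
  jseq <- substr(mol, 8433, 8532)  # 50 bp on each side of the junction
  useq <- substr(ref$sequence, 100, 199)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$length),
    sprintf("g1\t0\t%s\t8433\t60\t50M4977N50M\t*\t0\t0\t%s\t*", ref$name, jseq),
    sprintf("u1\t0\t%s\t100\t60\t100M\t*\t0\t0\t%s\t*", ref$name, useq),
    sprintf("m1\t0\t%s\t200\t60\t30M10D30M10D30M\t*\t0\t0\t*\t*", ref$name),
    sprintf("e1\t0\t%s\t300\t60\t50M\t*\t0\t0\t*\t*\tZE:f:0.5", ref$name)
  ), sam)
  alns <- read_sam(sam, ref)
  expect_identical(attr(alns, "aligner"), "external")
  g1 <- alns[alns$read_id == "g1", ]
  expect_identical(g1$n_gaps, 1L)
  expect_identical(g1$gap_length, 4977L)
  expect_identical(c(g1$b1_start, g1$b1_end, g1$b2_start, g1$b2_end),
                   c(8433L, 8482L, 13460L, 13509L))
  # junction [8483,13459] normalizes leftmost across the 13-bp repeat
  expect_identical(c(g1$d_start, g1$d_end), c(8470L, 13446L))
  expect_identical(g1$sliding, 13L)
  expect_identical(alns[alns$read_id == "u1", "n_gaps"], 0L)
  expect_identical(alns[alns$read_id == "m1", "n_gaps"], 2L)
  # ingested E-value tag is passed through unchanged
  expect_identical(alns[alns$read_id == "e1", "evalue"], 0.5)
})

test_that("expect-value analog is monotone and calibrated to the filter", {
  # perfect 100-bp match against a genome-scale reference passes 1e-5
  e_good <- score_alignment(list(read_len = 100L, mismatches = 0L), 16569L)
  expect_lt(e_good, 1e-5)
  # a 15-bp block with 5 mismatches fails
  e_bad <- score_alignment(list(read_len = 15L, mismatches = 5L), 16569L)
  expect_gt(e_bad, 1e-5)
  # monotone decreasing in score
  e1 <- score_alignment(list(read_len = 50L, mismatches = 0L), 16569L)
  e2 <- score_alignment(list(read_len = 50L, mismatches = 2L), 16569L)
  expect_lt(e1, e2)
  # ingested value returned unchanged
  expect_identical(score_alignment(list(evalue = 3e-7), 16569L), 3e-7)
})
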