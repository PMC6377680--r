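test_that("make_reference plants repeat copies verbatim and is deterministic", {
  rp <- repeat_plan("ACCTCCCTCACCA", 1000, 2500)
  ref <- make_reference(4300, repeat_plans = list(rp), seed = 7)
  expect_identical(substr(ref$sequence, 1000, 1012), "ACCTCCCTCACCA")
  expect_identical(substr(ref$sequence, 2500, 2512), "ACCTCCCTCACCA")
  expect_identical(make_reference(4300, repeat_plans = list(rp), seed = 7)$sequence,
                   ref$sequence)
  expect_false(identical(make_reference(4300, repeat_plans = list(rp),
                                        seed = 8)$sequence, ref$sequence))
  # empty plan list: background composition roughly honours gc
  bg <- make_reference(20000, gc = 0.25, seed = 1)
  gc_obs <- mean(strsplit(bg$sequence, "")[[1L]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.25), 0.02)
  # copy 2 mismatches are written
  rpm <- repeat_plan("ACCTCCCTCACCA", 100, 900,
                     mismatches_in_copy2 = data.frame(offset = 13, base = "G"))
  refm <- make_reference(2000, repeat_plans = list(rpm), seed = 2)
  expect_identical(substr(refm$sequence, 900, 912), "ACCTCCCTCACCG")
  expect_error(make_reference(2000, repeat_plans = list(
    repeat_plan("ACGTACGTACGT", 100, 105))), "overlap")
})

test_that("planted repeats are maximal (no chance extension at boundaries)", {
  for (seed in 1:20) {
    rp <- repeat_plan("ACCTCCCTCACCA", 500, 1500)
    ref <- make_reference(3000, repeat_plans = list(rp), seed = seed)
    ch <- strsplit(ref$sequence, "")[[1L]]
    expect_false(ch[499] == ch[1499])
    expect_false(ch[513] == ch[1513])
  }
})

test_that("copy-choice deletion geometry matches the retained side", {
  rp <- repeat_plan("ACCTCCCTCACCA", 8470, 13447)
  ref <- make_reference(16569, repeat_plans = list(rp), seed = 1)
  d5 <- plant_copy_choice_deletion(ref, rp, "five_prime")
  expect_identical(c(d5$d_start, d5$d_end), c(8483L, 13459L))
  expect_identical(d5$length, 4977L)
  d3 <- plant_copy_choice_deletion(ref, rp, "three_prime")
  expect_identical(c(d3$d_start, d3$d_end), c(8470L, 13446L))
  expect_identical(d3$length, 4977L)
  # perfect repeats: both retained sides excise to the same molecule
  expect_identical(mtbreak:::deleted_sequence(ref, d5),
                   mtbreak:::deleted_sequence(ref, d3))
  # the deleted molecule keeps exactly one repeat copy at the junction
  mol <- mtbreak:::deleted_sequence(ref, d5)
  expect_identical(substr(mol, 8470, 8482), "ACCTCCCTCACCA")
  hits <- gregexpr("ACCTCCCTCACCA", mol, fixed = TRUE)[[1L]]
  expect_identical(length(hits), 1L)
})

test_that("simulate_reads: read count, purity, duplicates, determinism", {
  rp <- repeat_plan("ACCTCCCTCACCA", 1000, 2500)
  ref <- make_reference(4300, repeat_plans = list(rp), seed = 3)
  del <- plant_copy_choice_deletion(ref, rp, "five_prime")
  # closed-form read count at 100x
  sim <- simulate_reads(truth_set(ref, list(del), 1.0), read_len = 150,
                        coverage = 100, seed = 4)
  expect_lte(abs(length(sim$reads) - ceiling(100 * 4300 / 150)), 1)
  # fraction 1.0, no errors: every read is a substring of the deleted molecule
  mol <- mtbreak:::deleted_sequence(ref, del)
  dbl <- paste0(mol, mol)
  ok <- vapply(sim$reads, function(r) {
    grepl(r, dbl, fixed = TRUE) || grepl(mtbreak:::revcomp(r), dbl, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
  # duplicates are position-identical with their source
  simd <- simulate_reads(truth_set(ref, list(del), 0.5), read_len = 100,
                         coverage = 10, dup_rate = 0.5, seed = 9)
  tt <- simd$truth
  dups <- tt[!is.na(tt$duplicate_of), ]
  expect_identical(nrow(dups), as.integer(round(0.5 * (nrow(tt) - nrow(dups)))))
  src <- tt[match(dups$duplicate_of, tt$read_id), ]
  expect_identical(dups$start, src$start)
  expect_identical(dups$molecule, src$molecule)
  # determinism
  sim2 <- simulate_reads(truth_set(ref, list(del), 0.5), read_len = 100,
                         coverage = 10, dup_rate = 0.5, seed = 9)
  expect_identical(simd$reads, sim2$reads)
  expect_identical(simd$truth, sim2$truth)
  # parameter validation
  expect_error(simulate_reads(truth_set(ref, list(del), 0.5), coverage = 0),
               "coverage")
  expect_error(simulate_reads(truth_set(ref, list(del), 0.5), error_rate = 1),
               "error_rate")
  expect_error(truth_set(ref, list(del), 1.2), "sum to <= 1")
})

test_that("substitution errors are recorded and bounded", {
  ref <- make_reference(2000, seed = 5)
  sim <- simulate_reads(truth_set(ref), read_len = 100, coverage = 5,
                        error_rate = 0.02, seed = 6)
  expect_true(all(sim$truth$n_errors >= 0))
  expect_gt(sum(sim$truth$n_errors), 0)
  # errors happen at the stated rate, roughly
  rate <- sum(sim$truth$n_errors) / (nrow(sim$truth) * 100)
  expect_lt(abs(rate - 0.02), 0.01)
})

test_that("FASTQ and truth-table output round-trip", {
  ref <- make_reference(1000, seed = 2)
  sim <- simulate_reads(truth_set(ref), read_len = 80, coverage = 3, seed = 2)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim, fq)
  back <- read_fastq(fq)
  expect_identical(back, sim$reads)
  tsv <- tempfile(fileext = ".tsv")
  write_truth_table(sim, tsv)
  tt <- utils::read.delim(tsv)
  expect_identical(nrow(tt), nrow(sim$truth))
})

test_that("error-free junction reads split-align to the planted event", {
  # simulator -> aligner round trip: every junction-spanning read with both
  # flanks >= seed_len yields breakpoints sliding-equivalent to truth
  co <- make_cohort(seed = 21)
  ev <- co$events[[1L]]
  mol <- mtbreak:::deleted_sequence(co$ref, ev)
  canon <- canonical_event(ev, co$ref)
  # junction reads: 40-bp flanks on both sides
  rl <- 80L
  jstart <- ev$d_start - 1L - 40L + 1L
  reads <- stats::setNames(substr(paste0(mol, mol), jstart, jstart + rl - 1L),
                           "jread")
  aln <- split_align(reads, co$ref)
  expect_identical(nrow(aln), 1L)
  expect_identical(aln$n_gaps, 1L)
  expect_identical(c(aln$d_start, aln$d_end), unname(canon))
})
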