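test_that("longest_exact_repeat recovers a planted 13-bp junction repeat", {
  rp <- repeat_plan("ACCTCCCTCACCA", 8470, 13447)
  ref <- make_reference(16569, repeat_plans = list(rp), seed = 1)
  del <- plant_copy_choice_deletion(ref, rp, "five_prime")
  ler <- longest_exact_repeat(del$d_start, del$d_end, ref)
  expect_identical(ler$k_exact, 13L)
  expect_identical(ler$repeat_seq, "ACCTCCCTCACCA")
  # three-prime excision of the same perfect repeat: same equivalence class
  del3 <- plant_copy_choice_deletion(ref, rp, "three_prime")
  expect_identical(longest_exact_repeat(del3$d_start, del3$d_end, ref)$k_exact,
                   13L)
})

test_that("longest_exact_repeat equals exhaustive brute force on small refs", {
  set.seed(123)
  for (rep in 1:400) {
    L <- sample(40:100, 1)
    ref <- circular_reference(rand_dna(L))
    d_start <- sample(5:(L %/% 2), 1)
    d_end <- d_start + sample(3:(L %/% 3), 1)
    ler <- longest_exact_repeat(d_start, d_end, ref)
    expect_identical(ler$k_exact,
                     brute_longest_repeat(ref$sequence, d_start, d_end))
    # sliding ambiguity equals k_exact by construction
    nj <- mtbreak:::normalize_junction(ref, d_start, d_end)
    expect_identical(nj$sliding,
                     longest_exact_repeat(nj$d_start,
                                          nj$d_start + (d_end - d_start),
                                          ref)$k_exact)
  }
})

test_that("no-repeat junction returns k_exact 0 and empty pattern", {
  # engineer a junction with guaranteed mismatches on both sides
  s <- paste0(strrep("AC", 30), "GGGG", strrep("TG", 30))
  ref <- circular_reference(s, circular = FALSE)
  # junction chosen so d_start-1='C'/d_end='G' and d_start='G'/d_end+1='T'
  ler <- longest_exact_repeat(61, 64, ref)
  expect_identical(ler$k_exact, 0L)
  expect_identical(ler$repeat_seq, "")
})

test_that("directionality recovers planted retained sides on informative events", {
  k <- 13L
  # 5' retention, copy-2 mismatch at the junction-distal end (offset k)
  rp5 <- repeat_plan("ACCTCCCTCACCA", 2000, 8000,
                     mismatches_in_copy2 = data.frame(offset = k, base = "G"))
  ref5 <- make_reference(16569, repeat_plans = list(rp5), seed = 51)
  d5 <- plant_copy_choice_deletion(ref5, rp5, "five_prime")
  ler5 <- longest_exact_repeat(d5$d_start, d5$d_end, ref5)
  expect_lte(ler5$k_exact, 1L)  # informative by construction
  dd5 <- directionality(d5$d_start, d5$d_end, ref5, sliding = ler5$k_exact)
  expect_identical(dd5$direction, "five_prime")
  expect_gte(dd5$k5, 13L)
  expect_identical(dd5$k5, brute_k_side(ref5$sequence, d5$d_start, d5$d_end,
                                        "five"))
  expect_identical(dd5$k3, brute_k_side(ref5$sequence, d5$d_start, d5$d_end,
                                        "three"))
  # 3' retention, copy-2 mismatch at offset 1
  rp3 <- repeat_plan("ACCTCCCTCACCA", 2000, 8000,
                     mismatches_in_copy2 = data.frame(offset = 1, base = "T"))
  ref3 <- make_reference(16569, repeat_plans = list(rp3), seed = 52)
  d3 <- plant_copy_choice_deletion(ref3, rp3, "three_prime")
  dd3 <- directionality(d3$d_start, d3$d_end, ref3)
  expect_identical(dd3$direction, "three_prime")
  expect_gte(dd3$k3, 13L)
})

test_that("perfect repeats and mid-repeat mismatches are not informative", {
  rp <- repeat_plan("ACCTCCCTCACCA", 2000, 8000)
  ref <- make_reference(16569, repeat_plans = list(rp), seed = 53)
  del <- plant_copy_choice_deletion(ref, rp, "five_prime")
  dd <- directionality(del$d_start, del$d_end, ref)
  expect_identical(dd$direction, "not_informative")
  # an internal mismatch at offset 7 still leaves 6 bp of exact sliding,
  # beyond the 1-bp uncertainty gate
  rpm <- repeat_plan("ACCTCCCTCACCA", 2000, 8000,
                     mismatches_in_copy2 = data.frame(offset = 7, base = "A"))
  refm <- make_reference(16569, repeat_plans = list(rpm), seed = 54)
  dm <- plant_copy_choice_deletion(refm, rpm, "five_prime")
  expect_identical(longest_exact_repeat(dm$d_start, dm$d_end, refm)$k_exact, 6L)
  expect_identical(directionality(dm$d_start, dm$d_end, refm)$direction,
                   "not_informative")
})

test_that("directionality needs a repeat-length difference of at least 2", {
  set.seed(77)
  found_unclassified <- FALSE
  for (rep in 1:200) {
    ref <- circular_reference(rand_dna(300))
    d_start <- 100L; d_end <- 220L
    dd <- directionality(d_start, d_end, ref)
    if (dd$direction == "not_informative") next
    if (abs(dd$k5 - dd$k3) < 2L) {
      expect_identical(dd$direction, "unclassified")
      found_unclassified <- TRUE
    } else if (dd$k5 > dd$k3) {
      expect_identical(dd$direction, "five_prime")
    } else {
      expect_identical(dd$direction, "three_prime")
    }
  }
  expect_true(found_unclassified)
})

test_that("directionality matches the brute-force oracle on random refs", {
  set.seed(321)
  for (rep in 1:300) {
    L <- sample(60:100, 1)
    ref <- circular_reference(rand_dna(L))
    d_start <- sample(10:(L %/% 2), 1)
    d_end <- d_start + sample(5:(L %/% 3), 1)
    dd <- directionality(d_start, d_end, ref, sliding = 0L)  # bypass the gate
    expect_identical(dd$k5,
                     brute_k_side(ref$sequence, d_start, d_end, "five"))
    expect_identical(dd$k3,
                     brute_k_side(ref$sequence, d_start, d_end, "three"))
  }
})

test_that("randomized breakpoints honour cardinality, lengths and seed", {
  observed <- data.frame(d_start = c(1000L, 2000L, 3000L),
                         d_end = c(6000L, 6500L, 9000L))
  region <- genomic_interval(500, 12000)
  ne <- randomize_breakpoints(observed, make_reference(16569, seed = 1),
                              region = region, n_sets = 20, seed = 5)
  expect_identical(length(ne$sets), 20L)
  for (s in ne$sets) {
    expect_identical(nrow(s), 3L)
    expect_true(all(s$d_start >= 500 & s$d_end <= 12000))
    expect_true(all((s$d_end - s$d_start + 1L) %in%
                      (observed$d_end - observed$d_start + 1L)))
  }
  ne2 <- randomize_breakpoints(observed, make_reference(16569, seed = 1),
                               region = region, n_sets = 20, seed = 5)
  expect_identical(ne$sets, ne2$sets)
  expect_error(randomize_breakpoints(observed, make_reference(16569, seed = 1),
                                     region = genomic_interval(1, 100)),
               "too small")
})

test_that("repeat enrichment: identity null gives fold 1; ratio is as defined", {
  ref <- make_reference(16569, seed = 61)
  observed <- data.frame(d_start = seq(1000L, 5500L, by = 500L),
                         d_end = seq(7000L, 11500L, by = 500L))
  observed <- annotate_repeats(observed, ref)
  ident <- structure(list(sets = replicate(5, observed[, c("d_start", "d_end")],
                                           simplify = FALSE),
                          n_sets = 5L, scheme = "length_matched",
                          region = genomic_interval(1, 16569), seed = 1L),
                     class = "null_ensemble")
  et <- repeat_enrichment(observed, ident, ref)
  expect_true(all(abs(et$fold[!is.na(et$fold)] - 1) < 1e-12))
  expect_true(all(abs(et$fold_cum[!is.na(et$fold_cum)] - 1) < 1e-12))
  expect_true(all(et$obs_freq >= 0 & et$obs_freq <= 1))
  # fold is observed / null mean: 0.09 over 0.05 is 1.8
  expect_equal(0.09 / 0.05, 1.8)
})

test_that("motif_table counts patterns per deletion and per read", {
  ann <- data.frame(repeat_seq = c("CCC", "CCC", "ACC", ""),
                    read_support = c(2L, 3L, 1L, 10L))
  mt <- motif_table(ann)
  expect_identical(mt$pattern, c("CCC", "ACC"))
  expect_identical(mt$n_unique, c(2L, 1L))
  expect_identical(mt$n_reads, c(5L, 1L))
  # empty patterns (k_exact = 0) are excluded
  expect_false("" %in% mt$pattern)
  # min_len filters short patterns
  expect_identical(nrow(motif_table(ann, min_len = 4L)), 0L)
})

test_that("pattern overlap: subset gives 1, disjoint gives 0", {
  ref <- make_reference(16569, seed = 62)
  a <- annotate_repeats(data.frame(d_start = c(2000L, 3000L),
                                   d_end = c(9000L, 10000L)), ref)
  a$repeat_seq <- c("ACCT", "CCCT")
  b <- a
  b$repeat_seq <- c("ACCT", "CCCT")
  region <- genomic_interval(1000, 12000)
  ov <- pattern_overlap(a, b, ref, region = region, n_random = 10, seed = 7)
  expect_identical(ov$observed, 1)
  expect_true(all(ov$null_fractions >= 0 & ov$null_fractions <= 1))
  b2 <- a
  b2$repeat_seq <- c("GGGA", "TTTA")
  ov2 <- pattern_overlap(a, b2, ref, region = region, n_random = 10, seed = 7)
  expect_identical(ov2$observed, 0)
})

test_that("directionality summary reproduces count-to-fraction arithmetic", {
  ann <- data.frame(
    direction = c(rep("five_prime", 80), rep("three_prime", 39),
                  rep("unclassified", 10), rep("not_informative", 494)),
    read_support = 1L)
  # per-read weighting uses supporting reads: bump some five_prime support
  ann$read_support[1:42] <- 2L
  ds <- directionality_summary(ann)
  expect_identical(unname(ds$counts[c("five_prime", "three_prime")]),
                   c(80L, 39L))
  expect_equal(unname(ds$frac_unique[["five_prime"]]), 80 / 119)
  expect_equal(unname(ds$frac_unique[["three_prime"]]), 39 / 119)
  expect_equal(unname(ds$frac_reads[["five_prime"]]), 122 / 161)
  # all one direction
  all5 <- data.frame(direction = rep("five_prime", 4), read_support = 1L)
  expect_equal(unname(directionality_summary(all5)$frac_unique[["five_prime"]]),
               1)
  # no informative cases -> absent fractions
  none <- data.frame(direction = rep("not_informative", 3), read_support = 1L)
  expect_true(is.na(directionality_summary(none)$frac_unique[["five_prime"]]))
})

test_that("a 100% five-prime cohort keeps a five-over-three excess despite
           background micro-repeats", {
  # all planted events retain the 5' copy; random background still produces
  # some spurious three_prime labels, so assert only the direction of bias
  k <- 13L
  plans <- lapply(0:11, function(i) {
    repeat_plan("ACCTCCCTCACCA", 1200 + 40L * i, 9000 + 220L * i,
                mismatches_in_copy2 = data.frame(offset = k, base = "G"))
  })
  n5 <- 0L; n3 <- 0L
  for (seed in 1:4) {
    ref <- make_reference(16569, repeat_plans = plans, seed = 100 + seed)
    calls <- do.call(rbind, lapply(plans, function(p) {
      d <- plant_copy_choice_deletion(ref, p, "five_prime")
      data.frame(d_start = d$d_start, d_end = d$d_end)
    }))
    ann <- annotate_repeats(calls, ref)
    n5 <- n5 + sum(ann$direction == "five_prime")
    n3 <- n3 + sum(ann$direction == "three_prime")
  }
  expect_gt(n5, n3)
  expect_gt(n5, 0L)
})
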