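# Shared synthetic cohort: 20 copy-choice events on a 16,569-bp circular
# reference — perfect 13-bp repeats, imperfect repeats with the copy-2
# mismatch placed at the junction-distal end (which is what makes an
# imperfect junction informative for directionality), and repeat-free
# junctions. Deletion spans are major-arc sized (11-13 kb).
make_cohort <- function(seed = 1L) {
  k <- 13L
  types <- c(rep("perfect", 8L), rep("imp5", 6L), rep("imp3", 3L),
             rep("none", 3L))
  pos5 <- 2000L + 60L * (seq_along(types) - 1L)
  span <- 11000L + 100L * (seq_along(types) - 1L)
  # one distinct 13-mer per event: sharing one repeat sequence across many
  # junctions would make junction reads genuinely ambiguous between events
  set.seed(seed)
  reps <- character(0)
  while (length(reps) < length(types)) {
    reps <- unique(c(reps, paste(sample(c("A", "C", "G", "T"), k,
                                        replace = TRUE), collapse = "")))
  }
  plans <- list()
  for (i in seq_along(types)) {
    if (types[i] == "none") next
    base_rep <- reps[i]
    mm <- switch(types[i],
      perfect = NULL,
      imp5 = data.frame(offset = k, base = "G"),   # junction-distal for 5' retention
      imp3 = data.frame(offset = 1L, base = "T"))  # junction-distal for 3' retention
    if (!is.null(mm)) {
      # ensure the substituted base actually differs from the repeat base
      rb <- substr(base_rep, mm$offset, mm$offset)
      mm$base <- setdiff(c("A", "C", "G", "T"), rb)[1L]
    }
    plans[[length(plans) + 1L]] <- repeat_plan(base_rep, pos5[i],
                                               pos5[i] + span[i],
                                               mismatches_in_copy2 = mm)
  }
  ref <- make_reference(16569L, repeat_plans = plans, seed = seed)
  events <- list()
  pi <- 0L
  for (i in seq_along(types)) {
    if (types[i] == "none") {
      events[[i]] <- planted_deletion(pos5[i] + 3L, pos5[i] + span[i] - 5L)
    } else {
      pi <- pi + 1L
      side <- if (types[i] == "imp3") "three_prime" else "five_prime"
      events[[i]] <- plant_copy_choice_deletion(ref, plans[[pi]], side)
    }
  }
  list(ref = ref, events = events, types = types,
       truth = truth_set(ref, events, rep(0.049, length(events)),
                         seed = seed))
}

# canonical (leftmost-normalized) representation of a planted event, for
# sliding-equivalence comparison with pipeline calls
canonical_event <- function(ev, ref) {
  ler <- longest_exact_repeat(ev$d_start, ev$d_end, ref)
  c(d_start = ev$d_start - ler$left_slide, d_end = ev$d_end - ler$left_slide)
}
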