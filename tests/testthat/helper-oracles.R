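# Independent brute-force oracles, deliberately naive: exhaustive enumeration
# over candidate repeat lengths and placements, with no shared logic with the
# package internals they check (the package slides outward from the junction;
# these enumerate every (length, offset) pair directly).

rand_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                              collapse = "")

# character vector at circular positions
circ_at <- function(ch, pos) ch[((pos - 1L) %% length(ch)) + 1L]

# longest exact repeat overlapping both breakpoints: enumerate every length k
# (descending) and every junction offset a in 0..k, compare the two copies.
brute_longest_repeat <- function(seq, d_start, d_end, kmax = 30L) {
  ch <- strsplit(seq, "")[[1L]]
  for (k in seq.int(kmax, 1L)) {
    for (a in 0L:k) {
      x <- circ_at(ch, seq.int(d_start - a, d_start - a + k - 1L))
      y <- circ_at(ch, seq.int(d_end + 1L - a, d_end + 1L - a + k - 1L))
      if (all(x == y)) return(k)
    }
  }
  0L
}

# longest junction-flush repeat on one side allowing max_mm mismatches,
# by direct substring comparison at every k
brute_k_side <- function(seq, d_start, d_end, side, max_mm = 1L, kcap = 60L) {
  ch <- strsplit(seq, "")[[1L]]
  gap <- d_end - d_start + 1L
  best <- 0L
  for (k in seq_len(min(kcap, gap))) {
    if (side == "five") {
      del_part <- circ_at(ch, seq.int(d_end - k + 1L, d_end))
      flank <- circ_at(ch, seq.int(d_start - k, d_start - 1L))
    } else {
      del_part <- circ_at(ch, seq.int(d_start, d_start + k - 1L))
      flank <- circ_at(ch, seq.int(d_end + 1L, d_end + k))
    }
    if (sum(del_part != flank) <= max_mm) best <- k
  }
  best
}

# transitive closure clustering at max-coordinate distance <= threshold
brute_clusters <- function(calls, threshold) {
  n <- nrow(calls)
  member <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      d <- max(abs(calls$d_start[i] - calls$d_start[j]),
               abs(calls$d_end[i] - calls$d_end[j]))
      if (d <= threshold && member[i] != member[j]) {
        member[member == max(member[i], member[j])] <-
          min(member[i], member[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(member, sort(unique(member)))
}

# brute-force membership of position p in a (possibly wrapping) interval
brute_contains <- function(start, end, wraps, p, L) {
  pos <- if (wraps) c(seq.int(start, L), seq.int(1L, end))
         else seq.int(start, end)
  p %in% pos
}
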