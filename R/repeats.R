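base_match <- function(x, y) !is.na(x) & !is.na(y) & x == y & x != "N"

#' Longest exact direct repeat overlapping a deletion's two breakpoints
#'
#' Slides the junction left and right: `a` is the largest count such that
#' `ref[d_start - j] == ref[d_end + 1 - j]` for `j = 1..a`, and `b` the
#' largest count such that `ref[d_start + j] == ref[d_end + 1 + j]` for
#' `j = 0..b-1`. The longest exact match overlapping both breakpoints then
#' has length `k_exact = a + b`, spanning `ref[(d_start - a) ..
#' (d_start + b - 1)]`, and equals both the classic retained-copy direct
#' repeat length of a copy-choice event and the junction's breakpoint-sliding
#' ambiguity. The search extends as far as bases keep matching (capped by the
#' retained-arc length on circular references; truncated at the sequence ends
#' on linear ones).
#'
#' @param d_start,d_end deleted interval (1-based inclusive; `d_end` may be
#'   given unwrapped, i.e. `> L`, for wrapping calls).
#' @param ref a [circular_reference()].
#' @return list with `k_exact`, `repeat_seq`, `left_slide`, `right_slide`.
#' @examples
#' rp <- repeat_plan("ACCTCCCTCACCA", 8470, 13447)
#' ref <- make_reference(16569, repeat_plans = list(rp), seed = 1)
#' del <- plant_copy_choice_deletion(ref, rp, "five_prime")
#' longest_exact_repeat(del$d_start, del$d_end, ref)$k_exact  # 13
#' @export
longest_exact_repeat <- function(d_start, d_end, ref) {
  d_start <- as.integer(d_start); d_end <- as.integer(d_end)
  if (d_end < d_start) stop("d_end < d_start (pass wrapping calls unwrapped)")
  gap <- d_end - d_start + 1L
  cap <- if (ref$circular) ref$length - gap else ref$length
  if (cap < 0L) stop("deleted interval longer than the reference")
  a <- 0L
  while (a < cap &&
         base_match(ref_bases(ref, d_start - 1L - a),
                    ref_bases(ref, d_end - a))) a <- a + 1L
  b <- 0L
  while (b < cap - a &&
         base_match(ref_bases(ref, d_start + b),
                    ref_bases(ref, d_end + 1L + b))) b <- b + 1L
  k <- a + b
  seq <- if (k > 0L)
    paste(ref_bases(ref, seq.int(d_start - a, d_start + b - 1L)),
          collapse = "") else ""
  list(k_exact = k, repeat_seq = seq, left_slide = a, right_slide = b)
}

# longest flush-anchored repeat with at most max_mismatch mismatches; mism is
# a logical mismatch vector ordered outward from the junction.
longest_mm_run <- function(mism, max_mismatch) {
  if (length(mism) == 0L) return(0L)
  cm <- cumsum(mism)
  ok <- which(cm <= max_mismatch)
  if (length(ok) == 0L) 0L else max(ok)
}

#' Orient an imperfect-repeat junction: 5' vs 3' retention
#'
#' Only junctions whose breakpoints are determined to within
#' `max_uncertainty` bp (i.e. exact sliding `<= max_uncertainty`) are
#' informative; others return `"not_informative"`. For informative calls,
#' `k5` is the longest match (allowing `max_mismatch` mismatches) between the
#' deleted segment's 3'-terminal bases and the retained 5' flank (evidence
#' that the 5' copy was retained and the downstream copy lost), and `k3` the
#' longest match between the deleted segment's 5'-terminal bases and the
#' retained 3' flank. Both comparisons anchor flush at the junction, without
#' internal gaps. The call is labelled `"five_prime"` when
#' `k5 - k3 >= delta_min`, `"three_prime"` when `k3 - k5 >= delta_min`, and
#' `"unclassified"` otherwise. The `max_k` search cap is extended
#' automatically whenever it is attained.
#'
#' @param d_start,d_end deleted interval (unwrapped if wrapping).
#' @param ref a [circular_reference()].
#' @param sliding the call's exact junction sliding; computed from the
#'   reference when `NULL`.
#' @param max_uncertainty maximum tolerated breakpoint ambiguity in bp.
#' @param max_mismatch mismatches allowed inside the imperfect repeat.
#' @param delta_min minimum `|k5 - k3|` needed to assign a side.
#' @param max_k initial repeat-length search cap.
#' @return list with `k5`, `k3`, `direction` in
#'   `{"five_prime","three_prime","unclassified","not_informative"}`.
#' @export
directionality <- function(d_start, d_end, ref, sliding = NULL,
                           max_uncertainty = 1L, max_mismatch = 1L,
                           delta_min = 2L, max_k = 30L) {
  d_start <- as.integer(d_start); d_end <- as.integer(d_end)
  if (is.null(sliding))
    sliding <- longest_exact_repeat(d_start, d_end, ref)$k_exact
  if (sliding > max_uncertainty) {
    return(list(k5 = NA_integer_, k3 = NA_integer_,
                direction = "not_informative"))
  }
  gap <- d_end - d_start + 1L
  search_k <- function(K) {
    K <- min(K, gap)  # a flush repeat cannot outgrow the deleted segment
    j <- seq_len(K)
    # k5: deleted-segment suffix vs retained 5' flank suffix
    m5 <- !base_match(ref_bases(ref, d_end + 1L - j),
                      ref_bases(ref, d_start - j))
    # k3: deleted-segment prefix vs retained 3' flank prefix
    m3 <- !base_match(ref_bases(ref, d_start - 1L + j),
                      ref_bases(ref, d_end + j))
    list(k5 = longest_mm_run(m5, max_mismatch),
         k3 = longest_mm_run(m3, max_mismatch), cap = K)
  }
  K <- as.integer(max_k)
  repeat {
    res <- search_k(K)
    if ((res$k5 < res$cap && res$k3 < res$cap) || res$cap >= gap) break
    K <- K * 2L
  }
  direction <- if (res$k5 - res$k3 >= delta_min) "five_prime"
    else if (res$k3 - res$k5 >= delta_min) "three_prime"
    else "unclassified"
  list(k5 = res$k5, k3 = res$k3, direction = direction)
}

#' Annotate segment calls with junction-repeat metrics
#'
#' Adds, per call: `k_exact` and `repeat_seq` from [longest_exact_repeat()],
#' the recomputed `sliding` (identical to `k_exact` by construction), and
#' `k5`, `k3`, `direction` from [directionality()].
#'
#' @param calls a `segment_calls` data.frame (or any data.frame with
#'   `d_start`, `d_end`, optionally `wraps`).
#' @param ref a [circular_reference()].
#' @param ... directionality parameters (`max_uncertainty`, `max_mismatch`,
#'   `delta_min`, `max_k`).
#' @return `calls` with annotation columns appended.
#' @export
annotate_repeats <- function(calls, ref, ...) {
  n <- nrow(calls)
  k_exact <- integer(n); repeat_seq <- character(n)
  k5 <- integer(n); k3 <- integer(n); direction <- character(n)
  wraps <- if ("wraps" %in% names(calls)) calls$wraps else rep(FALSE, n)
  for (i in seq_len(n)) {
    de <- calls$d_end[i] + if (wraps[i]) ref$length else 0L
    ler <- longest_exact_repeat(calls$d_start[i], de, ref)
    k_exact[i] <- ler$k_exact
    repeat_seq[i] <- ler$repeat_seq
    dd <- directionality(calls$d_start[i], de, ref, sliding = ler$k_exact, ...)
    k5[i] <- dd$k5; k3[i] <- dd$k3; direction[i] <- dd$direction
  }
  calls$k_exact <- k_exact
  calls$repeat_seq <- repeat_seq
  calls$sliding <- k_exact
  calls$k5 <- k5
  calls$k3 <- k3
  calls$direction <- direction
  calls
}

#' Randomized-breakpoint null ensemble
#'
#' Generates `n_sets` synthetic deletion sets, each of the same cardinality
#' as the observed set, inside `region`. The default `"length_matched"`
#' scheme draws each start uniformly in the region and a length resampled
#' with replacement from the observed deletion lengths (rejecting deletions
#' that leave the region), so each null set matches the observed set in both
#' count and length distribution. The `"uniform"` scheme draws both
#' breakpoints uniformly subject to a minimum gap.
#'
#' @param observed a `segment_calls` data.frame (only `d_start`/`d_end` are
#'   used).
#' @param ref a [circular_reference()].
#' @param region a [genomic_interval()]; defaults to the span of the observed
#'   breakpoints.
#' @param n_sets number of null sets (default 100).
#' @param scheme `"length_matched"` or `"uniform"`.
#' @param min_gap minimum deletion length for the uniform scheme.
#' @param seed integer seed; the ensemble is deterministic given the seed.
#' @return object of class `null_ensemble`: `sets` (list of data.frames with
#'   `d_start`, `d_end`), `n_sets`, `scheme`, `region`, `seed`.
#' @export
randomize_breakpoints <- function(observed, ref, region = NULL, n_sets = 100L,
                                  scheme = c("length_matched", "uniform"),
                                  min_gap = 100L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (nrow(observed) == 0L) stop("observed set is empty")
  if (is.null(region)) {
    region <- genomic_interval(min(observed$d_start), max(observed$d_end))
  }
  lo <- region$start; hi <- region$end
  if (region$wraps) stop("randomization region must not wrap")
  lens <- observed$d_end - observed$d_start + 1L
  n_obs <- nrow(observed)
  if (scheme == "length_matched" && min(lens) > hi - lo + 1L)
    stop("region too small for any observed deletion length")
  if (scheme == "uniform" && hi - lo + 1L < min_gap)
    stop("region too small for min_gap")
  sets <- with_seed(derive_seed(seed, "randomize_breakpoints"), {
    lapply(seq_len(n_sets), function(si) {
      ds <- integer(n_obs); de <- integer(n_obs)
      for (i in seq_len(n_obs)) {
        repeat {
          if (scheme == "length_matched") {
            len <- sample(lens, 1L)
            s <- sample.int(hi - lo + 1L, 1L) + lo - 1L
            e <- s + len - 1L
          } else {
            s <- sample.int(hi - lo + 1L, 1L) + lo - 1L
            e <- sample.int(hi - lo + 1L, 1L) + lo - 1L
            if (e < s) { tmp <- s; s <- e; e <- tmp }
            if (e - s + 1L < min_gap) next
          }
          if (e <= hi) { ds[i] <- s; de[i] <- e; break }
        }
      }
      data.frame(d_start = ds, d_end = de)
    })
  })
  structure(list(sets = sets, n_sets = as.integer(n_sets), scheme = scheme,
                 region = region, seed = as.integer(seed)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d sets of %d deletions, scheme '%s', region [%d, %d]\n",
              x$n_sets, nrow(x$sets[[1L]]), x$scheme,
              x$region$start, x$region$end))
  invisible(x)
}

#' Repeat-length enrichment of observed deletions over the null ensemble
#'
#' For each exact-repeat length `k` the table reports the observed fraction
#' of deletions with `k_exact == k` (and the cumulative `k_exact >= k`
#' variant), the null mean and standard deviation over ensemble sets, and the
#' fold enrichment `observed / null mean` (absent where the null mean is 0).
#' The cumulative column is the default for quoting fold enrichment "at k bp
#' or above"; both forms are emitted.
#'
#' @param observed annotated calls (must carry `k_exact`; see
#'   [annotate_repeats()]).
#' @param null a [randomize_breakpoints()] ensemble.
#' @param ref the [circular_reference()] (used to annotate the null sets).
#' @return data.frame of class `enrichment_table`: `k`, `obs_freq`,
#'   `null_mean`, `null_sd`, `fold`, and the `_cum` counterparts.
#' @export
repeat_enrichment <- function(observed, null, ref) {
  stopifnot("k_exact" %in% names(observed), inherits(null, "null_ensemble"))
  null_k <- lapply(null$sets, function(s) {
    vapply(seq_len(nrow(s)), function(i) {
      longest_exact_repeat(s$d_start[i], s$d_end[i], ref)$k_exact
    }, integer(1))
  })
  kmax <- max(observed$k_exact, unlist(null_k), 0L)
  ks <- 0L:kmax
  freq <- function(kv) {
    ex <- vapply(ks, function(k) mean(kv == k), numeric(1))
    cu <- vapply(ks, function(k) mean(kv >= k), numeric(1))
    cbind(ex, cu)
  }
  obs <- freq(observed$k_exact)
  nulls <- lapply(null_k, freq)
  nm_ex <- rowMeans(sapply(nulls, function(x) x[, 1L]))
  nm_cu <- rowMeans(sapply(nulls, function(x) x[, 2L]))
  sd_ex <- apply(sapply(nulls, function(x) x[, 1L]), 1L, stats::sd)
  sd_cu <- apply(sapply(nulls, function(x) x[, 2L]), 1L, stats::sd)
  out <- data.frame(
    k = ks,
    obs_freq = obs[, 1L], null_mean = nm_ex, null_sd = sd_ex,
    fold = ifelse(nm_ex > 0, obs[, 1L] / nm_ex, NA_real_),
    obs_freq_cum = obs[, 2L], null_mean_cum = nm_cu, null_sd_cum = sd_cu,
    fold_cum = ifelse(nm_cu > 0, obs[, 2L] / nm_cu, NA_real_))
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Frequency table of junction repeat patterns
#'
#' Counts distinct `repeat_seq` strings of length at least `min_len`, both
#' per unique deletion and weighted by supporting reads, sorted by count then
#' lexicographically. Junctions without a repeat (`k_exact == 0`) are
#' excluded.
#'
#' @param annotations annotated calls carrying `repeat_seq` (and optionally
#'   `read_support` for the per-read weighting).
#' @param min_len minimum pattern length to report.
#' @return data.frame with `pattern`, `n_unique`, `n_reads`.
#' @export
motif_table <- function(annotations, min_len = 1L) {
  keep <- nchar(annotations$repeat_seq) >= min_len &
    annotations$repeat_seq != ""
  a <- annotations[keep, , drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(pattern = character(0), n_unique = integer(0),
                      n_reads = integer(0)))
  support <- if ("read_support" %in% names(a)) a$read_support
             else rep(1L, nrow(a))
  nu <- tapply(rep(1L, nrow(a)), a$repeat_seq, sum)
  nr <- tapply(support, a$repeat_seq, sum)
  out <- data.frame(pattern = names(nu), n_unique = as.integer(nu),
                    n_reads = as.integer(nr))
  out <- out[order(-out$n_unique, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap of junction repeat patterns between two deletion sets
#'
#' Both sets are first restricted to a common reference region (breakpoints
#' inside `region`); the observed statistic is the fraction of set A's
#' distinct repeat patterns (length >= `min_len`) also present in set B.
#' As a control, set A is replaced by `n_random` randomized-breakpoint sets
#' (length-matched within the region, annotated against `ref`) and the
#' fraction recomputed, yielding an empirical two-sided p-value (doubling the
#' smaller tail, with the +1 correction) and a two-sided rank-sum p-value of
#' the observed value against the null values (reported as an approximation
#' of a Wilcoxon comparison; with a single observed value the two do not
#' coincide and neither is claimed to reproduce any particular published
#' variant).
#'
#' @param ann_a,ann_b annotated call tables (with `d_start`, `d_end`,
#'   `repeat_seq`).
#' @param ref the [circular_reference()] of set A (used for the null sets).
#' @param region a [genomic_interval()] common to the two datasets; defaults
#'   to the intersection of their breakpoint spans.
#' @param min_len minimum pattern length (default 3).
#' @param n_random number of randomized control sets.
#' @param seed integer seed.
#' @return list of class `overlap_report`: `observed`, `null_fractions`,
#'   `p_empirical`, `p_ranktest`, `patterns_a`, `patterns_b`, `region`.
#' @export
pattern_overlap <- function(ann_a, ann_b, ref, region = NULL, min_len = 3L,
                            n_random = 100L, seed = 1L) {
  if (is.null(region)) {
    lo <- max(min(ann_a$d_start), min(ann_b$d_start))
    hi <- min(max(ann_a$d_end), max(ann_b$d_end))
    if (lo > hi) stop("the two sets share no common region")
    region <- genomic_interval(lo, hi)
  }
  inside <- function(x) {
    x[x$d_start >= region$start & x$d_end <= region$end, , drop = FALSE]
  }
  a <- inside(ann_a); b <- inside(ann_b)
  pats <- function(x) unique(x$repeat_seq[nchar(x$repeat_seq) >= min_len])
  pa <- pats(a); pb <- pats(b)
  if (length(pa) == 0L || length(pb) == 0L) {
    warning("empty pattern set; overlap undefined")
    return(structure(list(observed = NA_real_, null_fractions = numeric(0),
                          p_empirical = NA_real_, p_ranktest = NA_real_,
                          patterns_a = pa, patterns_b = pb, region = region),
                     class = "overlap_report"))
  }
  observed <- length(intersect(pa, pb)) / length(pa)
  null <- randomize_breakpoints(a, ref, region = region, n_sets = n_random,
                                scheme = "length_matched", seed = seed)
  null_frac <- vapply(null$sets, function(s) {
    s <- annotate_repeats(s, ref)
    p <- pats(s)
    if (length(p) == 0L) return(0)
    length(intersect(p, pb)) / length(p)
  }, numeric(1))
  p_hi <- (1 + sum(null_frac >= observed)) / (1 + n_random)
  p_lo <- (1 + sum(null_frac <= observed)) / (1 + n_random)
  p_emp <- min(1, 2 * min(p_hi, p_lo))
  p_rank <- tryCatch(
    suppressWarnings(stats::wilcox.test(observed, null_frac)$p.value),
    error = function(e) NA_real_)
  structure(list(observed = observed, null_fractions = null_frac,
                 p_empirical = p_emp, p_ranktest = p_rank,
                 patterns_a = pa, patterns_b = pb, region = region),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> observed overlap %.3f (null mean %.3f over %d sets)\n",
              x$observed, mean(x$null_fractions), length(x$null_fractions)))
  cat(sprintf("  p_empirical = %.4g, p_ranktest = %.4g\n",
              x$p_empirical, x$p_ranktest))
  invisible(x)
}

#' Summarize 5'/3' repeat-retention directionality
#'
#' Counts calls by `direction` and reports 5'/3' fractions over the
#' classified informative cases, both per unique deletion and weighted by
#' supporting reads.
#'
#' @param annotations annotated calls carrying `direction` (and
#'   `read_support` for the per-read weighting).
#' @return list with `counts` (named: five_prime, three_prime, unclassified,
#'   not_informative), `reads` (read-weighted counts), `frac_unique` and
#'   `frac_reads` (each `c(five_prime =, three_prime =)`, `NA` when there are
#'   no classified cases).
#' @export
directionality_summary <- function(annotations) {
  lv <- c("five_prime", "three_prime", "unclassified", "not_informative")
  dir <- factor(annotations$direction, levels = lv)
  support <- if ("read_support" %in% names(annotations))
    annotations$read_support else rep(1L, nrow(annotations))
  counts <- as.integer(table(dir))
  names(counts) <- lv
  reads <- vapply(lv, function(d) sum(support[dir == d]), numeric(1))
  frac <- function(v) {
    tot <- v[["five_prime"]] + v[["three_prime"]]
    if (tot == 0) c(five_prime = NA_real_, three_prime = NA_real_)
    else c(five_prime = v[["five_prime"]] / tot,
           three_prime = v[["three_prime"]] / tot)
  }
  list(counts = counts, reads = reads,
       frac_unique = frac(counts), frac_reads = frac(reads))
}
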