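#' Filter gapped alignments on E-value, gap count, flanks and gap length
#'
#' Ungapped alignments are kept whenever their E-value passes (they feed the
#' wild-type denominators of heteroplasmy estimates). Gapped alignments are
#' kept only if all four criteria hold: E-value not above `max_evalue`
#' (strictly greater is rejected), at most `max_gaps` gaps, at least
#' `min_flank` aligned bases on both sides of the gap, and gap length at
#' least `min_gap`.
#'
#' @param alns a `gapped_alignments` data.frame.
#' @param max_evalue reject alignments with E-value strictly above this.
#' @param max_gaps maximum number of reference gaps (default 1).
#' @param min_flank minimum aligned bases on each side of the gap.
#' @param min_gap minimum reference gap length.
#' @return the surviving rows, with `attr(, "filter_log")`: a named integer
#'   vector of per-criterion rejection counts (non-exclusive) plus totals.
#' @export
filter_alignments <- function(alns, max_evalue = 1e-5, max_gaps = 1L,
                              min_flank = 15L, min_gap = 100L) {
  gapped <- alns$n_gaps > 0L
  bad_e <- alns$evalue > max_evalue
  bad_ngap <- gapped & alns$n_gaps > max_gaps
  bad_flank <- gapped & (is.na(alns$q1_len) | is.na(alns$q2_len) |
                           alns$q1_len < min_flank | alns$q2_len < min_flank)
  bad_gaplen <- gapped & alns$gap_length < min_gap
  reject <- bad_e | bad_ngap | bad_flank | bad_gaplen
  out <- alns[!reject, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "aligner") <- attr(alns, "aligner")
  attr(out, "reference") <- attr(alns, "reference")
  attr(out, "filter_log") <- c(
    input = nrow(alns), kept = nrow(out), rejected = sum(reject),
    evalue = sum(bad_e), n_gaps = sum(bad_ngap),
    flank = sum(bad_flank), gap_length = sum(bad_gaplen))
  class(out) <- c("gapped_alignments", "data.frame")
  out
}

# position key describing where a read (and optionally its mate) mapped;
# split-point independent: outermost block coordinates plus the normalized
# deleted interval.
dedup_key <- function(alns, use_mate) {
  last_end <- ifelse(alns$n_gaps > 0L, alns$b2_end, alns$b1_end)
  own <- paste(alns$strand, alns$b1_start, last_end, alns$n_gaps,
               alns$d_start, alns$d_end, sep = ":")
  if (use_mate) {
    has_mate <- !is.na(alns$mate_start)
    own[has_mate] <- paste(own[has_mate], alns$mate_start[has_mate], sep = "|")
  }
  own
}

#' Remove likely PCR duplicates
#'
#' Reads mapped at identical positions are collapsed to one representative
#' (mate positions are taken into account when available; reads whose mate
#' was lost deduplicate on their own position alone). Deterministic: the
#' lexicographically smallest read id in each group is kept.
#'
#' @param alns a `gapped_alignments` data.frame.
#' @param paired whether mate positions (`mate_start`) should enter the key.
#' @return the deduplicated rows with `attr(, "dedup_log")` counts.
#' @export
remove_duplicates <- function(alns, paired = FALSE) {
  if (nrow(alns) == 0L) {
    attr(alns, "dedup_log") <- c(input = 0L, kept = 0L, rejected = 0L)
    return(alns)
  }
  key <- dedup_key(alns, use_mate = paired)
  ord <- order(key, alns$read_id)
  keep_sorted <- !duplicated(key[ord])
  keep <- logical(nrow(alns))
  keep[ord] <- keep_sorted
  out <- alns[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "aligner") <- attr(alns, "aligner")
  attr(out, "reference") <- attr(alns, "reference")
  attr(out, "dedup_log") <- c(input = nrow(alns), kept = nrow(out),
                              rejected = nrow(alns) - nrow(out))
  class(out) <- c("gapped_alignments", "data.frame")
  out
}

#' Remove false gapped alignments caused by linearizing a circular genome
#'
#' When a circular genome is aligned as a linear sequence, a contiguous read
#' crossing the L -> 1 junction shows up as a spurious gapped alignment with
#' one block ending near L and the other starting near 1. Such records are
#' removed: block 1 must end within `window` of L, block 2 must start within
#' `window` of 1. No-op for linear references and for alignments produced by
#' the internal doubled-reference aligner (which never emits this artifact).
#'
#' @param alns a `gapped_alignments` data.frame.
#' @param ref the [circular_reference()].
#' @param window proximity window; default is each record's read length.
#' @return surviving rows with `attr(, "artifact_log")` counts.
#' @export
remove_circular_artifacts <- function(alns, ref, window = NULL) {
  log0 <- c(input = nrow(alns), kept = nrow(alns), rejected = 0L)
  if (!ref$circular || identical(attr(alns, "aligner"), "internal") ||
      nrow(alns) == 0L) {
    attr(alns, "artifact_log") <- log0
    return(alns)
  }
  W <- if (is.null(window)) alns$read_len else rep(as.integer(window), nrow(alns))
  gapped <- alns$n_gaps == 1L
  artifact <- gapped &
    alns$b1_end >= ref$length - W + 1L &
    alns$b2_start <= W
  artifact[is.na(artifact)] <- FALSE
  out <- alns[!artifact, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "aligner") <- attr(alns, "aligner")
  attr(out, "reference") <- attr(alns, "reference")
  attr(out, "artifact_log") <- c(input = nrow(alns), kept = nrow(out),
                                 rejected = sum(artifact))
  class(out) <- c("gapped_alignments", "data.frame")
  out
}

#' Group gapped alignments with identical breakpoints into segment calls
#'
#' One call per distinct leftmost-normalized `(d_start, d_end)` pair; its
#' read support is the number of member alignments. Ungapped alignments do
#' not produce calls. Ordering is deterministic (by coordinates).
#'
#' @param alns a `gapped_alignments` data.frame (filtered/deduplicated).
#' @return a data.frame of class `segment_calls` with columns `d_start`,
#'   `d_end`, `wraps`, `gap_length`, `sliding`, `read_support`.
#' @export
cluster_exact <- function(alns) {
  g <- alns[alns$n_gaps == 1L, , drop = FALSE]
  if (nrow(g) == 0L) {
    out <- data.frame(d_start = integer(0), d_end = integer(0),
                      wraps = logical(0), gap_length = integer(0),
                      sliding = integer(0), read_support = integer(0))
    class(out) <- c("segment_calls", "data.frame")
    return(out)
  }
  key <- paste(g$d_start, g$d_end, g$wraps, sep = ":")
  first <- !duplicated(key)
  out <- data.frame(d_start = g$d_start[first], d_end = g$d_end[first],
                    wraps = g$wraps[first], gap_length = g$gap_length[first],
                    sliding = g$sliding[first],
                    read_support = as.integer(table(key)[key[first]]))
  out <- out[order(out$d_start, out$d_end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("segment_calls", "data.frame")
  out
}

# max-coordinate distance between breakpoint pairs, used for linkage
breakpoint_dist <- function(calls) {
  ds <- outer(calls$d_start, calls$d_start, function(a, b) abs(a - b))
  de <- outer(calls$d_end, calls$d_end, function(a, b) abs(a - b))
  pmax(ds, de)
}

#' Single-linkage clustering of segment calls
#'
#' Calls are linked when `max(|d_start_i - d_start_j|, |d_end_i - d_end_j|)`
#' is at or below `threshold` (inclusive), and clusters are the transitive
#' closure of that relation (single linkage, computed with [stats::hclust()]).
#' Clusters whose total read support is below `min_reads` are flagged
#' (`visualize = FALSE`) rather than dropped, mirroring the convention that
#' the at-least-two-reads rule applies to visualization output while the
#' full table retains everything.
#'
#' @param calls a `segment_calls` data.frame.
#' @param threshold linkage distance threshold in bp (inclusive).
#' @param min_reads minimum total reads for a cluster to be flagged for
#'   visualization.
#' @return a data.frame of class `cluster_summary` (one row per cluster:
#'   representative minimum coordinates, member and read totals, maximum
#'   pairwise breakpoint distance, `visualize`), with the per-call cluster
#'   assignment in `attr(, "membership")`.
#' @export
cluster_linkage <- function(calls, threshold = 50L, min_reads = 2L) {
  n <- nrow(calls)
  if (n == 0L) {
    out <- data.frame(cluster = integer(0), d_start = integer(0),
                      d_end = integer(0), n_calls = integer(0),
                      total_reads = integer(0), max_dist = integer(0),
                      visualize = logical(0))
    class(out) <- c("cluster_summary", "data.frame")
    attr(out, "membership") <- integer(0)
    return(out)
  }
  member <- if (n == 1L) 1L else {
    d <- breakpoint_dist(calls)
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    stats::cutree(hc, h = threshold)
  }
  ids <- sort(unique(member))
  rows <- lapply(ids, function(cid) {
    idx <- which(member == cid)
    sub <- calls[idx, , drop = FALSE]
    md <- if (length(idx) == 1L) 0L else max(breakpoint_dist(sub))
    data.frame(cluster = cid, d_start = min(sub$d_start),
               d_end = min(sub$d_end), n_calls = length(idx),
               total_reads = sum(sub$read_support), max_dist = as.integer(md),
               visualize = sum(sub$read_support) >= min_reads)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$d_start, out$d_end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cluster_summary", "data.frame")
  attr(out, "membership") <- member
  out
}

#' Classify segment calls as deletions or likely duplications
#'
#' A chimeric junction is compatible with either deletion of the enclosed arc
#' or duplication of the complementary arc. Since a genuine deletion of a
#' region containing a replication origin would not propagate, calls whose
#' putative deleted interval overlaps OriH or OriL (by at least 1 bp) are
#' reclassified as likely duplications of the complementary arc; all others
#' stay deletions. With no origins configured on the reference, everything is
#' classified "deletion" and `attr(, "origin_warning")` is set.
#'
#' @param calls a `segment_calls` data.frame.
#' @param ref a [circular_reference()] carrying `ori_h` / `ori_l`.
#' @return `calls` with an added `classification` column.
#' @export
classify_del_dup <- function(calls, ref) {
  if (is.null(ref$ori_h) && is.null(ref$ori_l)) {
    calls$classification <- rep("deletion", nrow(calls))
    attr(calls, "origin_warning") <- TRUE
    return(calls)
  }
  hit <- logical(nrow(calls))
  for (ori in list(ref$ori_h, ref$ori_l)) {
    if (is.null(ori)) next
    ow <- ori[1L] > ori[2L]  # stored wrapping origin interval
    hit <- hit | mapply(function(s, e, w) {
      intervals_overlap(s, e, w, ori[1L], ori[2L], ow, ref$length)
    }, calls$d_start, calls$d_end, calls$wraps)
  }
  calls$classification <- ifelse(hit, "likely_duplication", "deletion")
  calls
}

# number of ungapped alignments covering position p with >= min_flank bases
# at p and on each side; block coordinates may be unwrapped (doubled) on
# circular references, so the position is checked at p and p + L.
count_spanning <- function(alns, p, min_flank, L, circular) {
  u <- alns[alns$n_gaps == 0L, , drop = FALSE]
  if (nrow(u) == 0L) return(0L)
  span_at <- function(pp) {
    u$b1_start <= pp - min_flank + 1L & u$b1_end >= pp + min_flank - 1L
  }
  hit <- span_at(p)
  if (circular) hit <- hit | span_at(p + L)
  sum(hit)
}

#' Estimate per-call heteroplasmy from junction and wild-type reads
#'
#' At each of a call's two breakpoints the junction fraction is
#' `f = g / (g + w)`, where `g` is the call's junction read support and `w`
#' the number of ungapped (wild-type) reads spanning that reference position
#' with at least `min_flank` bases on both sides; the call's heteroplasmy is
#' the mean of the two fractions. The fraction form (rather than the ratio
#' `g / w`) keeps the estimate a proportion in `[0, 1]`.
#'
#' @param calls a `segment_calls` data.frame.
#' @param alns the filtered alignments (must still contain the ungapped ones).
#' @param ref the [circular_reference()].
#' @param min_flank flank requirement for a wild-type read to count.
#' @return `calls` with added columns `het_g`, `het_w5`, `het_w3`,
#'   `heteroplasmy`.
#' @export
heteroplasmy <- function(calls, alns, ref, min_flank = 15L) {
  n <- nrow(calls)
  g <- calls$read_support
  w5 <- integer(n); w3 <- integer(n)
  for (i in seq_len(n)) {
    p5 <- pos_fold(calls$d_start[i] - 1L, ref$length)
    p3 <- pos_fold(calls$d_end[i] + 1L, ref$length)
    w5[i] <- count_spanning(alns, p5, min_flank, ref$length, ref$circular)
    w3[i] <- count_spanning(alns, p3, min_flank, ref$length, ref$circular)
  }
  f5 <- ifelse(g + w5 > 0L, g / (g + w5), NA_real_)
  f3 <- ifelse(g + w3 > 0L, g / (g + w3), NA_real_)
  calls$het_g <- g
  calls$het_w5 <- w5
  calls$het_w3 <- w3
  calls$heteroplasmy <- rowMeans(cbind(f5, f3), na.rm = TRUE)
  calls$heteroplasmy[is.nan(calls$heteroplasmy)] <- NA_real_
  calls$heteroplasmy[g == 0L] <- 0
  calls
}
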