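#' Parameters of the internal split aligner
#'
#' The aligner is exact-seed anchored: it looks for exact occurrences of the
#' read's first and last `seed_len` bases, extends each anchor with up to
#' `max_mismatch_per_block` substitutions per block, and represents the read
#' either as a single ungapped block or as two colinear blocks separated by
#' one reference gap. Substitution-only: no indels inside blocks. Scoring for
#' model selection is `matches - 3 * mismatches - gap_open` per candidate,
#' with ties broken toward the ungapped model and the leftmost placement.
#'
#' @param seed_len exact anchor length (default 15, the same value as the
#'   minimum flank used downstream, so no aligner-passing split read is
#'   trivially rejected by the flank filter).
#' @param max_mismatch_per_block maximum substitutions tolerated per block.
#' @param gap_open score penalty for opening the single gap.
#' @param max_seed_hits at most this many anchor occurrences are examined per
#'   seed (guards pathological low-complexity reads).
#' @return a list of class `align_params`.
#' @export
align_params <- function(seed_len = 15L, max_mismatch_per_block = 2L,
                         gap_open = 4L, max_seed_hits = 50L) {
  structure(list(seed_len = as.integer(seed_len),
                 max_mismatch_per_block = as.integer(max_mismatch_per_block),
                 gap_open = as.integer(gap_open),
                 max_seed_hits = as.integer(max_seed_hits)),
            class = "align_params")
}

# Build the alignment context: circular references are aligned against a
# doubled sequence (so reads crossing the L -> 1 junction align as a single
# ungapped block) with all reported coordinates folded back into 1..L.
align_context <- function(ref, params) {
  subj <- if (ref$circular) paste0(ref$sequence, ref$sequence) else ref$sequence
  list(ref = ref, params = params,
       subject = Biostrings::DNAString(subj),
       schars = strsplit(subj, "", fixed = TRUE)[[1L]],
       L = ref$length, n_subj = nchar(subj), circular = ref$circular)
}

seed_hits <- function(pattern, ctx) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), ctx$subject)
  IRanges::start(m)
}

# one empty row template for the alignment table
aln_row <- function(read_id = NA_character_, strand = "+", n_gaps = 0L,
                    b1_start = NA_integer_, b1_end = NA_integer_,
                    b2_start = NA_integer_, b2_end = NA_integer_,
                    q1_len = NA_integer_, q2_len = NA_integer_,
                    mismatches = 0L, gap_length = 0L,
                    d_start = NA_integer_, d_end = NA_integer_,
                    wraps = FALSE, sliding = 0L, score = NA_real_,
                    evalue = NA_real_, read_len = NA_integer_,
                    mate_start = NA_integer_) {
  data.frame(read_id = read_id, strand = strand, n_gaps = n_gaps,
             b1_start = b1_start, b1_end = b1_end, b2_start = b2_start,
             b2_end = b2_end, q1_len = q1_len, q2_len = q2_len,
             mismatches = mismatches, gap_length = gap_length,
             d_start = d_start, d_end = d_end, wraps = wraps,
             sliding = sliding, score = score, evalue = evalue,
             read_len = read_len, mate_start = mate_start,
             stringsAsFactors = FALSE)
}

# Align one oriented read; returns the best candidate row (without read_id /
# strand / evalue filled in) or NULL.
align_oriented <- function(rc, ctx) {
  n <- length(rc)
  p <- ctx$params
  sl <- p$seed_len
  subj <- ctx$schars
  # fast path: exact full-length ungapped match
  full <- seed_hits(paste(rc, collapse = ""), ctx)
  full <- full[full <= ctx$L | !ctx$circular]
  if (length(full) > 0L) {
    b1 <- min(full)
    return(aln_row(b1_start = b1, b1_end = b1 + n - 1L, q1_len = n,
                   mismatches = 0L, score = n, read_len = n))
  }
  pref_hits <- seed_hits(paste(rc[seq_len(sl)], collapse = ""), ctx)
  pref_hits <- pref_hits[pref_hits + n - 1L <= ctx$n_subj]
  if (ctx$circular) pref_hits <- pref_hits[pref_hits <= ctx$L]
  if (length(pref_hits) > p$max_seed_hits)
    pref_hits <- pref_hits[seq_len(p$max_seed_hits)]
  suff_hits <- seed_hits(paste(rc[seq.int(n - sl + 1L, n)], collapse = ""), ctx)
  suff_ends <- suff_hits + sl - 1L
  suff_ends <- suff_ends[suff_ends >= n]
  if (length(suff_ends) > p$max_seed_hits)
    suff_ends <- suff_ends[seq_len(p$max_seed_hits)]

  best <- NULL
  consider <- function(cand) {
    if (is.null(best)) return(cand)
    # higher score wins; ties: ungapped first, then leftmost placement
    if (cand$score > best$score) return(cand)
    if (cand$score < best$score) return(best)
    if (cand$n_gaps != best$n_gaps) {
      return(if (cand$n_gaps < best$n_gaps) cand else best)
    }
    key <- function(x) c(x$b1_start, x$d_start %||% NA_integer_)
    if (!is.na(cand$b1_start) && !is.na(best$b1_start) &&
        cand$b1_start < best$b1_start) return(cand)
    best
  }

  cums <- new.env(parent = emptyenv())
  cum_pref <- function(pp) {
    key <- as.character(pp)
    if (!is.null(cums[[key]])) return(cums[[key]])
    v <- cumsum(rc != subj[seq.int(pp, pp + n - 1L)])
    cums[[key]] <- v
    v
  }
  max_mm_ungapped <- 2L * p$max_mismatch_per_block

  # ungapped candidates anchored at prefix seeds
  for (pp in pref_hits) {
    mm <- cum_pref(pp)[n]
    if (mm <= max_mm_ungapped) {
      best <- consider(aln_row(b1_start = pp, b1_end = pp + n - 1L,
                               q1_len = n, mismatches = mm,
                               score = n - 3L * mm, read_len = n))
    }
  }
  # ungapped candidates anchored at suffix seeds
  for (qe in suff_ends) {
    pp <- qe - n + 1L
    if (pp < 1L) next
    if (ctx$circular && pp > ctx$L) pp <- pp - ctx$L
    if (pp + n - 1L > ctx$n_subj) next
    mm <- cum_pref(pp)[n]
    if (mm <= max_mm_ungapped) {
      best <- consider(aln_row(b1_start = pp, b1_end = pp + n - 1L,
                               q1_len = n, mismatches = mm,
                               score = n - 3L * mm, read_len = n))
    }
  }
  # gapped candidates: one prefix anchor + one suffix anchor, one gap
  if (n >= 2L * sl) {
    s_range <- seq.int(sl, n - sl)
    for (pp in pref_hits) {
      c1 <- cum_pref(pp)
      for (qe in suff_ends) {
        gap <- qe - n + 1L - pp
        if (gap < 1L) next
        if (ctx$circular && gap > ctx$L - 1L) next
        v2 <- rc != subj[seq.int(qe - n + 1L, qe)]
        c2 <- cumsum(v2)
        tot2 <- c2[n]
        mm_split <- c1[s_range] + (tot2 - c2[s_range])
        ok <- c1[s_range] <= p$max_mismatch_per_block &
              (tot2 - c2[s_range]) <= p$max_mismatch_per_block
        if (!any(ok)) next
        mm_min <- min(mm_split[ok])
        hits <- s_range[ok & mm_split == mm_min]
        s <- hits[1L]
        cand <- aln_row(n_gaps = 1L,
                        b1_start = pp, b1_end = pp + s - 1L,
                        b2_start = pp + s + gap, b2_end = qe,
                        q1_len = s, q2_len = n - s,
                        mismatches = mm_min, gap_length = gap,
                        d_start = pp + s, d_end = pp + s + gap - 1L,
                        sliding = length(hits) - 1L,
                        score = n - 3L * mm_min - p$gap_open, read_len = n)
        best <- consider(cand)
      }
    }
  }
  best
}

# Leftmost junction normalization at the reference level: slide the deleted
# interval left while the base entering the junction equals the base leaving
# it, and measure the total slide range (= the exact junction repeat length).
# Works in unwrapped coordinates (d_end may exceed L on circular references).
normalize_junction <- function(ref, d_start, d_end) {
  L <- ref$length
  gap <- d_end - d_start + 1L
  cap <- if (ref$circular) L - gap else ref$length
  match_at <- function(a, b) {
    x <- ref_bases(ref, a); y <- ref_bases(ref, b)
    !is.na(x) & !is.na(y) & x == y & x != "N"
  }
  a <- 0L
  while (a < cap && match_at(d_start - 1L - a, d_end - a)) a <- a + 1L
  b <- 0L
  while (b < cap - a && match_at(d_start + b, d_end + 1L + b)) b <- b + 1L
  d_start <- d_start - a
  d_end <- d_end - a
  if (ref$circular) {
    if (d_start < 1L) { d_start <- d_start + L; d_end <- d_end + L }
    if (d_start > L) { d_start <- d_start - L; d_end <- d_end - L }
  }
  list(d_start = d_start, d_end = d_end, sliding = a + b,
       wraps = ref$circular && d_end > L)
}

# fold an unwrapped interval into reporting coordinates
fold_interval <- function(d_start, d_end, L, circular) {
  if (!circular) return(list(d_start = d_start, d_end = d_end, wraps = FALSE))
  ds <- pos_fold(d_start, L)
  shift <- ds - d_start
  de <- d_end + shift
  list(d_start = ds, d_end = if (de > L) de - L else de, wraps = de > L)
}

#' Align reads against a reference with the internal split aligner
#'
#' Each read is aligned on both strands and reported on the forward reference
#' strand, as one ungapped block or two colinear blocks separated by a single
#' reference gap. Circular references are aligned against a doubled sequence,
#' so reads genuinely crossing the L -> 1 junction come back ungapped (never
#' as spurious gapped alignments). Gapped junctions are normalized to the
#' leftmost placement at the reference level and annotated with their sliding
#' range, so all reads over the same (possibly repeat-ambiguous) junction
#' normalize to identical breakpoints. Reads shorter than `seed_len` are
#' skipped and listed in `attr(, "skipped")`.
#'
#' @param reads named character vector of read sequences (or a single string).
#' @param ref a [circular_reference()].
#' @param params an [align_params()].
#' @return a data.frame of class `gapped_alignments`, one row per aligned
#'   read: block coordinates (`b1_*`, `b2_*`, unwrapped on the doubled
#'   reference for circular inputs), read flank lengths (`q1_len`, `q2_len`),
#'   `mismatches`, `gap_length`, normalized deleted interval
#'   (`d_start`, `d_end`, `wraps`, `sliding`), `score` and `evalue`.
#' @export
split_align <- function(reads, ref, params = align_params()) {
  stopifnot(inherits(ref, "circular_reference"), inherits(params, "align_params"))
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%04d", seq_along(reads))
  reads <- toupper(reads)
  ctx <- align_context(ref, params)
  skipped <- character(0)
  rows <- vector("list", length(reads))
  nc <- nchar(reads)

  # batch fast path: leftmost exact full-length occurrence of every read
  # (forward and reverse-complement), via an Aho-Corasick dictionary per
  # read-width class; anything unresolved falls through to seed-and-extend.
  exact_pos <- rep(NA_integer_, length(reads))
  exact_strand <- rep(NA_character_, length(reads))
  batch_exact <- function(seqs) {
    hits <- tryCatch({
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs))
      Biostrings::startIndex(Biostrings::matchPDict(pd, ctx$subject))
    }, error = function(e) NULL)
    if (is.null(hits)) return(rep(NA_integer_, length(seqs)))
    vapply(hits, function(st) {
      if (ctx$circular) st <- st[st <= ctx$L]
      if (length(st) == 0L) NA_integer_ else min(st)
    }, integer(1))
  }
  for (w in unique(nc[nc >= params$seed_len])) {
    idx <- which(nc == w)
    if (length(idx) < 5L) next
    fpos <- batch_exact(reads[idx])
    exact_pos[idx] <- fpos
    exact_strand[idx][!is.na(fpos)] <- "+"
    todo <- idx[is.na(fpos)]
    if (length(todo) > 0L) {
      rpos <- batch_exact(vapply(reads[todo], revcomp, character(1)))
      exact_pos[todo] <- rpos
      exact_strand[todo][!is.na(rpos)] <- "-"
    }
  }

  for (i in seq_along(reads)) {
    r <- reads[[i]]
    id <- names(reads)[i]
    if (nchar(r) < params$seed_len) {
      skipped <- c(skipped, id)
      next
    }
    if (!is.na(exact_pos[i])) {
      n <- nc[i]
      cand <- aln_row(b1_start = exact_pos[i], b1_end = exact_pos[i] + n - 1L,
                      q1_len = n, mismatches = 0L, score = n, read_len = n)
      strand <- exact_strand[i]
    } else {
      fwd <- align_oriented(strsplit(r, "", fixed = TRUE)[[1L]], ctx)
      cand <- fwd; strand <- "+"
      if (is.null(fwd) || fwd$mismatches > 0L || fwd$n_gaps > 0L) {
        rev <- align_oriented(strsplit(revcomp(r), "", fixed = TRUE)[[1L]], ctx)
        if (!is.null(rev) && (is.null(fwd) || rev$score > fwd$score)) {
          cand <- rev; strand <- "-"
        }
      }
    }
    if (is.null(cand)) next
    cand$read_id <- id
    cand$strand <- strand
    if (cand$n_gaps == 1L) {
      nj <- normalize_junction(ctx$ref, cand$d_start, cand$d_end)
      fi <- fold_interval(nj$d_start, nj$d_end, ctx$L, ctx$circular)
      cand$d_start <- fi$d_start; cand$d_end <- fi$d_end
      cand$wraps <- fi$wraps; cand$sliding <- nj$sliding
    }
    cand$evalue <- evalue_karlin(cand$read_len - cand$mismatches,
                                 cand$mismatches, cand$read_len, ctx$L)
    rows[[i]] <- cand
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else aln_row()[0, ]
  rownames(out) <- NULL
  # mate linkage for "/1"-"/2" read-id pairs, used by duplicate removal
  if (nrow(out) > 0L) {
    mate_no <- sub("^.*/([12])$", "\\1", out$read_id)
    is_pair <- mate_no %in% c("1", "2")
    if (any(is_pair)) {
      frag <- sub("/[12]$", "", out$read_id)
      mate_id <- ifelse(is_pair,
                        paste0(frag, "/", ifelse(mate_no == "1", "2", "1")),
                        NA_character_)
      out$mate_start <- out$b1_start[match(mate_id, out$read_id)]
    }
  }
  class(out) <- c("gapped_alignments", "data.frame")
  attr(out, "aligner") <- "internal"
  attr(out, "skipped") <- skipped
  attr(out, "reference") <- ref$name
  out
}

# Karlin-Altschul ungapped lambda for match +1 / mismatch -2 under uniform
# base composition; cached after the first call.
ka_env <- new.env(parent = emptyenv())
ka_lambda <- function() {
  if (is.null(ka_env$lambda)) {
    f <- function(l) (4 * exp(l) + 12 * exp(-2 * l)) / 16 - 1
    ka_env$lambda <- stats::uniroot(f, c(1e-6, 5), tol = 1e-12)$root
  }
  ka_env$lambda
}

evalue_karlin <- function(matches, mismatches, m, n_ref, K = 0.1) {
  s <- matches - 2 * mismatches
  K * m * n_ref * exp(-ka_lambda() * s)
}

#' Expect-value analog of an alignment
#'
#' Returns the alignment's ingested E-value when one is present (e.g. carried
#' over from an external aligner's SAM tag); otherwise computes a
#' Karlin-Altschul-style expect value `E = K * m * n * exp(-lambda * S)` with
#' match score +1, mismatch score -2, `S = matches - 2 * mismatches` summed
#' over blocks, `m` the aligned read length, `n` the reference length,
#' `lambda` solved for uniform base composition (about 1.34) and `K = 0.1`.
#' Monotone decreasing in the alignment score. This analog is not calibrated
#' to any external aligner's E-values; it serves the same filtering role.
#'
#' @param aln one row of a `gapped_alignments` table (or a list with fields
#'   `read_len`, `mismatches`, optionally `evalue`).
#' @param ref_length reference length used when computing from scratch.
#' @return a single numeric expect value.
#' @export
score_alignment <- function(aln, ref_length) {
  if (!is.null(aln$evalue) && length(aln$evalue) == 1L && !is.na(aln$evalue))
    return(as.numeric(aln$evalue))
  evalue_karlin(aln$read_len - aln$mismatches, aln$mismatches,
                aln$read_len, ref_length)
}

#' Ingest gapped alignments from SAM/BAM
#'
#' Accepts alignments produced by an external aligner, with deletions encoded
#' as `D`/`N` CIGAR operations; records with more than one gap keep their
#' `n_gaps` (the downstream filter rejects them), unmapped and secondary
#' records are skipped, and records whose CIGAR contains insertions are
#' skipped with a warning (the pipeline's blocks are substitution-only).
#' Junctions of single-gap records are leftmost-normalized against `ref` and
#' annotated with their sliding range. An E-value can be carried in an
#' optional SAM tag (default `ZE`); when absent it is computed with
#' [score_alignment()] assuming zero mismatches (SAM records carry no
#' mismatch count without an MD tag).
#'
#' @param path SAM or BAM file.
#' @param ref the [circular_reference()] the records were aligned to.
#' @param evalue_tag optional SAM tag holding a per-record E-value.
#' @return a `gapped_alignments` data.frame (see [split_align()]), with
#'   `attr(, "aligner") = "external"` so that circular-artifact removal is
#'   applied.
#' @export
read_sam <- function(path, ref, evalue_tag = "ZE") {
  stopifnot(inherits(ref, "circular_reference"))
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) path else
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mrnm", "mpos"),
    tag = evalue_tag,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)
  if (length(ga) == 0L) {
    out <- aln_row()[0, ]
    class(out) <- c("gapped_alignments", "data.frame")
    attr(out, "aligner") <- "external"
    return(out)
  }
  cig <- GenomicAlignments::cigar(ga)
  has_indel <- grepl("[I]", cig)
  if (any(has_indel)) {
    warning(sum(has_indel), " record(s) with insertions skipped")
  }
  mcols <- S4Vectors::mcols(ga)
  ev_tags <- if (!is.null(mcols[[evalue_tag]])) mcols[[evalue_tag]]
             else rep(NA_real_, length(ga))
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = BiocGenerics::start(ga), ops = c("M", "=", "X"))
  qlens <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cig, ops = c("M", "=", "X"))
  rows <- vector("list", length(ga))
  for (i in seq_along(ga)) {
    if (has_indel[i]) next
    b <- blocks[[i]]
    nb <- length(b)
    n_gaps <- nb - 1L
    bs <- IRanges::start(b); be <- IRanges::end(b)
    ql <- IRanges::width(qlens[[i]])
    strand <- if (bitwAnd(mcols$flag[i], 16L) > 0L) "-" else "+"
    read_len <- sum(ql)
    row <- aln_row(read_id = mcols$qname[i], strand = strand,
                   n_gaps = n_gaps,
                   b1_start = bs[1L], b1_end = be[1L],
                   q1_len = ql[1L], mismatches = 0L,
                   read_len = read_len,
                   mate_start = if (!is.na(mcols$mpos[i]) && mcols$mpos[i] > 0L)
                     as.integer(mcols$mpos[i]) else NA_integer_,
                   evalue = as.numeric(ev_tags[i]))
    if (n_gaps >= 1L) {
      row$b2_start <- bs[nb]; row$b2_end <- be[nb]
      row$q2_len <- ql[nb]
      row$gap_length <- bs[2L] - be[1L] - 1L
      if (n_gaps == 1L) {
        nj <- normalize_junction(ref, be[1L] + 1L, bs[2L] - 1L)
        fi <- fold_interval(nj$d_start, nj$d_end, ref$length, ref$circular)
        row$d_start <- fi$d_start; row$d_end <- fi$d_end
        row$wraps <- fi$wraps; row$sliding <- nj$sliding
      } else {
        row$d_start <- be[1L] + 1L
        row$d_end <- bs[2L] - 1L
      }
    } else {
      row$gap_length <- 0L
    }
    if (is.na(row$evalue))
      row$evalue <- evalue_karlin(read_len, 0L, read_len, ref$length)
    row$score <- read_len
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else aln_row()[0, ]
  rownames(out) <- NULL
  class(out) <- c("gapped_alignments", "data.frame")
  attr(out, "aligner") <- "external"
  attr(out, "reference") <- ref$name
  out
}
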