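#' Circular reference sequence with replication-origin annotations
#'
#' Container for an mtDNA-like reference: an uppercase A/C/G/T sequence,
#' a circularity flag, and optional closed intervals for the heavy-strand
#' (OriH) and light-strand (OriL) replication origins. All coordinates in
#' the package are 1-based and both ends inclusive; on circular references,
#' position arithmetic wraps modulo the sequence length back into `1..L`.
#'
#' @param sequence single uppercase string over A,C,G,T (N allowed only with
#'   `allow_n = TRUE`; an N never matches anything in repeat searches).
#' @param name sequence name.
#' @param circular logical; `TRUE` for circular genomes/templates.
#' @param ori_h,ori_l optional length-2 integer vectors `c(start, end)`
#'   (closed intervals, may wrap on circular references) marking the
#'   replication origins used for deletion/duplication reclassification.
#' @param allow_n permit N characters.
#' @return an object of class `circular_reference` with fields `name`,
#'   `sequence`, `chars` (exploded sequence), `length`, `circular`,
#'   `ori_h`, `ori_l`.
#' @examples
#' ref <- circular_reference("ACGTACGTAC", name = "toy")
#' ref$length
#' @export
circular_reference <- function(sequence, name = "ref", circular = TRUE,
                               ori_h = NULL, ori_l = NULL, allow_n = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alphabet), "", sequence)
  if (nzchar(bad)) {
    stop("reference contains characters outside {", alphabet, "}: ",
         substr(bad, 1L, 10L))
  }
  L <- nchar(sequence)
  check_iv <- function(iv, what) {
    if (is.null(iv)) return(NULL)
    iv <- as.integer(iv)
    if (length(iv) != 2L || any(iv < 1L) || any(iv > L))
      stop(what, " must be c(start, end) within 1..L")
    iv
  }
  structure(list(
    name = as.character(name),
    sequence = sequence,
    chars = strsplit(sequence, "", fixed = TRUE)[[1L]],
    length = L,
    circular = isTRUE(circular),
    ori_h = check_iv(ori_h, "ori_h"),
    ori_l = check_iv(ori_l, "ori_l")
  ), class = "circular_reference")
}

#' @export
print.circular_reference <- function(x, ...) {
  cat(sprintf("<circular_reference> %s: %d bp, %s\n", x$name, x$length,
              if (x$circular) "circular" else "linear"))
  if (!is.null(x$ori_h)) cat(sprintf("  ori_h: [%d, %d]\n", x$ori_h[1], x$ori_h[2]))
  if (!is.null(x$ori_l)) cat(sprintf("  ori_l: [%d, %d]\n", x$ori_l[1], x$ori_l[2]))
  invisible(x)
}

# Fold positions into 1..L (vectorized). Linear references must already be
# in range; circular references wrap modulo L.
pos_fold <- function(p, L) ((p - 1L) %% L) + 1L

check_positions <- function(p, ref) {
  if (any(p < 1L | p > ref$length))
    stop("position out of range 1..", ref$length)
  invisible(p)
}

# Bases at (possibly out-of-range, circular) positions as a character vector.
ref_bases <- function(ref, pos) {
  if (ref$circular) {
    ref$chars[pos_fold(as.integer(pos), ref$length)]
  } else {
    out <- rep(NA_character_, length(pos))
    ok <- pos >= 1L & pos <= ref$length
    out[ok] <- ref$chars[as.integer(pos[ok])]
    out
  }
}

#' Circular distance between two positions
#'
#' The shorter arc between two 1-based positions on a circular reference
#' (`min(|a-b|, L-|a-b|)`); the plain absolute difference on linear
#' references. Symmetric and a metric on `1..L`.
#'
#' @param a,b positions in `1..L`.
#' @param ref a [circular_reference()].
#' @return non-negative integer distance.
#' @examples
#' ref <- circular_reference(strrep("ACGT", 25))
#' circular_distance(1, 100, ref)  # 1: positions adjacent across the origin
#' @export
circular_distance <- function(a, b, ref) {
  check_positions(c(a, b), ref)
  d <- abs(as.integer(a) - as.integer(b))
  if (ref$circular) pmin(d, ref$length - d) else d
}

#' Closed genomic interval, possibly wrapping the circular origin
#'
#' @param start,end 1-based inclusive bounds.
#' @param wraps `TRUE` when the interval crosses the L -> 1 junction of a
#'   circular reference (then `start > end` is allowed).
#' @return object of class `genomic_interval`.
#' @export
genomic_interval <- function(start, end, wraps = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  if (!wraps && start > end) stop("start > end in a non-wrapping interval")
  structure(list(start = start, end = end, wraps = isTRUE(wraps)),
            class = "genomic_interval")
}

# Length of an interval on a reference of length L.
interval_length <- function(iv, L) {
  if (iv$wraps) iv$end - iv$start + 1L + L else iv$end - iv$start + 1L
}

#' Test whether a position lies inside an interval (wrap-aware)
#'
#' @param iv a [genomic_interval()].
#' @param p position in `1..L`.
#' @param ref the [circular_reference()] providing `L` and circularity.
#' @return logical.
#' @export
interval_contains <- function(iv, p, ref) {
  check_positions(p, ref)
  if (iv$start < 1L || iv$end > ref$length && !iv$wraps)
    stop("interval out of range")
  if (iv$wraps) {
    if (!ref$circular) stop("wrapping interval on a linear reference")
    p >= iv$start | p <= iv$end
  } else {
    p >= iv$start & p <= iv$end
  }
}

# Do two closed intervals (a1,a2 non-wrapping or wrapping as flagged) overlap
# by >= 1 bp on a circle of length L? Used for origin reclassification.
intervals_overlap <- function(s1, e1, w1, s2, e2, w2, L) {
  expand <- function(s, e, w) if (w) c(s, e + L) else c(s, e)
  a <- expand(s1, e1, w1); b <- expand(s2, e2, w2)
  # compare on the doubled line; shift each by 0 or L to catch wrap pairings
  for (da in c(0L, L)) for (db in c(0L, L)) {
    if (a[1] + da <= b[2] + db && b[1] + db <= a[2] + da) return(TRUE)
  }
  FALSE
}

#' Read a reference from FASTA
#'
#' Reads a (single- or multi-record) FASTA file via Biostrings; the first
#' record is used unless `record` names one.
#'
#' @param path FASTA file.
#' @param record optional record name to select.
#' @param circular,ori_h,ori_l,allow_n passed to [circular_reference()].
#' @return a [circular_reference()].
#' @export
read_fasta <- function(path, record = NULL, circular = TRUE,
                       ori_h = NULL, ori_l = NULL, allow_n = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  i <- 1L
  if (!is.null(record)) {
    i <- match(record, nm)
    if (is.na(i)) stop("record not found in FASTA: ", record)
  }
  circular_reference(as.character(ss[[i]]), name = nm[i], circular = circular,
                     ori_h = ori_h, ori_l = ori_l, allow_n = allow_n)
}

#' Write a reference (or any named sequences) to FASTA
#'
#' @param ref a [circular_reference()] or a named character vector of
#'   sequences.
#' @param path output file.
#' @return `path`, invisibly. Round-trips with [read_fasta()].
#' @export
write_fasta <- function(ref, path) {
  if (inherits(ref, "circular_reference")) {
    seqs <- stats::setNames(ref$sequence, ref$name)
  } else {
    stopifnot(is.character(ref), !is.null(names(ref)))
    seqs <- ref
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
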