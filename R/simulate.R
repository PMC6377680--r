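#' Plan a pair of direct (or imperfect) repeats to plant in a reference
#'
#' A repeat plan places two copies of `repeat_sequence` at `pos5` and `pos3`
#' (starts of the first and second copy, `pos5 < pos3`). The downstream copy
#' may carry substitutions (`mismatches_in_copy2`), making the pair an
#' imperfect repeat: such junctions can later be oriented as 5'- or
#' 3'-retained, exactly like class II deletions. The prototypical plan is the
#' 13-bp repeat ACCTCCCTCACCA at mtDNA positions 8470 and 13447 that flanks
#' the common deletion.
#'
#' @param repeat_sequence uppercase ACGT string.
#' @param pos5,pos3 1-based start positions of the two copies.
#' @param mismatches_in_copy2 optional data.frame with columns `offset`
#'   (1-based within the repeat) and `base` (the substituted base in copy 2).
#' @return object of class `repeat_plan`.
#' @export
repeat_plan <- function(repeat_sequence, pos5, pos3,
                        mismatches_in_copy2 = NULL) {
  repeat_sequence <- toupper(repeat_sequence)
  stopifnot(grepl("^[ACGT]+$", repeat_sequence))
  k <- nchar(repeat_sequence)
  pos5 <- as.integer(pos5); pos3 <- as.integer(pos3)
  if (pos5 >= pos3) stop("pos5 must be < pos3")
  if (pos5 + k - 1L >= pos3) stop("repeat copies overlap")
  mm <- mismatches_in_copy2
  if (!is.null(mm)) {
    mm <- as.data.frame(mm)
    stopifnot(all(c("offset", "base") %in% names(mm)))
    mm$offset <- as.integer(mm$offset)
    mm$base <- toupper(as.character(mm$base))
    if (any(mm$offset < 1L | mm$offset > k))
      stop("mismatch offset outside the repeat")
    if (nrow(mm) > k) stop("more mismatches than repeat length")
    ref_base <- substring(repeat_sequence, mm$offset, mm$offset)
    if (any(mm$base == ref_base))
      stop("a mismatch base equals the copy-1 base at that offset")
  }
  structure(list(repeat_sequence = repeat_sequence, pos5 = pos5, pos3 = pos3,
                 k = k, mismatches_in_copy2 = mm),
            class = "repeat_plan")
}

# Sequence of copy 2 (with planted substitutions applied).
plan_copy2_seq <- function(plan) {
  ch <- strsplit(plan$repeat_sequence, "", fixed = TRUE)[[1L]]
  mm <- plan$mismatches_in_copy2
  if (!is.null(mm) && nrow(mm) > 0L) ch[mm$offset] <- mm$base
  paste(ch, collapse = "")
}

#' Generate a random circular reference with planted repeat pairs
#'
#' Background bases are i.i.d. with the requested GC content; each plan's two
#' repeat copies are then written verbatim (copy 2 with its planted
#' substitutions). Planted repeats are made *maximal*: the bases immediately
#' flanking the two copies are resampled so that a planted k-bp repeat cannot
#' be extended into a (k+1)-bp repeat by background chance, which keeps the
#' planted repeat length an exact, seed-independent ground truth.
#'
#' @param L reference length (>= 1).
#' @param gc GC fraction of the background (default 0.44, human mtDNA-like).
#' @param repeat_plans list of [repeat_plan()] objects; copies of different
#'   plans must not overlap.
#' @param seed integer seed; the same seed reproduces the same sequence.
#' @param name,circular,ori_h,ori_l passed to [circular_reference()].
#' @return a [circular_reference()].
#' @examples
#' rp <- repeat_plan("ACCTCCCTCACCA", 1000, 2500)
#' ref <- make_reference(4300, repeat_plans = list(rp), seed = 7)
#' substr(ref$sequence, 1000, 1012)
#' @export
make_reference <- function(L, gc = 0.44, repeat_plans = list(), seed = 1,
                           name = "synthetic", circular = TRUE,
                           ori_h = NULL, ori_l = NULL) {
  L <- as.integer(L)
  stopifnot(L >= 1L, gc >= 0, gc <= 1)
  occupied <- integer(0)
  for (pl in repeat_plans) {
    stopifnot(inherits(pl, "repeat_plan"))
    if (pl$pos3 + pl$k - 1L > L) stop("plan does not fit in L")
    span <- c(seq.int(pl$pos5, pl$pos5 + pl$k - 1L),
              seq.int(pl$pos3, pl$pos3 + pl$k - 1L))
    if (any(span %in% occupied)) stop("overlapping repeat plans")
    occupied <- c(occupied, span)
  }
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- with_seed(derive_seed(seed, "make_reference"), {
    ch <- sample(names(probs), L, replace = TRUE, prob = probs)
    for (pl in repeat_plans) {
      c1 <- strsplit(pl$repeat_sequence, "", fixed = TRUE)[[1L]]
      c2 <- strsplit(plan_copy2_seq(pl), "", fixed = TRUE)[[1L]]
      ch[seq.int(pl$pos5, pl$pos5 + pl$k - 1L)] <- c1
      ch[seq.int(pl$pos3, pl$pos3 + pl$k - 1L)] <- c2
    }
    # enforce repeat maximality at the four copy boundaries
    for (pl in repeat_plans) {
      lo <- pos_fold(c(pl$pos5 - 1L, pl$pos3 - 1L), L)
      hi <- pos_fold(c(pl$pos5 + pl$k, pl$pos3 + pl$k), L)
      for (pair in list(lo, hi)) {
        guard <- setdiff(pair, occupied)  # never rewrite a planted copy
        while (ch[pair[1L]] == ch[pair[2L]] && length(guard) > 0L) {
          i <- guard[length(guard)]
          ch[i] <- sample(setdiff(names(probs), ch[i]), 1L)
        }
      }
    }
    ch
  })
  circular_reference(paste(chars, collapse = ""), name = name,
                     circular = circular, ori_h = ori_h, ori_l = ori_l)
}

#' Form a deletion by copy-choice recombination between two repeat copies
#'
#' Emulates template switching during light-strand synthesis: the nascent
#' strand dissociates at one repeat copy, reanneals to the other, and the
#' intervening sequence plus one copy is lost. With
#' `retained_side = "five_prime"` the lower-coordinate copy survives and the
#' deleted interval runs from the base after copy 1's end through copy 2's
#' end; with `"three_prime"` the downstream copy survives and the deleted
#' interval runs from copy 1's start through the base before copy 2's start.
#' Either way the deleted molecule keeps exactly one repeat copy at the
#' junction; for perfect repeats the two choices produce identical molecules.
#'
#' @param ref a [circular_reference()] in which the plan's copies are present.
#' @param plan a [repeat_plan()].
#' @param retained_side `"five_prime"` or `"three_prime"`.
#' @return object of class `planted_deletion`: fields `d_start`, `d_end`
#'   (first/last deleted position), `length`, `retained_side`,
#'   `source_repeat`.
#' @examples
#' rp <- repeat_plan("ACCTCCCTCACCA", 8470, 13447)
#' ref <- make_reference(16569, repeat_plans = list(rp), seed = 1)
#' del <- plant_copy_choice_deletion(ref, rp, "five_prime")
#' del$length  # 4977
#' @export
plant_copy_choice_deletion <- function(ref, plan,
                                       retained_side = c("five_prime",
                                                         "three_prime")) {
  retained_side <- match.arg(retained_side)
  k <- plan$k
  c1 <- paste(ref_bases(ref, seq.int(plan$pos5, plan$pos5 + k - 1L)),
              collapse = "")
  c2 <- paste(ref_bases(ref, seq.int(plan$pos3, plan$pos3 + k - 1L)),
              collapse = "")
  if (c1 != plan$repeat_sequence || c2 != plan_copy2_seq(plan))
    stop("plan copies are not present in the reference")
  if (retained_side == "five_prime") {
    d_start <- plan$pos5 + k
    d_end <- plan$pos3 + k - 1L
  } else {
    d_start <- plan$pos5
    d_end <- plan$pos3 - 1L
  }
  structure(list(d_start = d_start, d_end = d_end,
                 length = d_end - d_start + 1L,
                 retained_side = retained_side, source_repeat = plan),
            class = "planted_deletion")
}

#' A deletion planted directly by coordinates (no repeat involved)
#'
#' Class III analogue: the junction has no engineered repeat.
#'
#' @param d_start,d_end first and last deleted positions.
#' @return object of class `planted_deletion` with `source_repeat = NULL`.
#' @export
planted_deletion <- function(d_start, d_end) {
  d_start <- as.integer(d_start); d_end <- as.integer(d_end)
  if (d_end < d_start) stop("d_end < d_start")
  structure(list(d_start = d_start, d_end = d_end,
                 length = d_end - d_start + 1L,
                 retained_side = NA_character_, source_repeat = NULL),
            class = "planted_deletion")
}

# Sequence of the deleted molecule: reference with [d_start, d_end] excised.
deleted_sequence <- function(ref, del) {
  paste0(substr(ref$sequence, 1L, del$d_start - 1L),
         substr(ref$sequence, del$d_end + 1L, ref$length))
}

#' Ground-truth mixture of wild-type and deleted molecules
#'
#' @param ref a [circular_reference()].
#' @param events list of `planted_deletion` objects.
#' @param fractions per-event molecule fractions; the wild-type fraction is
#'   the remainder and the total must not exceed 1.
#' @param seed integer recorded for provenance.
#' @return object of class `truth_set`.
#' @export
truth_set <- function(ref, events = list(), fractions = numeric(0), seed = 1L) {
  stopifnot(length(events) == length(fractions))
  fractions <- as.numeric(fractions)
  if (any(fractions < 0) || sum(fractions) > 1 + 1e-12)
    stop("event fractions must be non-negative and sum to <= 1")
  for (ev in events) stopifnot(inherits(ev, "planted_deletion"))
  structure(list(reference = ref, events = events, fractions = fractions,
                 wt_fraction = 1 - sum(fractions), seed = as.integer(seed)),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d planted event(s) on %s (%d bp), wt fraction %.3f\n",
              length(x$events), x$reference$name, x$reference$length,
              x$wt_fraction))
  invisible(x)
}

# Apply n substitution errors at random positions of a read (char vector in,
# char vector out); returns list(chars, positions).
apply_errors <- function(chars, n_err) {
  if (n_err == 0L) return(list(chars = chars, positions = integer(0)))
  pos <- sample.int(length(chars), n_err)
  for (i in pos) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  list(chars = chars, positions = pos)
}

#' Simulate sequencing reads from a molecule mixture with ground truth
#'
#' Shotgun model: molecules are circular, read start positions are uniform on
#' each molecule, and the number of reads drawn from a molecule is
#' proportional to its molecule fraction times its length, so per-position
#' depth is proportional to molecule fraction (this is what makes
#' junction-read fractions estimate heteroplasmy). Substitution errors are
#' i.i.d. per base; no indel errors are simulated. PCR duplicates are
#' position-identical copies of existing reads with independently resampled
#' errors. Reads are emitted on a random strand.
#'
#' @param truth a [truth_set()].
#' @param read_len read length (default 150).
#' @param coverage mean depth over the reference; the total read count is
#'   `ceiling(coverage * L / read_len)`.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param dup_rate fraction of additional duplicate reads (relative to the
#'   unique read count).
#' @param paired if `TRUE`, reads are generated as mate pairs from the two
#'   ends of fragments (read 1 forward, read 2 reverse-complemented) and
#'   duplicates copy both mates' positions; the total read count still honours
#'   `coverage`.
#' @param insert_size mean fragment length for paired mode.
#' @param insert_sd standard deviation of the fragment length (rounded
#'   normal, truncated below at `read_len`); insert-length variation is what
#'   makes position-based duplicate removal specific in paired data.
#' @param seed integer seed; simulation is deterministic given the seed.
#' @return object of class `simulated_reads`: `reads` (named character
#'   vector), `truth` (per-read table: molecule, event, start on molecule,
#'   strand, `spans_junction`, `duplicate_of`, `n_errors`, `mate_id`), plus
#'   the generating parameters.
#' @export
simulate_reads <- function(truth, read_len = 150L, coverage = 50,
                           error_rate = 0, dup_rate = 0, paired = FALSE,
                           insert_size = 400L, insert_sd = 30, seed = 1L) {
  stopifnot(inherits(truth, "truth_set"))
  if (coverage <= 0) stop("coverage must be > 0")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (dup_rate < 0) stop("dup_rate must be >= 0")
  read_len <- as.integer(read_len)
  ref <- truth$reference
  mols <- c(list(ref$sequence), lapply(truth$events, deleted_sequence,
                                       ref = ref))
  mol_names <- c("wt", if (length(truth$events))
    paste0("event", seq_along(truth$events)))
  mol_len <- nchar(mols)
  if (any(mol_len < read_len)) stop("a molecule is shorter than read_len")
  fracs <- c(truth$wt_fraction, truth$fractions)
  # junction position on each deleted molecule: between d_start-1 and d_start
  junc <- c(NA_integer_,
            vapply(truth$events, function(e) e$d_start - 1L, integer(1)))
  w <- fracs * mol_len
  if (sum(w) <= 0) stop("all molecule weights are zero")
  w <- w / sum(w)
  n_unique <- as.integer(ceiling(coverage * ref$length /
                                   (read_len * (if (paired) 2L else 1L))))

  with_seed(derive_seed(seed, "simulate_reads"), {
    mol_id <- sample.int(length(mols), n_unique, replace = TRUE, prob = w)
    start <- integer(n_unique)
    for (m in unique(mol_id)) {
      idx <- which(mol_id == m)
      start[idx] <- sample.int(mol_len[m], length(idx), replace = TRUE)
    }
    strand <- sample(c("+", "-"), n_unique, replace = TRUE)
    if (paired) strand <- rep("+", n_unique)  # pair geometry fixes strands
    ins <- if (paired) {
      pmax(read_len,
           as.integer(round(stats::rnorm(n_unique, insert_size, insert_sd))))
    } else rep(read_len, n_unique)
    n_dup <- as.integer(round(dup_rate * n_unique))
    dup_src <- if (n_dup > 0L) sample.int(n_unique, n_dup, replace = TRUE)
               else integer(0)
    mol_id <- c(mol_id, mol_id[dup_src])
    start <- c(start, start[dup_src])
    strand <- c(strand, strand[dup_src])
    ins <- c(ins, ins[dup_src])
    n <- n_unique + n_dup
    ids <- sprintf("r%06d", seq_len(n))
    dup_of <- c(rep(NA_character_, n_unique), ids[dup_src])
    n_err <- if (error_rate > 0) stats::rbinom(n, read_len, error_rate)
             else integer(n)

    if (paired && any(mol_len < max(ins)))
      stop("a molecule is shorter than the largest fragment")
    seqs <- character(if (paired) 2L * n else n)
    out_ids <- character(length(seqs))
    rows <- vector("list", length(seqs))
    k <- 0L
    for (i in seq_len(n)) {
      m <- mol_id[i]
      Lm <- mol_len[m]
      mc <- strsplit(mols[[m]], "", fixed = TRUE)[[1L]]
      take <- function(s, len) mc[pos_fold(seq.int(s, s + len - 1L), Lm)]
      spans <- function(s, len) {
        !is.na(junc[m]) && ((junc[m] - s) %% Lm) <= (len - 2L)
      }
      if (!paired) {
        er <- apply_errors(take(start[i], read_len), n_err[i])
        sq <- paste(er$chars, collapse = "")
        if (strand[i] == "-") sq <- revcomp(sq)
        k <- k + 1L
        seqs[k] <- sq; out_ids[k] <- ids[i]
        rows[[k]] <- data.frame(
          read_id = ids[i], molecule = mol_names[m],
          event = if (m == 1L) NA_integer_ else m - 1L,
          start = start[i], strand = strand[i],
          spans_junction = spans(start[i], read_len),
          duplicate_of = dup_of[i], n_errors = length(er$positions),
          mate_id = NA_character_, stringsAsFactors = FALSE)
      } else {
        s2 <- pos_fold(start[i] + ins[i] - read_len, Lm)
        id1 <- paste0(ids[i], "/1"); id2 <- paste0(ids[i], "/2")
        e1 <- apply_errors(take(start[i], read_len),
                           stats::rbinom(1L, read_len, error_rate))
        e2 <- apply_errors(take(s2, read_len),
                           stats::rbinom(1L, read_len, error_rate))
        k <- k + 1L
        seqs[k] <- paste(e1$chars, collapse = ""); out_ids[k] <- id1
        rows[[k]] <- data.frame(
          read_id = id1, molecule = mol_names[m],
          event = if (m == 1L) NA_integer_ else m - 1L,
          start = start[i], strand = "+",
          spans_junction = spans(start[i], read_len),
          duplicate_of = if (is.na(dup_of[i])) NA_character_
                         else paste0(dup_of[i], "/1"),
          n_errors = length(e1$positions), mate_id = id2,
          stringsAsFactors = FALSE)
        k <- k + 1L
        seqs[k] <- revcomp(paste(e2$chars, collapse = "")); out_ids[k] <- id2
        rows[[k]] <- data.frame(
          read_id = id2, molecule = mol_names[m],
          event = if (m == 1L) NA_integer_ else m - 1L,
          start = s2, strand = "-",
          spans_junction = spans(s2, read_len),
          duplicate_of = if (is.na(dup_of[i])) NA_character_
                         else paste0(dup_of[i], "/2"),
          n_errors = length(e2$positions), mate_id = id1,
          stringsAsFactors = FALSE)
      }
    }
    structure(list(reads = stats::setNames(seqs, out_ids),
                   truth = do.call(rbind, rows),
                   read_len = read_len, coverage = coverage,
                   error_rate = error_rate, dup_rate = dup_rate,
                   paired = paired, seed = as.integer(seed),
                   truth_set = truth),
              class = "simulated_reads")
  })
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat(sprintf("<simulated_reads> %d reads of %d bp (%.0fx requested), %d duplicates\n",
              length(x$reads), x$read_len, x$coverage,
              sum(!is.na(x$truth$duplicate_of))))
  invisible(x)
}

#' Write simulated reads as FASTQ (Phred+33, fixed quality)
#'
#' @param sim a [simulate_reads()] result (or a named character vector).
#' @param path output FASTQ file.
#' @param quality_char fixed base-quality character (default "I", Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path, quality_char = "I") {
  reads <- if (inherits(sim, "simulated_reads")) sim$reads else sim
  stopifnot(is.character(reads), !is.null(names(reads)))
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::PhredQuality(strrep(quality_char, nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a simulation's per-read truth table as TSV
#'
#' @param sim a [simulate_reads()] result.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(sim, path) {
  stopifnot(inherits(sim, "simulated_reads"))
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
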