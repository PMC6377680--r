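#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline in one serializable object. The
#' defaults are the thresholds used throughout: E-value cutoff 1e-5 (strictly
#' greater rejected), at most one gap, 15 bp minimum flank on each side of
#' the gap, 100 bp minimum gap, single-linkage threshold 50 bp (inclusive)
#' with a 2-read minimum for visualization clusters, directionality gates of
#' 1 bp breakpoint uncertainty, 1 mismatch, and a repeat-length difference of
#' at least 2. Unknown keys are rejected. One master seed feeds a named
#' substream per stochastic component (see [derive_seed()]).
#'
#' @param ... overrides of the defaults listed above.
#' @return a list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    seed_len = 15L,
    max_mismatch_per_block = 2L,
    max_evalue = 1e-5,
    max_gaps = 1L,
    min_flank = 15L,
    min_gap = 100L,
    linkage_threshold = 50L,
    min_cluster_reads = 2L,
    max_uncertainty = 1L,
    max_mismatch = 1L,
    delta_min = 2L,
    max_k = 30L,
    n_sets = 100L,
    scheme = "length_matched",
    paired = FALSE,
    artifact_window = NULL,
    coordinate_convention = "1-based inclusive"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' Serialization round-trips exactly: `write_config()` followed by
#' [read_config()] reproduces the configuration, and re-serializing yields
#' byte-identical YAML.
#'
#' @param config a [run_config()].
#' @param path YAML file.
#' @return `path` invisibly (writer); a `run_config` (reader).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full deletion-calling pipeline
#'
#' Executes align (or ingest) -> filter -> deduplicate -> circular-artifact
#' removal -> exact clustering -> linkage clustering -> deletion/duplication
#' classification -> heteroplasmy -> junction-repeat annotation, and returns
#' everything with a per-stage reconciliation report. Idempotent given
#' identical inputs, configuration and seed.
#'
#' @param reads input evidence: a named character vector of read sequences, a
#'   FASTQ path, a [simulate_reads()] result, or a pre-computed
#'   `gapped_alignments` table (e.g. from [read_sam()]).
#' @param ref a [circular_reference()].
#' @param config a [run_config()].
#' @return object of class `mtbreak_run` with fields `calls` (annotated
#'   segment-call table), `clusters`, `alignments` (post-filter), `report`
#'   (per-stage counts; inputs reconcile with outputs plus rejections at
#'   every stage), `config`, `reference`.
#' @examples
#' rp <- repeat_plan("ACCTCCCTCACCA", 1000, 2500)
#' ref <- make_reference(4300, repeat_plans = list(rp), seed = 3)
#' del <- plant_copy_choice_deletion(ref, rp, "five_prime")
#' sim <- simulate_reads(truth_set(ref, list(del), 0.3), read_len = 100,
#'                       coverage = 5, seed = 3)
#' res <- run_pipeline(sim, ref)
#' res$calls[, c("d_start", "d_end", "read_support", "k_exact")]
#' @export
run_pipeline <- function(reads, ref, config = run_config()) {
  stopifnot(inherits(ref, "circular_reference"),
            inherits(config, "run_config"))
  report <- list()
  if (inherits(reads, "simulated_reads")) reads <- reads$reads
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads, ignore.case = TRUE)) {
    reads <- read_fastq(reads)
  }
  if (inherits(reads, "gapped_alignments")) {
    alns <- reads
    report$align <- c(input = nrow(alns) +
                        length(attr(alns, "skipped") %||% character(0)),
                      aligned = nrow(alns),
                      skipped = length(attr(alns, "skipped") %||% character(0)))
  } else {
    params <- align_params(seed_len = config$seed_len,
                           max_mismatch_per_block = config$max_mismatch_per_block)
    alns <- split_align(reads, ref, params)
    report$align <- c(input = length(reads), aligned = nrow(alns),
                      skipped = length(attr(alns, "skipped")) +
                        (length(reads) - nrow(alns) -
                           length(attr(alns, "skipped"))))
  }
  filtered <- filter_alignments(alns, max_evalue = config$max_evalue,
                                max_gaps = config$max_gaps,
                                min_flank = config$min_flank,
                                min_gap = config$min_gap)
  report$filter <- attr(filtered, "filter_log")
  dedup <- remove_duplicates(filtered, paired = config$paired)
  report$dedup <- attr(dedup, "dedup_log")
  clean <- remove_circular_artifacts(dedup, ref,
                                     window = config$artifact_window)
  report$artifact <- attr(clean, "artifact_log")
  calls <- cluster_exact(clean)
  report$cluster <- c(gapped = sum(clean$n_gaps == 1L), calls = nrow(calls))
  clusters <- cluster_linkage(calls, threshold = config$linkage_threshold,
                              min_reads = config$min_cluster_reads)
  calls <- classify_del_dup(calls, ref)
  if (isTRUE(attr(calls, "origin_warning")))
    report$origin_warning <- TRUE
  calls <- heteroplasmy(calls, clean, ref, min_flank = config$min_flank)
  calls <- annotate_repeats(calls, ref,
                            max_uncertainty = config$max_uncertainty,
                            max_mismatch = config$max_mismatch,
                            delta_min = config$delta_min,
                            max_k = config$max_k)
  structure(list(calls = calls, clusters = clusters, alignments = clean,
                 report = report, config = config,
                 reference = ref$name, reference_length = ref$length),
            class = "mtbreak_run")
}

#' @export
print.mtbreak_run <- function(x, ...) {
  cat(sprintf("<mtbreak_run> %s (%d bp): %d segment call(s), %d cluster(s)\n",
              x$reference, x$reference_length, nrow(x$calls),
              nrow(x$clusters)))
  if (nrow(x$calls) > 0L) {
    cat(sprintf("  deletions: %d, likely duplications: %d; total read support %d\n",
                sum(x$calls$classification == "deletion"),
                sum(x$calls$classification == "likely_duplication"),
                sum(x$calls$read_support)))
  }
  invisible(x)
}

#' @exportS3Method base::summary
summary.mtbreak_run <- function(object, ...) {
  x <- object
  print(x)
  if (nrow(x$calls) > 0L) {
    ds <- directionality_summary(x$calls)
    cat("  junction repeats: median k_exact",
        stats::median(x$calls$k_exact), "\n")
    cat(sprintf("  directionality (unique): 5' %s, 3' %s, unclassified %d, not informative %d\n",
                ds$counts[["five_prime"]], ds$counts[["three_prime"]],
                ds$counts[["unclassified"]], ds$counts[["not_informative"]]))
    if (!is.na(ds$frac_unique[["five_prime"]]))
      cat(sprintf("  5' retention fraction: %.1f%% unique, %.1f%% per read\n",
                  100 * ds$frac_unique[["five_prime"]],
                  100 * ds$frac_reads[["five_prime"]]))
  }
  cat("  stage report:\n")
  for (nm in names(x$report)) {
    v <- x$report[[nm]]
    if (is.logical(v)) next
    cat("   ", nm, ":", paste(names(v), v, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Per-position breakpoint frequency table
#'
#' Counts 5' and 3' breakpoints per reference position (or bin), both
#' read-weighted and per unique call — the histogram drawn as the outer ring
#' of circular deletion plots.
#'
#' @param calls a `segment_calls` data.frame.
#' @param bin bin width in bp (default 1).
#' @param L optional reference length used to bound the bins.
#' @return data.frame with `pos` (bin start), `reads_5p`, `reads_3p`,
#'   `unique_5p`, `unique_3p`.
#' @export
breakpoint_histogram <- function(calls, bin = 1L, L = NULL) {
  if (nrow(calls) == 0L)
    return(data.frame(pos = integer(0), reads_5p = integer(0),
                      reads_3p = integer(0), unique_5p = integer(0),
                      unique_3p = integer(0)))
  bin <- as.integer(bin)
  b5 <- ((calls$d_start - 1L) %/% bin) * bin + 1L
  b3 <- ((calls$d_end - 1L) %/% bin) * bin + 1L
  support <- calls$read_support
  pos <- sort(unique(c(b5, b3)))
  agg <- function(b, w) {
    v <- tapply(w, b, sum)
    out <- stats::setNames(rep(0L, length(pos)), pos)
    out[names(v)] <- as.integer(v)
    out
  }
  data.frame(pos = pos,
             reads_5p = agg(b5, support), reads_3p = agg(b3, support),
             unique_5p = agg(b5, rep(1L, nrow(calls))),
             unique_3p = agg(b3, rep(1L, nrow(calls))),
             row.names = NULL)
}

#' @exportS3Method graphics::plot
plot.mtbreak_run <- function(x, which = c("arcs", "histogram"), ...) {
  which <- match.arg(which)
  calls <- x$calls
  if (nrow(calls) == 0L) {
    graphics::plot.new()
    graphics::title("no segment calls")
    return(invisible(x))
  }
  L <- x$reference_length
  if (which == "histogram") {
    h <- breakpoint_histogram(calls)
    graphics::plot(NA, xlim = c(1, L), ylim = c(0, max(h$reads_5p, h$reads_3p)),
                   xlab = "reference position", ylab = "breakpoint reads",
                   main = "breakpoint frequency", ...)
    graphics::segments(h$pos, 0, h$pos, h$reads_5p, col = "darkorange")
    graphics::segments(h$pos, 0, h$pos, h$reads_3p, col = "steelblue")
    graphics::legend("topright", legend = c("5' breakpoints", "3' breakpoints"),
                     col = c("darkorange", "steelblue"), lty = 1, bty = "n")
  } else {
    graphics::plot(NA, xlim = c(1, L), ylim = c(0, 1.1),
                   xlab = "reference position", ylab = "", yaxt = "n",
                   main = "deletion arcs (height ~ read support)", ...)
    smax <- max(calls$read_support)
    for (i in seq_len(nrow(calls))) {
      xs <- seq(calls$d_start[i], calls$d_end[i], length.out = 60)
      mid <- (calls$d_start[i] + calls$d_end[i]) / 2
      half <- (calls$d_end[i] - calls$d_start[i]) / 2
      ys <- (calls$read_support[i] / smax) * sqrt(pmax(0, 1 - ((xs - mid) / half)^2))
      graphics::lines(xs, ys,
                      col = if (calls$classification[i] == "deletion")
                        "steelblue" else "firebrick")
    }
  }
  invisible(x)
}

#' Write pipeline outputs to files
#'
#' Emits the full call table as TSV (1-based inclusive coordinates, with
#' sliding, support, classification, heteroplasmy and repeat annotations; a
#' `#`-prefixed header block records the configuration), the calls as BEDPE
#' (0-based half-open, converted on write), the per-position breakpoint
#' histogram as TSV, and the run report as JSON.
#'
#' @param run an [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(run, dir, prefix = "mtbreak") {
  stopifnot(inherits(run, "mtbreak_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- run$config
  header <- c(
    sprintf("# reference: %s (%d bp)", run$reference, run$reference_length),
    sprintf("# coordinates: %s", cfg$coordinate_convention),
    sprintf("# seed: %d", cfg$seed),
    paste0("# config: ", gsub("\n", " ", yaml::as.yaml(unclass(cfg)))))
  paths <- c(
    calls = file.path(dir, paste0(prefix, "_calls.tsv")),
    bedpe = file.path(dir, paste0(prefix, "_calls.bedpe")),
    histogram = file.path(dir, paste0(prefix, "_breakpoints.tsv")),
    report = file.path(dir, paste0(prefix, "_report.json")))
  con <- file(paths[["calls"]], "w")
  writeLines(header, con)
  suppressWarnings(utils::write.table(run$calls, con, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  close(con)
  calls <- run$calls
  if (nrow(calls) > 0L) {
    # BEDPE: the two breakpoint loci as 0-based half-open single-base features
    bedpe <- data.frame(chrom1 = run$reference, start1 = calls$d_start - 1L,
                        end1 = calls$d_start, chrom2 = run$reference,
                        start2 = calls$d_end, end2 = calls$d_end + 1L,
                        name = sprintf("call%04d", seq_len(nrow(calls))),
                        score = calls$read_support,
                        strand1 = "+", strand2 = "+")
  } else {
    bedpe <- data.frame()
  }
  utils::write.table(bedpe, paths[["bedpe"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(breakpoint_histogram(calls), paths[["histogram"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$report, paths[["report"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
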