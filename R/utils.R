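`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed for a named stochastic component
#'
#' Every stochastic stage draws from its own named substream so that adding
#' or reordering stages never perturbs another stage's random numbers. The
#' substream seed is a deterministic 31-bit hash of the master seed and the
#' component name.
#'
#' @param seed master integer seed.
#' @param name character scalar naming the component (e.g. "reads").
#' @return an integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Run code under a local RNG state; restores .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Reverse complement of a plain character string (ACGTN only).
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}
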