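# mtbreak

Detection of large mitochondrial DNA deletions (and likely duplications)
from deep-sequencing reads, with junction-repeat characterization and a
generative simulator of copy-choice deletion formation.

## What it does, and for whom

Deletions of the circular 16,569-bp human mitochondrial genome underlie
several mitochondrial diseases and accumulate with ageing. A deletion's
sequencing signature is the *gapped (split) alignment*: a read crossing the
junction aligns as two blocks separated by a reference gap. `mtbreak` is for
researchers who want to go from reads (FASTQ, or SAM from an external
aligner) to:

- unique breakpoint-pair calls with read support, after E-value / gap-count /
  flank / gap-length filtering, PCR-duplicate removal, and removal of the
  false gapped alignments a linearized circular genome produces;
- single-linkage clusters of nearby calls (50-bp breakpoint distance);
- deletion vs likely-duplication classification by replication-origin
  overlap, and per-call heteroplasmy `g/(g+w)` from junction vs wild-type
  spanning reads;
- junction-repeat annotation: longest exact direct repeat overlapping the two
  breakpoints (equal to the junction's breakpoint-sliding ambiguity),
  imperfect-repeat 5'/3' retention directionality, motif tables,
  randomized-breakpoint null ensembles with repeat-length enrichment, and
  cross-dataset repeat-pattern overlap statistics.

The model at the core is copy-choice recombination during light-strand
replication: for a direct repeat of length `k` with copies starting at
`p5 < p3`, retention of the 5' copy deletes `[p5 + k, p3 + k - 1]` and
retention of the 3' copy deletes `[p5, p3 - 1]`; either way one repeat copy
survives at the junction. For perfect repeats the two products are
identical, so the breakpoint can slide across the repeat and the retained
side is undecidable; only imperfect repeats (k5 vs k3 with one mismatch
allowed, difference >= 2, breakpoint uncertainty <= 1 bp) can be oriented.
The bundled simulator plants exactly this mechanism, with ground truth, so
the whole pipeline is testable offline.

## Worked example

The classic "common deletion" geometry, rebuilt synthetically: the 13-bp
repeat ACCTCCCTCACCA planted at positions 8470 and 13447 of a 16,569-bp
circular reference, one copy-choice deletion, reads simulated at 20x with a
20% deleted-molecule fraction, then called back:

```r
library(mtbreak)

rp  <- repeat_plan("ACCTCCCTCACCA", 8470, 13447)
ref <- make_reference(16569, repeat_plans = list(rp), seed = 1)
del <- plant_copy_choice_deletion(ref, rp, "five_prime")
del$length
#> [1] 4977

sim <- simulate_reads(truth_set(ref, list(del), 0.2),
                      read_len = 150, coverage = 20, dup_rate = 0.3, seed = 2)
res <- run_pipeline(sim, ref)
res$calls[, c("d_start", "d_end", "read_support", "heteroplasmy",
              "k_exact", "repeat_seq", "direction")]
#>   d_start d_end read_support heteroplasmy k_exact    repeat_seq       direction
#> 1    8470 13446            4    0.2166667      13 ACCTCCCTCACCA not_informative
```

Reading the output: the deletion removed 4,977 bp (~5.0 kb). The call is
reported at its leftmost-normalized junction `[8470, 13446]` — sliding the
breakpoints left across the full 13-bp repeat, so it is the same equivalence
class as the planted `[8483, 13459]`; `k_exact = 13` recovers the planted
repeat and equals the sliding ambiguity. The heteroplasmy estimate 0.217
approximates the planted molecule fraction 0.2 at this depth. A perfect
repeat cannot be oriented, hence `not_informative`; imperfect-repeat
junctions come back as `five_prime`/`three_prime` when the two sides differ
by at least 2 bp of (one-mismatch) repeat length.

`summary(res)` prints per-stage counts (align/filter/dedup/artifact/cluster),
`plot(res)` draws deletion arcs or the breakpoint histogram, and
`write_outputs(res, dir)` emits the call TSV (1-based, with a config header),
BEDPE (0-based half-open), the per-position breakpoint histogram, and a JSON
run report.

For real data: `read_fasta()` loads the reference (e.g. rCRS, supplied by the
user), `run_pipeline()` accepts FASTQ or a `read_sam()` table from an
external aligner, and replication-origin intervals for duplication
reclassification are passed to `circular_reference()`/`make_reference()` as
configuration.

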