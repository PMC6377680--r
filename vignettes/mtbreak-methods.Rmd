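---
title: "Detecting mtDNA deletions and characterizing their junction repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mtDNA deletions and characterizing their junction repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtbreak)
```

## The problem

Large deletions of the 16,569-bp circular human mitochondrial genome cause
mitochondrial disease and accumulate with ageing. Most fall in the major arc
between the two replication origins (OriH, OriL), and their breakpoints are
enriched for direct repeats: the archetype is the "common deletion", which
removes ~5.0 kb between two 13-bp repeats (ACCTCCCTCACCA, starting at rCRS
positions 8470 and 13447), retaining one repeat copy at the junction.

A deletion junction leaves a characteristic sequencing signature: a read
crossing the junction aligns as two blocks separated by a reference gap (a
gapped, or split, alignment). `mtbreak` turns a pile of reads into a table of
unique breakpoint pairs with read support, deletion/duplication
classification, heteroplasmy estimates, and junction-repeat annotations — and
ships a generative simulator of the copy-choice deletion mechanism so every
stage can be validated against planted ground truth without any external
data.

## The copy-choice model and the simulator

Under strand-displacement replication, light-strand synthesis copies a long
single-stranded heavy-strand template. If the polymerase dissociates while
replicating a repeat, the nascent 3' end can re-anneal (mispair) to a
downstream copy of the repeat and synthesis resumes there: one repeat copy
and the intervening sequence are lost. `plant_copy_choice_deletion()`
implements exactly this geometry. For a repeat of length $k$ with copies
starting at $p_5 < p_3$:

* retained 5' copy: deleted interval $[p_5 + k,\; p_3 + k - 1]$
  (the downstream copy is lost with the intervening sequence);
* retained 3' copy: deleted interval $[p_5,\; p_3 - 1]$.

For perfect repeats the two molecules are identical — which is why perfect
junctions can never be oriented, and why the breakpoint can be placed
anywhere across the repeat ("junction sliding"). Only *imperfect* repeats
(the downstream copy carrying substitutions) break the symmetry.

The generator (`make_reference()`, `simulate_reads()`) emulates:

* a circular reference with i.i.d. background bases at a configurable GC
  content (default 0.44, human-mtDNA-like) and planted repeat pairs, perfect
  or imperfect;
* shotgun reads with uniform starts on each circular molecule, read counts
  per molecule proportional to molecule fraction times molecule length (so
  per-position depth is proportional to molecule fraction — the property that
  makes junction-read fractions estimate heteroplasmy);
* i.i.d. substitution errors (no indels — the aligner's blocks are
  substitution-only by design, and indel robustness is out of scope);
* PCR duplicates as position-identical copies with independently resampled
  errors, matching the position-based duplicate filter;
* optional mate pairs from fragments with normally distributed insert sizes.
  Insert-length variation is deliberate: it is what makes position-based
  duplicate removal specific in paired data.

Two generator choices deserve emphasis. First, planted repeats are made
*maximal*: the bases flanking each copy are resampled so a planted 13-bp
repeat cannot extend to 14 bp by background chance. This makes the planted
repeat length an exact ground truth for any seed, at the cost of a slight
departure from pure i.i.d. background at four positions per plan. Second,
reads are allocated to molecules by fraction x length. A literal
"proportional to fraction" allocation would make per-position depth — and
hence any junction-fraction estimator — biased by the wild-type/deleted
molecule length ratio; fraction x length is the standard shotgun model and
keeps the heteroplasmy estimand equal to the molecule fraction.

What the simulator does **not** emulate: real base-quality profiles, indels,
chimeric library artifacts, nuclear mitochondrial segments (NUMTs), strand
bias, or replication kinetics (the in vitro hairpin barrier is a sequence
feature, not a kinetic object). Tests passing on synthetic data therefore
validate the pipeline's logic, not its robustness to every real-data
pathology.

## The aligner

`split_align()` is an exact-seed anchored split aligner: leftmost exact
occurrences of the read's first and last `seed_len` bases anchor two blocks,
each extended with at most `max_mismatch_per_block` substitutions, with at
most one reference gap between them. Reads are tried on both strands and
reported on the forward strand. It is deterministic by construction:
candidates are scored (`matches - 3 x mismatches - gap_open`), ties prefer
the ungapped model and then the leftmost placement.

Circularity is handled by aligning against a doubled reference and folding
coordinates back to `1..L`. A read genuinely crossing the L -> 1 junction
therefore aligns as a single ungapped block and can never masquerade as a
deletion — the artifact that `remove_circular_artifacts()` exists to remove
from *external* (linear-aligner) input is structurally absent from internal
alignments.

Junctions are normalized at the reference level: the breakpoint pair slides
to its leftmost equivalent placement, and the size of the equivalence class
(the sliding range) is recorded. Normalizing on the reference rather than
within each read matters: two reads over the same repeat junction with
different flank lengths would otherwise normalize to different coordinates,
splitting one event into several calls. `seed_len` defaults to 15 so that no
alignment the aligner emits is trivially rejected by the 15-bp flank filter.

The E-value analog (`score_alignment()`) is a Karlin–Altschul expect value
with match +1 / mismatch -2, lambda solved for uniform base composition and
K = 0.1. It is monotone in score and calibrated only in the sense that
sound full-length alignments pass the 1e-5 cutoff and short noisy ones fail
it; it is *not* calibrated to any external aligner's E-values.

## Filtering, deduplication, clustering, classification

Thresholds follow the filter wording read literally: E-value strictly above
1e-5 rejected; more than one gap rejected; flanks of at least 15 bp on both
sides and gap length of at least 100 bp required (boundary values kept).
Ungapped alignments are exempt from the gap rules — they are the wild-type
denominators of heteroplasmy. Duplicate removal groups reads mapped at
identical positions (mate positions included when available; reads whose
mate is missing deduplicate on their own position), keeping the
lexicographically smallest read id for determinism.

Exact clustering groups identical leftmost-normalized breakpoint pairs into
one call per distinct pair. Single-linkage clustering then links calls whose
breakpoint-pair distance `max(|d5 - d5'|, |d3 - d3'|)` is at most 50 bp; the
threshold is inclusive (a distance of exactly 50 links, 51 does not) — the
source wording gives a threshold without strictness, and the inclusive
reading is adopted and documented here. Clusters with fewer than 2 total
reads are flagged rather than dropped: the 2-read rule is a visualization
convention, and the full table keeps everything.

A junction is compatible with deletion of the enclosed arc *or* duplication
of the complementary arc; since deleting a replication origin is not viable,
calls whose putative deleted interval overlaps OriH or OriL (>= 1 bp) are
reclassified as likely duplications. Origin coordinates are configuration,
not hard-coded biology: the package does not fix rCRS intervals, and users
supply their own (for rCRS work, OriH within the non-coding region, e.g.
around 16100-200 spanning the origin of the coordinate system, and OriL near
5730-5770, are reasonable defaults; the published analyses do not state the
exact bounds they used, so these remain explicit user choices).

Heteroplasmy at each breakpoint is the junction fraction `g / (g + w)` —
`g` junction reads, `w` wild-type reads spanning the position with at least
15 bp on both sides — averaged over the two breakpoints. The fraction form
(bounded by 1) rather than the ratio `g / w` is a documented choice; the
source wording ("fraction of gapped to wild-type reads") does not
distinguish the two, and "fraction" plus the proportion-like reported values
favour this reading.

## Junction repeats and directionality

`longest_exact_repeat()` computes the longest exact match overlapping both
breakpoints by sliding the junction: `a` bases leftward plus `b` bases
rightward of the normalized breakpoint, `k_exact = a + b`. This equals the
retained-copy repeat length for copy-choice events, and — provably — the
junction's sliding ambiguity, a consistency asserted in the tests against an
exhaustive enumeration oracle.

Directionality follows a strict gate: only calls whose breakpoints are
certain to within 1 bp (`k_exact <= 1`) are informative. For those, `k5` is
the longest junction-flush match (allowing 1 mismatch) between the deleted
segment's end and the retained 5' flank, `k3` the mirror image, and a side
is assigned only when the lengths differ by at least 2. Both comparisons
anchor flush at the junction without internal gaps — the simplest reading of
"longest repeat on either side"; offset or gapped repeat placements are not
searched. A consequence worth spelling out: an imperfect repeat is
informative only when its mismatch sits at the junction-distal end of the
lost copy (for 5' retention, the last one or two repeat positions; for 3'
retention, the first one or two). A mismatch in the middle of a 13-mer
leaves 6 bp of exact sliding and the call is correctly, and deliberately,
`not_informative`. The search cap `max_k = 30` extends itself automatically
whenever attained, so it never binds.

The randomized-breakpoint null (`randomize_breakpoints()`) defaults to the
length-matched scheme: each null set has the observed cardinality, uniform
starts in the observed breakpoint span, and lengths resampled from the
observed lengths — "similar in size" is read as matching both count and
length distribution, the more conservative null for repeat statistics (a
uniform-breakpoint scheme is also provided). Enrichment tables report both
exact-length and cumulative (>= k) frequencies with per-length fold =
observed / null mean; the cumulative form is the default for quoting "k bp
or above" folds, and both are emitted because published histograms are
binned by exact length while the prose quotes cumulative thresholds.

`pattern_overlap()` compares distinct junction repeat patterns (>= 3 bp)
between two datasets restricted to a common region, against length-matched
randomized controls. Two p-values are emitted without claiming equivalence:
an empirical two-sided p (doubled smaller tail, +1 correction) and a
two-sided rank-sum p of the one observed value against the null values. With
a single observed statistic the "Wilcoxon test" of the published comparison
is ambiguous; emitting both, labelled, is the honest option.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere (BEDPE output converts to
  0-based half-open on write and says so in its header). Circular position
  arithmetic is modulo L back into 1..L.
* N bases never match anything in repeat searches; references reject N
  unless explicitly allowed.
* Reads shorter than `seed_len` are skipped and logged, not errors.
* Empty inputs yield empty tables and a reconciled zero-count report.
* Degenerate heteroplasmy denominators (no spanning reads at either
  breakpoint) yield `NA`, never division by zero; `g = 0` yields 0.
* All stochastic components draw from named substreams of one master seed
  (`derive_seed()`), so adding a stage never perturbs another stage's draws,
  and every simulation is bit-reproducible given the seed.

## Problem sizes used in the validation suite

The test suite validates at desk scale, chosen to exercise every code path
on genome-like instances: a 20-event cohort on a 16,569-bp circular
reference at 100x coverage with 30% duplicates for end-to-end recovery;
paired-end mixtures at 500x on a 4,300-bp in-vitro-style template for
heteroplasmy (fractions 0.05/0.2/0.5, recovered within three binomial
standard errors); 1,000 random references (L <= 100) for exhaustive oracle
agreement of the repeat and directionality searches; and 100-set null
ensembles for the randomization statistics. Deletion spans in the recovery
cohort are 11-13 kb so that deleted molecules are short and junction depth
is comfortably above the recovery threshold at 100x — the same reason real
major-arc deletions are easy to see at modest mtDNA coverage.

## Known limitations

* The internal aligner handles exactly one gap and substitutions only; it is
  a calling-grade aligner for this pipeline, not a general-purpose mapper.
  Multi-gap chimeras are filtered, as in the analysis it implements.
* SAM ingest consumes `D`/`N`-encoded gaps; split reads encoded as
  primary + supplementary pairs are not reassembled.
* When the *same* repeat sequence flanks several distinct deletions (as the
  common repeat does in real mtDNA), a junction read whose flank barely
  clears the repeat can be equally well explained by more than one junction
  pairing; such score ties resolve deterministically to the leftmost
  placement, which can attribute a read to the wrong member of the ambiguous
  family. This is a property of the evidence, not the implementation.
* Directionality misclassification on real data is bounded but not zero —
  background micro-homology can mimic the opposite side. A cohort planted
  100% 5'-retained still shows a nonzero 3' fraction; the suite asserts only
  that the 5' excess survives, mirroring the interpretation that observed 3'
  fractions overstate the true rate.
* Heteroplasmy assumes deduplicated, uniformly sampled reads; amplification
  or capture protocols with position bias will bias it.
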