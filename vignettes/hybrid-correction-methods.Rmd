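---
title: "Hybrid long-read error correction with a de Bruijn graph: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid long-read error correction with a de Bruijn graph: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrec)
```

## The problem

Third-generation (PacBio-style) sequencing produces reads of thousands of
bases with error rates around 15%, dominated by insertions, then
deletions, then substitutions.  Second-generation short reads are two
orders of magnitude more accurate but much shorter.  Hybrid correction
uses a short-read library from the same sample to repair the long reads:
wherever a long read disagrees with what the short reads say the
underlying molecule looks like, the disagreeing stretch is replaced by a
short-read-supported sequence, while the read's length and long-range
structure are kept.

`lrec` implements the graph-based strategy: instead of aligning short
reads onto long reads (accurate but extremely expensive), it summarises
the short-read library *once* as a de Bruijn graph (DBG) and then, for
each erroneous region of each long read, searches the graph for a path
whose spelled sequence best explains that region.

## The model

### Solid and weak k-mers

All k-length substrings (k-mers) of the short reads are counted under
their *canonical* form — the lexicographic minimum of the k-mer and its
reverse complement — so both strands share one graph node.  `k` must be
odd so a k-mer can never equal its own reverse complement.  A k-mer is
**solid** when

1. its canonical count is at least the threshold `s`
   (`solid_threshold`, default 3), and
2. (by default) at least one of its four single-base right extensions
   *and* one of its four left extensions also pass the count threshold.

Rule 1 is the usual k-mer-spectrum filter: at sufficient coverage a
sequencing error almost never recurs `s` times, so sub-threshold k-mers
are presumed erroneous ("weak").  Rule 2 (`require_arcs`) additionally
discards isolated nodes that have no neighbours in the graph; it is kept
as a behavioural feature of the original succinct-representation design
even though this package's exact hash index has no false positives, and
can be disabled with `require_arcs = FALSE`.  k-mers containing `N` are
never counted and always weak — a conservative choice for ambiguous
bases.

The DBG itself is implicit: nodes are solid k-mers, and an arc joins two
k-mers that overlap by k-1 bases.  Adjacency is computed on demand by
querying the four possible extensions, always in appended/prepended base
order `A < C < G < T`, which makes every downstream traversal
deterministic.  Traversal steps require only the count threshold of the
neighbour, not its arc condition; anchors, by contrast, must be fully
solid.

### Partitioning a long read

Each k-mer start position of a long read is classified solid or weak
against the index.  Maximal stretches of solid positions form **solid
runs**; the gaps between them are **inner weak regions**, and weak
stretches touching the read's start or end are the **head** and
**tail**.  Coordinates are 0-based and half-open throughout — one
convention everywhere avoids an entire class of off-by-one errors.  A
read with no solid k-mer at all cannot be anchored to the graph and is
passed through unchanged (lower case, flagged as skipped).

### Bridging inner regions

For an inner region the corrector picks a *source* solid k-mer on the
left and a *target* on the right and searches the DBG for a path from
source to target whose spelled sequence minimises the edit distance to
the read region (the compared span runs from the source k-mer's first
base to the target k-mer's last base, anchors included — the paper-style
contract that paths "start and end with the appropriate solid k-mers"
leaves the compared span open; including both anchors pins the dynamic
programme at both ends).

Because solidity is a statistical filter, a single anchor pair can fail
(a falsely solid k-mer traps the search in the wrong part of the graph).
Robustness comes from redundancy: every solid position is tried as a
source against its next `t` solid positions (`target_count`, default 5),
skipping pairs that lie in one run (nothing to correct), overlap in the
read (`q - p < k`, the signature of a tandem repeat or false solid
k-mer), or span more than `max_region_span` bases (default 500; the DP
row and the search cost grow with the span, and distant anchor pairs
rarely admit a path).

The search itself is a depth-first traversal that extends the current
path one base at a time and maintains, per node, one row of the edit
distance DP against the region — so the distance of every partial path
is known *node-wise*, and a branch is abandoned the moment even its best
possible extension would exceed the error budget

\[ E = \lceil \texttt{max\_error\_rate} \times |\mathrm{region}| \rceil ,\]

with `max_error_rate = 0.4` by default (generous on purpose: a 15%-error
read can locally be much worse).  Path length is capped at
`|region| + E`, a sound prune since longer paths must exceed the budget.
The amount of branching work is bounded by `branching_limit` (default
200): every time the DFS takes a non-first alternative at a node the
counter increases, and past the limit the whole region search aborts and
discards its candidates — in repeat-dense graph neighbourhoods an
exhaustive search is hopeless and the region is better left to the
fallbacks below.  The published description counts "paths encountered",
which is ambiguous between completed paths and branch events; counting
branch events was chosen here because it bounds work even when no path
ever completes.

### The path graph

Successful bridges become arcs of a per-read **path graph**: nodes are
the solid k-mer *occurrence positions* of the read (positions, not k-mer
values — repeats make value-nodes ambiguous), each found bridge is an
arc from its source to its target position weighted by its edit
distance and carrying its replacement sequence.  Consecutive positions
inside a run are joined by weight-0 arcs carrying the original bases.
When every trial from a run-end source fails, a **dummy arc** to the
next solid position keeps the graph connected; it is weighted by the
spanned region length (so real bridges are always preferred) and its
replacement keeps the original bases — the corrector never deletes inner
sequence.  Before giving up on such a region, one-sided **extension
searches** (below) are run inward from both flanks; a successful flank
correction replaces a prefix and/or suffix of the region and lowers the
dummy weight by the number of weak bases covered (floored at 1).  A
flank correction that would eat into the opposite anchor, or two
corrections that would overlap, are dropped (left side wins) — the
published method only says to "adapt" the edge, so this package chooses
the conservative variant.

The applied corrections are then selected globally: the minimum-weight
path from the first to the last solid position (Dijkstra's problem; as
every arc points forward in read coordinates the implementation relaxes
arcs in position order, which is exact on this DAG).  Ties prefer fewer
arcs, then the earliest-sorted arc sequence.  The chosen replacements
are spliced into the read; neighbouring replacements share their
junction k-mer, which is emitted once.

### Heads and tails: extension searches

A head or tail has only one anchor, so there is no target to aim at.
The tail search grows paths from the anchor, scoring them node-wise
against the tail; a branch is abandoned when its minimal edit distance
exceeds `max_error_rate` times the consumed path length — a linear
drop-off criterion standing in for the BLAST-style X-drop the published
method alludes to without parameterising.  Among admissible paths the
longest (then closest) is kept, and — because optimising length tends to
overshoot the part that aligns well — it is trimmed back to the prefix
with the best global alignment score against any tail prefix (match +1,
mismatch -1, gap -1; ties toward the longer prefix).  Heads are handled
by reverse-complementing anchor and segment, searching as a tail, and
flipping the result back; the canonical-k-mer graph is strand-symmetric,
so this is exact.

### Two passes and the case encoding

The whole procedure runs twice, the second time on the reverse
complement of the first pass's output.  Corrections made in pass one
create new solid k-mers that anchor pass two, and starting the path
searches from the opposite end can reach different parts of the graph
around repeats.  The head/tail extension is applied in both passes (the
published wording "for each pass ... we apply the head/tail correction"
is read literally).  Finally every base of the corrected read is
emitted upper case if it is covered by at least one solid k-mer and
lower case otherwise; `trim_corrected()` cuts weak ends and
`trim_split()` extracts the solid runs as separate records.

## Evaluation: sensitivity and gain

With simulated data the true genomic interval of every read is known, so
the evaluator needs no external mapper.  For each read, the original and
the corrected sequence are each aligned to the truth region — the
original directly from the simulator's recorded edits (or by DP),
the corrected by a unit-cost edit alignment with a deterministic
traceback (prefer match/mismatch, then deletion, then insertion) — and
the two alignments are merged column-wise on truth coordinates, padding
insertions at the same junction left-aligned.  Each column is TP
(original wrong, corrected right), FN (both wrong), FP (original right,
corrected wrong) or TN (both right), and

\[ \mathrm{Sensitivity} = \frac{TP}{TP+FN}, \qquad
   \mathrm{Gain} = \frac{TP-FP}{TP+FN}. \]

Sensitivity asks how many errors were recognised and fixed; gain
additionally penalises newly introduced errors and is the headline
statistic.  With many indels the column classification is
convention-dependent (equally-scoring alignments can shuffle columns);
the deterministic traceback and the merge convention above make the
numbers reproducible.  Two consistency rules remove artefacts: a
corrected read identical to its original reuses the original's alignment
(nothing can count as corrected), and an empty corrected read scores all
original-error columns FN and everything else TN.

## The simulator

The generator provides the study conditions every test runs under: an
i.i.d. random genome (default 50 kb, GC 0.5); fixed-length short reads
(75 bp) placed uniformly on both strands at 50x coverage with 0.5%
substitution errors; and long reads (uniform 2-8 kb, 10x) drawn from
uniform genome intervals on random strands, mutated by a per-base error
process at rate 0.15 where an error is an insertion with probability
0.55, a deletion with 0.30 and a substitution with 0.15 — the
insertion-skewed profile of PacBio chemistry, with the exact split
chosen here since only the qualitative ordering is published.  Every
edit is recorded so each read can be reconstructed from its truth
region, which the test suite verifies read by read.  All three
generators are fully deterministic in `sim_config(seed =)`; the genome,
short-read and long-read streams use `seed`, `seed + 1` and `seed + 2`
so changing one component's parameters does not silently reshuffle the
others.

What the simulator does *not* emulate: coverage biases, chimeric reads
and adapters, quality values, context-dependent (e.g. homopolymer)
errors, and real genome repeat structure — an i.i.d. 50 kb genome is
nearly repeat-free at k = 19.  Passing tests therefore demonstrate the
correctness of the machinery and its behaviour under the stated error
model, not performance on repeat-rich genomes, where bridging is
intrinsically harder and the branching limit matters far more.

## Defaults, sizes and numerical choices

| parameter | default | why |
|---|---|---|
| `k` | 19 | best accuracy in the published bacterial/yeast parameter sweeps; must be odd, at most 31 (2-bit packing in a 64-bit word) |
| `solid_threshold` | 3 | published default; modest effect, smaller is slightly better |
| `require_arcs` | `TRUE` | published solidity refinement |
| `max_error_rate` | 0.4 | published default; budget per region, anchors included |
| `branching_limit` | 200 | published default |
| `target_count` | 5 | published default |
| `max_region_span` | 500 | no published value; spans beyond ~500 bases at 15% error are vanishingly rare and quadratically expensive |

Degenerate inputs: reads shorter than `k` have no k-mer positions and
are skipped; an empty short-read set makes every k-mer weak (every read
is skipped); an all-weak corrected read trims to an empty record, kept
with a warning.  Tie-breaks — DFS child order, first-found-wins among
equal-distance paths, fewer-arcs-then-sorted-order in the shortest path,
longer-prefix in score trimming — are all fixed, so identical inputs
give byte-identical outputs; the suite asserts this end to end.

The reference problem sizes used by the test suite and the acceptance
script — a 50 kb genome, about 33 000 short reads and 100 long reads —
are the package's chosen desk-scale study conditions: large enough that
k = 19 anchors behave as on real bacterial data (about one error per
seven bases leaves solid runs every few dozen positions), small enough
that a full simulate–index–correct–evaluate cycle completes in well
under a minute.  At these conditions the pipeline reaches a gain above
0.9; the acceptance machinery only requires the much looser 0.8, since
gain depends on the stochastic error layout.

## Known limitations

* The branching limit aborts a region wholesale; candidates found before
  the abort are discarded (matching the published "abandoned" wording),
  which can leave a bridgeable region uncorrected in repeat tangles.
* One-sided fallback corrections use a heuristic weight
  (region length minus weak bases covered, floored at 1); the published
  method does not specify the adaptation.
* The evaluator's column classification inherits the usual
  indel-alignment ambiguity; numbers from other conventions can differ
  by small amounts, in either direction.
* Correction is single-threaded by design — reads are independent, and
  any parallelisation must not change the output.
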