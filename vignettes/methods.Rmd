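---
title: "Probabilistic SV discovery: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic SV discovery: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svprob)
```

## The breakpoint model

A structural variant is one or more *breakpoints*: pairs of bases
adjacent in the sample genome but not in the reference. Different
evidence classes locate a breakpoint with very different spatial
resolution, so `svprob` represents every piece of evidence the same way:
two breakpoint probability intervals (one per breakpoint end), each a
half-open reference range with a vector of relative probabilities, plus
a variety label (`DELETION`, `DUPLICATION`, `INVERSION`, `INTERCHROM`)
inferred from the evidence orientation. The label describes the
orientation signature, not certified biology — a `(+,-)` signature is
reported as a deletion even if the underlying event is more complex.

Evidence items cluster when they share a variety and chromosome pair and
their intervals intersect on *both* sides. Membership is the transitive
closure of that pairwise relation, so the outcome does not depend on the
order in which files or samples are read. Each cluster maintains
*liberal* bounds — per side, the arithmetic mean of member starts and of
member ends (floored) — rather than the intersection, because outlier
alignments typically arrive first and a max/min rule would let them drag
the cluster away from the true breakpoint.

A cluster that reaches the evidence-weight threshold becomes a call. Per
side, the call support is the intersection of member intervals
(`[max starts, min ends)`) and the distribution the per-position
**product** of member probabilities, normalized and tail-trimmed. The
product is what gives the method its resolution: one split read
multiplied into a stack of wide read-pair distributions collapses the
interval to a handful of bases. If the liberal merge admitted members
with no common support (empty or all-zero product), the fallback finds
the leftmost peak of the member *sum* per side, discards members whose
interval does not contain that point, and recomputes. A mixture (sum)
finalization is available (`mode = "sum"`) for low-quality data; it is
less precise but defined everywhere.

Each call reports the trimmed interval, a central 95% credible interval,
and the leftmost maximum-probability position, per side.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `discordant_z` (`v_l`) | 4 | apparent lengths outside `mean ± v_l·sd` are discordant |
| `v_f` | = `discordant_z` | read-pair interval extent `⌈mean + v_f·sd⌉` bases |
| `back_distance` | 20 | bases the interval extends behind the read end |
| `v_s` | 20 | split interval half-width; span `2·v_s + 1` bases |
| `decay_scale` | `v_s/4` | bases per e-fold drop of the split profile |
| `min_non_overlap` | 150 | read bases covered by exactly one split segment |
| `min_mapping_threshold` | 1 | mapq floor (10 is sensible for real data) |
| `min_total_weight` (`mw`) | 4 | evidence weight required for a call |
| `trim_keep` | 0.999 | mass kept by tail trimming (drop lowest 0.1%) |
| slop | 50 | truth padding used by the evaluator |

The published run settings expose one spread knob; `v_l` and `v_f` both
default to `discordant_z = 4` but can be set independently. Evidence
*weight* participates in thresholding only — it never exponentiates the
probability product. A weight-2 prior therefore counts as two reads
toward `mw` but shapes the distribution exactly like one uniform
interval.

The read-pair probability profile at position `i` beyond a forward read
is `D(i − x.start)`, the empirical fragment-length survival function:
the chance the fragment was long enough for its pair to span `i`. `D` is
clamped to 1 at or behind the read start, so the `back_distance` region
carries the profile maximum and `p` is non-increasing away from the
read. The library (`mean`, `sd`, `D`) is estimated from properly-paired
records, loaded from a `length<TAB>count` histogram, or — when only
`mean`/`stdev` are given — taken as a normal upper tail.

## Multi-sample calling

Every evidence channel carries a sample identifier; clustering is
sample-blind, and thresholds are applied to the pooled cluster.
`calling_thresholds()` supports the published family designs:
`per_sample_min` (at least one named sample reaches its own minimum —
the "support of four from at least one individual" rule) and
`required_samples` (each must contribute positive weight, e.g. the
proband). The spec text for `per_sample_min` was ambiguous; this reading
is the one that reproduces the trio protocol.

## Choices the sources left open

* **Trimming semantics.** The published description ("lowest 0.1% of the
  distribution") is ambiguous between mass-based and value-rank-based
  trimming. `trim_distribution()` is mass-based and end-anchored: it
  repeatedly removes whichever *terminal* position carries less
  probability while the removed mass stays within `1 − keep`, then
  renormalizes. Ties remove the right end, so `keep = 0` degenerates to
  the leftmost argmax. Rank-based trimming is not implemented.
* **Left/right convention.** The first read of the canonical pair maps
  to the left interval and its mate to the right, even when a short
  event makes the mate's upstream-extending interval *start* earlier on
  the chromosome. Ordering sides by interval start instead (an early
  implementation) silently multiplies distributions belonging to
  opposite breakpoint ends whenever the event is shorter than the
  fragment spread. Split evidence orders sides by junction center;
  generic and inter-chromosomal evidence order by `(chromosome, start)`
  under natural chromosome ranking.
* **Duplication split centers.** The duplication rule is applied with
  the *genomically first* segment in the role of the formula's first
  segment, so the two centers land on the duplicated unit's start and
  end — the same two positions the read-pair channel brackets. Applying
  the formula in query order would place both centers a segment-length
  inside the unit.
* **Double counting.** A fragment whose read crosses a junction cleanly
  enough to split would otherwise appear twice — once as a split, once
  as a discordant pair built from the split read's primary segment. The
  pair channel therefore skips fragments in which either mate is split;
  soft-clipped (non-split) crossing reads still pair normally, as they
  do in real aligner output.
* **Mean bounds** are unweighted (evidence weight does not move cluster
  bounds), and argmax/fallback-peak ties break leftmost, for
  determinism.
* **Numerics.** Products run in log space with a per-factor floor of
  1e-300 (safe for clusters of 10^4 members); read-pair profile
  positions past the longest observed fragment get 1e-12 rather than 0
  so a single stale outlier cannot zero an otherwise coherent product;
  reverse-orientation profiles use offsets `D(end − i)` exactly, which
  differ from the mirrored forward profile by the one-base shift
  inherent to half-open coordinates.

## The simulator: what it emulates, what it does not

`sim_config()` + `simulate_variants()` build a variant-bearing genome
from a random (or supplied) reference: deletions remove their segment,
tandem duplications repeat it in place, inversions reverse-complement
it, and translocation-style insertions copy a 1 kb donor segment from
another chromosome — each recorded as one or two novel adjacencies in a
truth table. A piecewise block map links altered and reference
coordinates. `simulate_alignments()` draws fragments uniformly at
`Normal(500, 50)` lengths (150 bp reads, the published geometry),
pushes both reads through the map, and renders: contiguous records;
split records (primary + supplementary) when a read crosses an
adjacency with at least `min_flank = 20` aligned bases on both sides;
soft-clipped records below that. Mate fields and insert sizes reflect
reference-space geometry; fragments wholly inside one block are flagged
properly paired. Output is an in-memory record table or SAM text, and
`mix_samples()` pools variant-genome and reference-genome reads at an
exact allele-frequency split. Everything is deterministic under
`seed` (the generator uses a private RNG stream and restores yours).

Deliberately *not* emulated: repeats and mappability (every read maps
uniquely and exactly), base errors (an optional concern of aligners,
not of clustering), GC bias, chimeras, PCR duplicates. Consequently a
green simulation establishes the correctness of the evidence geometry,
clustering and scoring — not performance on a real genome. Idealized
mapping biases sensitivity *upward* relative to published human-genome
values, most visibly at low coverage; the scaled-down studies carry
explicit tolerances for this. Two stated-world choices fixed before any
measurement: variants are placed with a 1 kb buffer (two fragment
lengths) so desk-scale clusters of neighboring variants stay distinct,
and the tumor-mixture study draws deletion sizes log-uniformly from
50 bp–10 kb to mimic the small-size skew of the population callset the
original study embedded.

## Evaluation

`pad_truth()` expands each simulated breakpoint by 50 bp of
bidirectional slop; `match_calls()` counts a call as a true positive
when both of its intervals intersect the two intervals of one truth
record and the varieties match. Each call is assigned to at most one
truth record (greedy by overlap); each truth *variant* counts once
toward sensitivity however many calls or adjacencies hit it (an
inversion's two adjacencies are "any-adjacency" detected); unmatched
calls are false positives, and duplicate hits collapse by default
(`strict = TRUE` makes them FPs). `pad_point_calls()` widens single-base
calls from point-resolution external callers to 28 bp (split support)
or 282 bp (pair-only) before matching, mirroring the published
comparison protocol.

## Known limitations

No genotyping, no VCF/BND output, no CRAM, no insertion variants fully
contained in a read (their split geometry needs read-space sizes during
clustering), no native read-depth signal (consume a segmentation through
the generic channel instead), one fragment library per read-pair
channel (use several channels for multi-library samples). Excluded
regions must be supplied or derived from a depth track
(`compute_excluded_regions()`, the `2·mode + 3·sd` rule with
autosome/sex-chromosome separation and full mitochondrial exclusion).
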