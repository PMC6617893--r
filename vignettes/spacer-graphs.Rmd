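---
title: "Compressed spacer graphs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed spacer graphs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacergraphs)
```

## The problem

A CRISPR array is a genomic tape recorder: short direct repeats alternate
with ~30 bp spacers copied from past invaders, new spacers are integrated at
the leader end, and internal blocks are occasionally deleted. Long reads
capture whole arrays, so a single metagenome sample contains many partially
overlapping *variants* of the same array — the raw material for studying
acquisition and loss without time series. `spacergraphs` turns a table of
per-read arrays into labeled spacer sequences, groups of spacer-sharing
arrays, and *compressed spacer graphs* that summarize each group's
organizational diversity, plus orientation and trailer-conservation calls,
redundancy statistics, and an intra-sample protospacer search.

## Spacer clustering

Spacers are clustered greedily, longest first, cd-hit style: a sequence
joins the first cluster (founding order) whose representative it matches at
`identity >= 0.90`, else it founds a cluster. The 0.90 default absorbs a
small number of sequencing errors or true point mutations in a ~30 bp
spacer while keeping distinct spacers apart (two random 30-mers essentially
never reach 90%).

Identity is defined as matched bases in an optimal alignment divided by the
length of the shorter sequence, with match = +1 and mismatches and gaps
contributing nothing (end gaps free). With zero gap cost the optimum equals
the longest common subsequence over exact base matches — deliberately
simple for ~30 bp sequences, where affine gap models add parameters without
changing decisions at a 90% threshold. `N` never matches anything.
`strand_mode = "both"` (default) also scores the reverse complement, so
spacers extracted from opposite-strand array calls co-cluster.

No k-mer prefilter is used: because internal gaps are free, no fixed-length
seed is provably shared by all pairs above threshold, and the compiled
alignment kernel keeps the exhaustive member-versus-representative scan
fast at realistic spacer counts. A lossless accelerator is an extension
point, not a correctness requirement.

## Grouping spacer-sharing arrays

Arrays relabeled as integer sequences are grouped greedily: the largest
unclustered array founds a group; sweeps (in spacer-count order) add any
array sharing at least one label with any current member of any group,
first-founded group winning, until a sweep adds nothing; then the next
reference is chosen. Sweeping to a fixed point makes membership transitive
— an array joins if it shares a spacer with *any* clustered array, not only
the reference. The stricter reference-only reading is available via
`transitive = FALSE`. Ties on spacer count break by `array_id` so results
are reproducible. Singletons are kept as groups of one; the
`min_group_report = 10` threshold is a reporting filter (which groups get
graphs), never a clustering parameter.

## Spacer graphs and compression

Within a group, each array contributes one edge per adjacent label pair;
edge support counts how often an adjacency is observed. Compression is
unitig-style edge contraction: `u -> v` merges whenever `out(u) == 1` and
`in(v) == 1`. Three guards keep every array readable as a single contiguous
walk:

* labels occurring twice within one array are pinned to singleton blocks
  (merging them would make walks ambiguous);
* an edge with a reverse partner (`v -> u`) is never contracted (a 2-cycle
  inside a block cannot be spelled as one pass);
* fragmented arrays may *enter or leave* a block mid-way, but only at walk
  ends — the walk computation verifies this and records entry/exit offsets.

The contraction fixed point is order-independent; edges are still processed
in deterministic label order, and blocks are renumbered by first label so
output is canonical. A `strict = TRUE` variant additionally requires
`in(u) <= 1` and `out(v) <= 1` — the literal "both nodes have in- and
out-degree at most one" rule. The two differ only where a chain hangs off a
junction; both reproduce the canonical chain-plus-bypass example
(`a,b,c,d` + `a,d` → blocks `a`, `[b-c]`, `d` with three edges).

The *dominant path* is the walk of the most frequent array organization,
counted over arrays complete at both ends (fragments would otherwise vote
as distinct organizations); ties go to the longer organization, then the
lexicographically smallest label sequence. Sources (in-degree 0) are where
newly gained spacers accumulate; the sink holds the conserved trailer-end
"anchor" spacer. DOT export and `autoplot()` color sources blue, sinks
yellow (sink wins on a lone block), dominant-path edges red, leader on the
left.

## Orientation and trailer conservation

Two independent signals are combined:

* **Repeat degeneracy** — mean mismatches of the last repeat against the
  positionwise-majority consensus minus the same for the first repeat,
  using only arrays whose respective end is complete. Positive means the
  right end decays, i.e. it is the trailer. With no eligible ends the score
  is `NA` with a warning, never silently zero.
* **Graph topology** — `sign(n_sources - n_sinks)`. Leader-end acquisition
  produces many alternative sources funneling into one sink. Terminal-block
  *counts* are the diversity measure: counting labels inside terminal
  blocks would let the long conserved core, which compresses into the sink
  block, swamp the signal.

Agreeing signs give a high-confidence call; one informative signal gives a
low-confidence call; conflicts yield `undetermined` with both scores
reported. Conflicts are surfaced deliberately — dedicated orientation
predictors disagree on real arrays, and silently resolving the disagreement
would hide exactly the interesting cases.

Trailer conservation reports the modal trailer-end label (ties: smallest
label) among arrays whose trailer-side end is complete; fragments carry no
evidence about the true terminal spacer and are excluded by the
completeness flags.

## The simulator's stated world

`sim_config()` defaults describe one diversifying locus: a 20-spacer
ancestor with 30 bp spacers and repeats, 50 sampled lineages, Poisson(0.3)
novel leader insertions and Poisson(0.1) internal deletions of
geometric-length blocks (mean 3) per lineage, 0.5% per-base substitution,
and 3 mismatches planted once in the *ancestral* trailer-proximal repeat —
degeneracy is a property of the locus, so descendants inherit it. The
trailer spacer is protected from deletion by default, mirroring observed
anchor conservation; with protection on, trailer conservation among
complete-ended arrays is exactly 1 at the true-label level for any seed
(clustering noise on real sequences can still split a trailer label — that
is an artifact of measurement, not of the locus). Gains are always novel
sequences (no reacquisition), matching the observation that leader spacers
are group-specific; mid-array insertion and multi-ancestor recombination
are documented extensions, off by default. Strand randomization is off by
default because graph construction assumes a consistent within-group
orientation, as upstream array detection provides.

What the generator does *not* emulate: platform-specific error profiles
(only uniform substitutions), GC bias, chimeric reads, and between-group
spacer sharing. A green simulation-based test therefore establishes
algorithmic correctness on the stated world, not detector robustness on
raw sequencing data.

Read fragmentation truncates each end independently with the configured
probability, removing at least one unit when possible but never emptying an
array, and clears the end's completeness flag; truncated ends keep their
boundary repeat so the `n + 1` repeat layout is uniform. Every stochastic
draw flows through one seeded RNG, and `replay_array()` rebuilds any
emitted array from the recorded event history exactly.

## Protospacer search

The spacer-versus-reads matcher is a deterministic in-package replacement
for an external BLAST step: exact 12-mer seeds on both strands anchor
candidate placements, each extended to a full-spacer alignment; spacers
shorter than the seed fall back to exhaustive placement. Because gaps are
free, an optimal alignment's coordinates are ambiguous at the ends; the
reported span is the *tightest* one attaining the optimal match count
(computed from forward and reverse DP rows), so exact plants are recovered
at exact coordinates. A hit needs `matches / spacer_length >= 0.90` and a
matched span covering `>= 0.95` of the spacer — defaults chosen here, since
no thresholds are inherited from upstream tooling. Hits overlapping a
declared CRISPR interval by one or more bases are kept but flagged
`in_crispr_region`, keeping the exclusion auditable; self-targeting spacers
are reported, not filtered, because invader status is an ad hoc judgement.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere (intervals, hits, BED).
* Redundancy (`n_spacers / n_clusters`) is kept at full precision
  internally; printing rounds to 2 decimals.
* Empty array tables produce empty outputs with a warning, not an error;
  zero-label arrays and duplicate ids are validation errors.
* A deletion that would exceed the array, empty it, or hit a protected
  trailer is resampled (bounded retries); a lineage is never emitted with
  zero spacers.
* Reporting rounds and tie-breaks (cluster founding order, `array_id`
  order, smallest-label anchors) are all deterministic so reruns are
  byte-identical.

## Known limitations

* Greedy grouping is order-dependent in principle: a group founded early
  can fail to absorb arrays that only later become connected through
  another group's growth, so groups refine, but need not equal, connected
  components of the sharing graph. The naive-rule equivalence and
  component-refinement properties are both tested.
* The clustering scan is quadratic in the number of clusters; datasets of
  ~50k spacers are minutes, not seconds.
* Orientation inference is a heuristic combination of two signs; groups
  with a single organization and clean repeats are honestly
  `undetermined`.
* Conversion from upstream CRISPR-detector output formats to the array TSV
  is an extension point; no detector output parser ships in the package.
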