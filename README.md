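# spacergraphs

Characterizing the diversity and dynamics of CRISPR arrays captured in long
sequencing reads. Long reads cover whole arrays, so one metagenome sample
contains many overlapping variants of the same array; `spacergraphs` is for
microbiome researchers who want to read acquisition and loss events,
array orientation, and trailer-end conservation out of that variation —
from a single time point, without isolates or time series.

## What it computes

Given arrays as ordered repeat/spacer sequences per read (a documented TSV;
array *detection* is upstream and out of scope):

1. **Spacer clustering** — greedy, longest-first clustering at 90% identity
   (cd-hit semantics: each sequence joins the first cluster whose
   representative it matches, identity = matches / min(|a|, |b|), reverse
   complements included), so near-identical spacers share an integer label
   and arrays become label sequences.
2. **Array grouping** — the largest unclustered array founds a group;
   arrays sharing ≥ 1 label with any member join, swept to a fixed point.
3. **Compressed spacer graphs** — per group, a directed graph with one node
   per spacer label and edges for observed adjacencies (support = counts),
   then unitig-style contraction of every edge u→v with out(u) = in(v) = 1
   into blocks. Every array remains a contiguous walk. Sources (in-degree
   0) hold newly gained leader spacers; the sink holds the conserved
   trailer "anchor" spacer; the dominant path is the most frequent
   organization.
4. **Orientation** — sign of the repeat-degeneracy contrast (trailer repeat
   decays) combined with graph topology (sources vs sinks); conflicts are
   reported as `undetermined`, never silently resolved.
5. **Statistics** — spacer redundancy `n_spacers / n_clusters` (≈ 9 for
   long reads vs ≈ 1.01 for short-read assemblies of the same gut
   microbiome), trailer conservation, per-group reports.
6. **Protospacer search** — spacers matched back against same-sample reads
   (seeded, deterministic, both strands); hits inside declared CRISPR
   intervals are flagged `in_crispr_region` rather than dropped.
7. **Simulator** — a forward model of array evolution (leader gains,
   segmental losses, point mutations, trailer-repeat degeneracy, read
   fragmentation) with a replayable event history, so every stage is
   testable without downloads.

## Worked example

```r
library(spacergraphs)

sim <- simulate_population(sim_config(seed = 20, population_size = 15,
                                      n_ancestral_spacers = 10))
res <- run_pipeline(sim$arrays, min_group_report = 10)

res$redundancy
#> # Spacer redundancy: 149 spacers / 13 clusters = 11.46

res$graphs[["1"]]
#> # Compressed spacer graph: 8 blocks, 9 edges; 3 source(s), 1 sink(s)
#> # blocks: [1-3] [4-5-6] 7 8 [9-10-2] 11 12 13

res$orientations[["1"]]
#> # A tibble: 1 × 5
#>   group_id orientation degeneracy_score topology_score confidence
#>      <int> <chr>                  <dbl>          <dbl> <chr>
#> 1        1 as_given                2.93              1 high
```

The 15 simulated arrays share 13 spacer labels in 8 blocks: three source
blocks (recently gained leader spacers, drawn blue) funnel into the
conserved core, ending at the single sink with the anchor spacer (yellow).
The degeneracy score ≈ +2.9 recovers the 3 mismatches planted in the
trailer repeat, agreeing with the topology signal, so the orientation call
is `as_given` with high confidence. `autoplot(res$graphs[["1"]])` draws the
graph; `write_dot()` exports Graphviz DOT with the same coloring.

A thin command-line front end over the same functions ships at
`inst/cli/spacergraphs` (subcommands `simulate`, `cluster-spacers`,
`cluster-arrays`, `build-graph`, `stats`, `protospacer`, `run-all`).

## Acceptance script

`scripts/acceptance.R` regenerates a simulated multi-group dataset from the
given seed, runs the complete pipeline (clustering → grouping → graphs →
orientation/trailer calls → redundancy), prints the per-group report, and
writes the JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
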