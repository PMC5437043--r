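---
title: "Ranking plastome mutational hotspots: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking plastome mutational hotspots: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastohotspot)
```

## The problem

Chloroplast genomes (plastomes) of closely related plant species — the
motivating case is the orchid genus *Dendrobium* — are ~150 kb circles with
a conserved quadripartite architecture: a large single-copy region (LSC), a
small single-copy region (SSC), and two identical inverted repeats (IRa,
IRb), so that total length = LSC + SSC + 2×IR. Within a genus, gene content
and order are essentially fixed; what varies are the lengths of the regions,
insertion/deletion (InDel) events, microsatellite (cpSSR) repeat counts, and
point substitutions concentrated in a minority of intergenic spacers and
introns — the *mutational hotspots* that make good markers for species
identification and low-level phylogenetics.

`plastohotspot` implements the comparative workflow that turns a set of
annotated plastomes into a ranked hotspot catalogue and a recommended
marker combination:

1. **Quadripartite accounting** — region lengths, AT content, retained NDH
   gene length, and signed "changed lengths" of each taxon against a
   reference, with Spearman correlations between them.
2. **InDel analysis** — pairwise global alignment against the reference,
   region by region; each maximal gap run is one event; events are classed
   by region and by NDH-relatedness; distribution and correlation tests.
3. **Sequence variability (SV)** — for each syntenic intergenic/intronic
   locus, over all unordered taxon pairs:
   SV = (mutations + InDel events) / (conserved sites + mutations + InDel
   events) × 100, averaged per locus; loci are ranked by mean SV.
4. **cpSSR detection** — maximal perfect tandem repeats (mono ≥ 8 units,
   2–6 bp motifs ≥ 5 units), matched across taxa by flanking context and
   classed polymorphic when repeat counts differ.
5. **Combination analysis** — all 2^k − 1 subsets of the top-k hotspots are
   concatenated, a bootstrapped distance tree is inferred for each, and
   subsets are scored by the mean bootstrap support (BS) of ingroup
   internal edges; a regression of mean BS on subset size and a plateau
   detector summarize how many hotspots are worth combining.

## Statistical kernels

Three procedures are implemented self-contained, because every downstream
table depends on their exact conventions:

* **Spearman correlation**: Pearson correlation of midranks; two-sided p
  from the t distribution with n − 2 df. This matches the default
  behavior of mainstream statistics packages at these sample sizes, and
  the t-approximation keeps p-values comparable across the n = 10–30 range
  the pipeline produces. A constant vector is an error, not NA: every
  caller that can legitimately produce a constant (e.g. the combination
  correlations at fixed subset size) catches it and reports NA explicitly.
* **Mann–Whitney U, two-sided**: U uses midranks. Up to a pooled n of 12
  the p-value is exact by full enumeration of group assignments, defined
  as P(|U − E(U)| ≥ |u − E(U)|) under the permutation null; beyond that a
  normal approximation with tie correction and a 0.5 continuity correction
  is used. The two definitions agree within 0.05 on balanced continuous
  samples of ten, which the tests verify.
* **OLS line**: closed-form least squares with R² = 1 − SSE/SST; a
  constant response is reported as slope 0, R² = 0.

## Alignment conventions

Pairwise global alignment uses affine gap costs (match +1, mismatch −1,
gap open 4, gap extend 0.5) through `Biostrings::pairwiseAlignment`; the
traceback is deterministic, and a brute-force enumeration oracle checks
optimality on small strings in the test suite. Conventions that matter
downstream:

* **Region-by-region alignment.** LSC aligns with LSC, SSC with SSC, and
  one IR copy with one IR copy. This avoids spurious cross-boundary gaps
  and means IR events are counted once, in line with treating the two IRs
  as a single class.
* **One event per maximal gap run**, regardless of length; adjacent gap
  runs in opposite rows are two events. Terminal gap runs are excluded —
  they reflect ends, not InDels.
* **SV trimming.** Before counting, terminal gap runs are removed; SV is
  undefined (NA, with a warning) if nothing remains. `pairwise_sv()`
  canonicalizes argument order before aligning, because SV is symmetric by
  definition while tie-broken gap placement need not be.
* **NDH-relatedness window.** An event is NDH-related when its reference
  interval (for insertions, the two flanking bases) comes within 50 bp of
  an annotated `ndh*` feature. The window absorbs the scars that gene
  truncation leaves just outside the annotated extent.

Multiple alignments are built center-star: the center is the taxon with the
best summed pairwise score; all others are merged against it under "once a
gap, always a gap". Center-star is a heuristic — where pairwise homology is
ambiguous it may shift a gap relative to the simultaneous optimum — but
degapping always recovers the inputs exactly, which is the invariant the
downstream bootstrap actually needs.

## Tree inference and mean bootstrap support

The combination score needs thousands of small trees, so the engine is
neighbor joining on Jukes–Cantor distances with pairwise deletion of
gap/N sites. Distances are computed in-package because two conventions
need to be explicit: a saturated pair (mismatch fraction ≥ 0.75, where the
JC correction diverges) is capped at a configurable maximum (default 3
substitutions/site) with a warning, and a pair sharing no scorable column
is a hard error naming the pair. `ape::dist.dna` serves as the
cross-check oracle in the tests.

Supports are classical nonparametric bootstrap: columns resampled with
replacement, NJ rerun, and each internal bipartition of the point tree
scored by its replicate frequency. Trees are rooted on the outgroup clade.
`mean_bs()` averages supports over *ingroup internal edges*: the root, the
ingroup crown edge (identical to the ingroup/outgroup split) and the
outgroup clade are excluded by default, because those edges are fixed by
the rooting, not by the marker's signal; `scope = "all"` is available for
comparison. Whether a mean-BS figure includes outgroup-adjacent nodes is
exactly the kind of unstated convention that changes absolute values by a
few points, which is why it is a documented switch rather than a silent
choice.

The plateau is the smallest subset size whose per-size mean BS is within a
tolerance (default 2 BS points) of the maximum per-size mean. The
regression of mean BS on subset size is fitted over all combinations, not
per-size means: the per-combination scatter is informative (its R² < 1
reflects genuine between-combination variance) and matches how the
relation is usually reported.

## The synthetic-data generator

Every stage is testable without downloading an accession because the
package ships a generator with known ground truth. What it emulates:

* a quadripartite ancestor with a realistic plastid gene order, named
  spacers/introns (each ≥ 150 bp, plus short decoys below the filter), the
  11-gene NDH family with ndhB in the IRs and most others in the SSC, and
  seeded SSR tracts;
* a Yule ingroup tree joined to an outgroup clade on a long stem;
* per-branch Jukes–Cantor substitutions, with a rate multiplier m > 1
  inside designated hotspot loci (hotspot sequence is also drawn AT-rich,
  so the SV–GC anticorrelation emerges by construction);
* region-biased InDels (LSC highest), geometric lengths (p = 0.3, capped
  at 30 bp at test scale), applied to one IR copy and mirrored so IRa stays
  the reverse complement of IRb;
* SSR slippage: per branch, each seeded tract gains or loses one repeat
  unit with a configurable probability;
* NDH loss: designated terminal lineages have genes truncated (3′ half
  removed, pseudo flag set) or fully deleted.

Each node's sequence carries a per-base map to ancestral coordinates;
annotations are lifted through that map, and the ground-truth InDel list is
*derived from the map* rather than logged event by event, so the truth is
replayable by construction (the tests verify that region lengths equal the
ancestral length plus the net signed truth InDels).

Default rates are chosen to mimic a within-genus plastome comparison:
root-to-tip expected substitutions 0.02/site, InDel rates per site of
0.002 (LSC), 0.001 (SSC) and 0.0003 (IR) — matching the empirical pattern
of a few hundred events per ~150 kb pair concentrated in the LSC — and a
background AT content of 62%.

What the generator does *not* emulate: codon structure and selection on
coding sequence, IR boundary expansion/contraction (region lengths change
only through InDels), recombination, and compound/imperfect SSRs. Passing
tests therefore demonstrate that the pipeline recovers planted signal of
the kind real plastomes display, not that any particular biological claim
about a real genus is reproduced.

## Problem sizes

Desk-scale runs use 15 kb genomes (the quadripartite proportions of a
150 kb plastome scaled down), 10–15 ingroup taxa plus 3 outgroups, 12
loci with 2 decoys, and 100–200 bootstrap replicates; the enumeration
guard allows up to 16 hotspots (65,535 subsets). These sizes exercise the
complete pipeline — including the 63-combination analysis of a top-6
hotspot set — in minutes on one core. All sizes scale up by configuration;
nothing in the code is specific to the test scale.

## Degenerate inputs and edge conventions

* Empty sequences cannot be aligned (error); an alignment that is all
  terminal gaps has undefined SV (NA + warning) and the pair is skipped.
* A locus present in fewer than two taxa of the current subset is excluded
  from the SV table with a warning; rank tables mark loci outside the
  tracked top with an NA, written as the "–" sentinel.
* Ranks are ordered by mean SV descending with ties broken
  lexicographically by locus name, so output orderings are reproducible.
* In the top-combination table, equal mean BS ranks the smaller subset
  first; the recommendation is the minimal-size member of the top set.
* The pair set for mean SV is all C(n,2) unordered distinct pairs, and the
  pair count is carried in the output for audit.
* GC content of a locus is computed on the reference taxon's sequence — a
  single deterministic representative.

## Known limitations

Center-star alignment and NJ-with-bootstrap are deliberate stand-ins for
heavier simultaneous-alignment and ML machinery; the combination-scoring
procedure is engine-agnostic, and the absolute mean-BS level depends on
the engine even though the ranking it induces is what the analysis
consumes. The SSR homology matching uses flanking context rather than full
locus alignment and can miss a site whose flanks have diverged beyond the
mismatch allowance. The SV statistic weights a substitution and an entire
InDel event equally, as defined.
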