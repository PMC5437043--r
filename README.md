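# plastohotspot

Comparative plastome analysis for marker selection: quadripartite length
accounting, InDel-event analysis, a sequence-variability (SV) statistic
that ranks mutational hotspots among syntenic intergenic/intronic loci,
polymorphic chloroplast microsatellite (cpSSR) detection, and an
exhaustive multi-hotspot combination analysis scored by mean bootstrap
support — plus a synthetic-plastome generator with known ground truth so
the whole pipeline runs and is tested without downloading a single
accession.

## Who this is for

Plant molecular systematists choosing loci for species identification or
low-level phylogenetics in groups (orchids being the motivating case)
where whole plastomes are available for a handful of taxa and the question
is: *which* intergenic spacers and introns are the fastest evolving, and
*how many* of them must be combined before tree support stops improving?

## The statistics at the core

For each syntenic locus, over every unordered pair of taxa in which it is
present, the package aligns the two sequences, trims terminal gaps, and
computes

> SV = (nucleotide mutations + InDel events) /
>       (conserved sites + nucleotide mutations + InDel events) × 100,

where an InDel event is one maximal internal gap run. Loci are ranked by
mean SV over all C(n, 2) pairs. All 2^k − 1 subsets of the top-k hotspots
are then concatenated; each subset gets a neighbor-joining tree on
Jukes–Cantor distances with nonparametric bootstrap supports, and is
scored by the mean support of ingroup internal edges (mean BS). A
regression of mean BS on subset size and a plateau detector (smallest k
within 2 BS points of the maximum per-k mean) summarize the
size/performance trade-off. Supporting analyses: changed-length
correlations of LSC/SSC/IR against total plastome length (Spearman),
region-biased InDel distribution tests (two-sided Mann–Whitney), and
cpSSR detection at the mono ≥ 8 / multi ≥ 5 unit thresholds with
cross-taxon polymorphism calls.

## Worked example

Simulate a small annotated plastome set with four planted hotspots, rank
the loci, and score every combination of the top six:

```r
library(plastohotspot)

cfg <- sim_config(n_taxa = 10, genome_scale = 15000, n_loci = 12,
                  hotspot_loci = 4, hotspot_multiplier = 5, seed = 7)
sim  <- simulate_plastome_set(cfg)
loci <- extract_syntenic_loci(sim$records, reference_id = "t01")
svt  <- mean_sv_table(loci)
head(svt, 5)
#> # A tibble: 5 × 7
#>   locus       type   region mean_sv gc_percent n_pairs  rank
#>   <chr>       <chr>  <chr>    <dbl>      <dbl>   <int> <int>
#> 1 psbA-trnH   spacer LSC      13.8        32.5      78     1
#> 2 rps16-trnQ  spacer LSC      12.5        31.4      78     2
#> 3 atpI-rps2   spacer LSC      12.5        28.3      78     3
#> 4 rpl2-ndhB   spacer IR       12.4        29.9      78     4
#> 5 trnL intron intron LSC       3.48       41.4      78     5
```

The four planted hotspots (`psbA-trnH`, `rps16-trnQ`, `atpI-rps2`,
`rpl2-ndhB`) occupy ranks 1-4: their mean SV (12-14%) separates cleanly
from the background loci (~3.5%), and their GC content is visibly lower —
the AT bias that real plastome hotspots show. `n_pairs = 78` is all
C(13, 2) pairs of the 10 ingroup + 3 outgroup taxa.

```r
res <- hotspot_combinations(loci, svt, hotspots = head(svt$locus, 6),
                            outgroups = c("og1", "og2", "og3"),
                            n_replicates = 100, seed = 1)
pa <- plateau_analysis(res)
pa
#> <plateau_analysis> 63 combinations, k = 1..6
#>   mean BS = 0.91 k + 87.65 (R^2 = 0.075)
#>   plateau at k = 5 (mean BS 92.0, tolerance 2)
glance(pa)
#> # A tibble: 1 × 6
#>   slope intercept r_squared plateau_k plateau_mean_bs n_combinations
#>   <dbl>     <dbl>     <dbl>     <int>           <dbl>          <int>
#> 1 0.913      87.6    0.0749         5            92.0             63
```

Mean BS climbs with the number of combined hotspots and flattens at
k = 5 on this synthetic set; `autoplot(pa)` draws the mean ± SD curve
with the fitted line, and `top_combinations(res)` lists the
best-supported subsets with the minimal-size recommendation flagged.

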