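# ighrep

Similarity analysis of B cell receptor (BCR) heavy-chain repertoires.

Even inbred, untreated mice carry largely private antibody repertoires.
Anyone designing an immunization or infection experiment needs to know the
*baseline* similarity between individuals — otherwise treatment effects
cannot be told apart from ordinary mouse-to-mouse variation. `ighrep` is an
R package for making that measurement on IgH (heavy-chain) repertoires,
stratified by isotype (IgA/IgG/IgM) and tissue (blood/spleen), at three
scales:

* **gene usage** — pooled V/D/J frequency profiles compared by Pearson
  correlation;
* **CDR3 clonotype** — abundance profiles compared by the Morisita–Horn
  similarity index
  $\mathrm{MHSI} = 2\sum_i p_i q_i \,/\, (\sum_i p_i^2 + \sum_i q_i^2)$,
  evenness by the normalized Shannon diversity entropy
  $\mathrm{NSDE} = -\sum_i p_i \ln p_i / \ln N$, richness by Chao1
  ($S_{obs} + f_1^2/2f_2$) with bootstrap rarefaction, Chao-based
  extrapolation and sequencing coverage, and clonotype sharing across
  individuals;
* **clonal lineage** — networks over CDR3 nucleotide clonotypes grouped by
  identical V gene, J gene and CDR3 length, with edges at ≥ 95% nucleotide
  identity; lineages are connected components of ≥ 2 nodes, the proportion
  of mutated clonotypes and the network degree distribution summarize
  somatic hypermutation, and cross-individual lineages are traced back to
  every sample carrying one of their nodes.

Upstream of the statistics, the package demultiplexes raw reads into
isotypes by constant-region primer matching (Hamming mismatches over a
fixed read window, IUPAC-aware) and filters clone tables to qualified
clones (CDR3 ≥ 4 aa, stop-free, in frame). A seeded synthetic-repertoire
generator plants known lineage, sharing and abundance structure so the
whole pipeline is testable without sequencing data. Input and output use
AIRR Rearrangement TSVs with a configurable column mapping.

## Worked example

Simulate a three-mouse study, then measure blood IgM similarity between
individuals:

```r
library(ighrep)
library(dplyr)

sim <- simulate_repertoires(sim_config(n_individuals = 3,
                                       n_clonotypes = 500, seed = 42))
sim
#> Simulated repertoire: 2999 clone records, 6 samples, 3 individuals (BAL)

blood_igm <- filter(sim$clones, tissue == "blood", isotype == "IgM")
profs <- lapply(split(blood_igm, blood_igm$mouse_id), clonotype_profile)

mhsi(profs$m01, profs$m02)
#> [1] 0.000858913
nsde(profs$m01)
#> [1] 0.7893499
chao1(profs$m01); coverage_pct(profs$m01)
#> [1] 398.25
#> [1] 74.57627
```

The MHSI near zero says the two mice share almost no CDR3 clonotype mass
(only planted public clonotypes overlap); the NSDE of 0.79 reflects the
skewed clonal abundance; the Chao1 estimate says mouse m01's observed 297
clonotypes cover about 75% of its estimated richness.

Lineage structure and sharing:

```r
net <- build_lineages(filter(blood_igm, mouse_id == "m01"))
net
#> Clonal lineage network: 300 clonotypes, 31 edges (>= 95% identity), 24 lineages (>= 2 nodes)
mutated_ratio(net)
#> [1] 18
degree_stats(net)$max_degree
#> [1] 2

sharing_ratios(split(blood_igm, blood_igm$mouse_id))
#> # A tibble: 3 × 3
#>       k n_clonotypes    pct
#>   <int>        <int>  <dbl>
#> 1     1          827 97.3
#> 2     2           19  2.24
#> 3     3            4  0.471
```

18% of m01's clonotypes sit in somatic-mutation lineages (the simulation
planted 20% repertoire-wide), and 97% of the clonotype union is private to
a single mouse — the hallmark of baseline BCR repertoires.

`run_pipeline(run_config(input = <AIRR dir>, out_dir = <dir>))` runs every
stage over a directory of AIRR TSVs and writes per-subset summaries,
pairwise Pearson/MHSI matrices, rarefaction curves, lineage and sharing
tables, plus a `manifest.json`; identical inputs and seed reproduce the
bundle byte for byte. See the vignette
(`vignettes/repertoire-similarity.Rmd`) for the statistical model and all
tunable parameters.

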