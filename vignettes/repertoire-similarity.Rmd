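---
title: "Measuring IgH repertoire similarity with ighrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring IgH repertoire similarity with ighrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighrep)
library(dplyr)
```

## The problem

Inbred laboratory mice are the workhorse of antibody discovery and
immunization studies, yet even genetically identical individuals carry
largely private B cell receptor (BCR) repertoires. Before attributing a
repertoire change to an experimental treatment, one needs to know how much
two *untreated* mice differ at baseline — and that answer depends strongly
on the scale of comparison (germline gene usage, CDR3 clonotype, or clonal
lineage), on the antibody isotype (IgA, IgG, IgM), and on the tissue
sampled (blood vs spleen). `ighrep` implements the full measurement
pipeline for heavy-chain (IgH) repertoires: from raw-read isotype
demultiplexing and qualified-clone filtering through diversity and overlap
statistics to clonal-lineage networks and cross-individual lineage sharing,
together with a synthetic-repertoire generator that makes every stage
testable without sequencing data.

## Input model: clones and clonotypes

The unit of input is a *clone*: one qualified rearrangement record with V/D/J
gene calls, the CDR3 nucleotide and amino-acid sequence, and an abundance
(`count`). Qualification (`filter_qualified()`) requires a CDR3 of at least
4 amino acids, free of stop (`*`) and frame-break (`_`) symbols, with
`nchar(cdr3_nt) == 3 * nchar(cdr3_aa)` (the in-frame check is confined to
the CDR3 triplet relation; the upstream clone caller owns full V(D)J frame
logic). A *clonotype* aggregates all clones sharing a key: the CDR3 amino
acid sequence for diversity and overlap statistics, or the
`(V, J, CDR3 nt)` triple for lineage work. Tables are read and written as
AIRR Rearrangement TSVs through a configurable column mapping
(`airr_default_mapping()`).

When a sample was sequenced in technical duplicate, statistics use only the
replicate with the larger criterion value (clones or clonotypes;
`select_technical_duplicate()`), with a lexicographic tie-break for
determinism.

## Isotype demultiplexing

Libraries built with isotype-specific constant-region primers allow each
read to be classified by comparing a fixed window at the start of the read
against every primer. Mismatch counting is positional (Hamming, no indels),
because the primers sit at a fixed position by library design; degenerate
IUPAC codes in a primer match any base they stand for. The default
in-house set (`primers_inhouse()`) compares 20 nt of read 1 and assigns a
read when its best primer has fewer than 5 mismatches; the public-data
variant (`primers_public()`) compares a single IgM primer at fewer than 6
mismatches against read 2, after trimming the synthesis overhang preceding
the located primer (`locate_primer()`, `trim_overhang()`). A read that ties
between two primers under the threshold is left unassigned: the bound makes
such reads genuinely ambiguous, and discarding is the conservative choice.

```{r demux}
ps <- primers_inhouse()
ps
classify_isotype("AAGACATTTGGGAAGGACTGACGTACGT", ps)
```

## Similarity and diversity statistics

**Gene usage.** `gene_usage()` computes abundance-weighted frequencies per
segment class, with clones lacking a D segment tallied under an explicit
`"D-empty"` class so D frequencies still sum to one (an unweighted mode is
available behind `weighted = FALSE`). `gene_usage_correlation()` computes
the Pearson correlation over the *pooled* V + D + J frequency vector,
expressed over the union of gene names.

**Morisita–Horn similarity (MHSI).** For clonotype frequencies $p_i$ and
$q_i$ over the union of clonotypes of two repertoires,

$$\mathrm{MHSI} = \frac{2\sum_i p_i q_i}{\sum_i p_i^2 + \sum_i q_i^2}
\in [0, 1],$$

an abundance-weighted overlap that is 1 only for identical frequency
profiles and 0 for disjoint ones. Abundances default to summed clone
counts per clonotype (`clonotype_profile(weight = "count")`); counting each
clone row once is available as `weight = "unique"`.

**Evenness (NSDE).** The normalized Shannon diversity entropy of a profile
with $N$ clonotypes,

$$\mathrm{NSDE} = -\sum_{i=1}^{N} \frac{p_i \ln p_i}{\ln N},$$

is 1 for a perfectly even repertoire. A single-clonotype profile has
$\ln N = 0$; we define its evenness as 0 (with a warning), since one
clonotype has no evenness to speak of.

**Richness, rarefaction, coverage.** `chao1()` implements the classical
estimator $S_{obs} + f_1^2/(2 f_2)$ from singleton/doubleton counts,
switching to the bias-corrected $S_{obs} + f_1(f_1-1)/2$ when $f_2 = 0$.
`rarefaction_curve()` subsamples the clone pool without replacement at
every 1% of the clone count (100 bootstrap replications by default) and
extrapolates to five times the observed depth with the Chao1-based
accumulation form at Hill order $q = 0$. Sequencing coverage is
$100 \cdot S_{obs}/\hat S_{chao}$.

```{r mhsi}
mhsi(c(x = 2, y = 1), c(x = 1, y = 1))   # 18/19
nsde(c(3, 1))
chao1(c(A = 1, B = 1, C = 2))
```

## Clonal lineages

Somatic hypermutation produces clusters of clonotypes that share V gene, J
gene and CDR3 length and differ at a few nucleotides. On real data, the 2D
histogram of nearest-neighbor identity against CDR3 length
(`nn_distribution()`) shows two hot spots — mutants at $\ge 95\%$ identity
and unrelated background around 55–90% — which motivates the lineage
criteria implemented by `build_lineages()`: nodes are unique CDR3 nt
clonotypes, edges join same-`(V, J, length)` pairs at $\ge 95\%$ identity,
and lineages are connected components with at least 2 nodes. Three choices
deserve emphasis:

* the threshold is **inclusive** — a pair at exactly 95.0% is linked — and
  identities are compared with a $10^{-9}$ tolerance so that ratios such as
  19/20 hit the boundary exactly rather than falling to floating-point
  noise;
* membership is **single-linkage**: two members of one lineage need not be
  within 5% of each other, only connected through intermediates, matching
  the network framing (cliques would fragment ladders of successive
  mutations);
* the **degree** of a node is its number of direct within-threshold
  partners, computed from the edge set, not from component size;
  `degree_stats()` reports the distribution over lineage members (degrees
  pooled at $\ge 8$) and the maximal degree over all nodes.

`mutated_ratio()` — the percentage of clonotypes inside any lineage — is
the repertoire's snapshot proportion of somatically mutated clonotypes.

## Sharing between individuals

`sharing_ratios()` counts, for each distinct clonotype in a group of
individuals (same strain, tissue, isotype), how many individuals carry it,
and reports the percentage of the union at each occupancy; sharing is by
presence/absence, unweighted by abundance. `build_cross_lineages()` pools
all samples of one strain and isotype, applies the same lineage criteria to
the pooled clonotypes, retains lineages of at least 3 nodes (5 for the
stricter variant; 2 when studying the size distribution), and traces each
node back to every sample containing its exact `(V, J, CDR3 nt)` triple. A
lineage is *present* in a sample when at least one node traces back to it;
its *abundance* there is the summed node frequency under that sample's own
normalization. `lineage_occupancy()` tabulates lineages over
(blood-sample count, spleen-sample count) cells, and
`lineage_abundance_mhsi()` applies the Morisita–Horn index to
lineage-level abundance vectors. Occupancy matrices are always emitted in
full; any display-driven omission of small cells is a plotting concern, not
an analysis one.

Group comparisons (`compare_groups()`) use two-sided Wilcoxon tests:
rank-sum for unpaired data, signed-rank for paired data, exact for group
sizes up to 25 without ties (the regime of small animal cohorts) and
normal-approximate with continuity correction beyond. Paired samples whose
differences are all zero return p = 1 with a warning rather than an error.

## The synthetic-data generator

`simulate_repertoires()` emulates the statistical structure the analysis
assumes, not mouse biology. For each individual × tissue × isotype subset
it plants:

* **skewed clonal abundance** — lognormal by default
  ($\sigma = 1.5$), with a discrete power law as the alternative;
* **gene usage** drawn once per study from a Dirichlet (concentration 0.5)
  and shared by all individuals, as inbred animals share germline usage;
  D-less clones arise with their own probability mass;
* **lineages** — a configurable fraction (default 20%) of clonotypes sit in
  planted lineages whose sizes follow a geometric law with ~70% two-node
  lineages; each member is within $\lfloor 0.05 \cdot L_{nt} \rfloor$
  substitutions of its ancestor, and rejection sampling keeps *every other
  same-group pair* strictly below 95% identity, reproducing the two
  nearest-neighbor hot spots with a clean boundary;
* **public clonotypes** — a per-individual fraction (default 10%) drawn
  from a shared pool twice that size, so pool members appear in each mouse
  with probability one half and occupancy across $m$ mice is binomial;
* **tissue overlap** — whole units (lineages or singletons) are allocated
  to blood-only/both/spleen-only bins so that a configurable fraction
  (default 30%) of a tissue subset is shared within the individual and
  lineages never straddle a tissue partially.

Defaults are sized for desk-scale work: 1,000 clonotypes per individual per
tissue, and $10^4$ per subset in the deeper recovery analyses — one to two
orders of magnitude below real sequencing experiments, a deliberate choice
that keeps the full test suite and the reproduction script in the minutes
range. `emit_airr()` writes round-trippable AIRR TSVs; `emit_reads()`
writes primer-tagged FASTQ pairs whose ground truth records the exact
number of injected primer-window mismatches per read, so demultiplexing
boundary behavior is testable read by read.

What passing tests on this generator do **not** show: robustness to real
germline allele diversity, junctional P/N-nucleotide structure, selection,
class-switch dynamics, clone-caller errors, or sequencing error profiles
beyond uniform substitution. The generator validates the *measurement
machinery* — that planted lineages, sharing fractions and abundance skew
are recovered exactly or within sampling error — not biological realism.

```{r sim}
sim <- simulate_repertoires(sim_config(n_individuals = 3,
                                       n_clonotypes = 300, seed = 21))
sim
sub <- filter(sim$clones, sample_id == "BAL_m01_blood", isotype == "IgM")
net <- build_lineages(sub)
net
mutated_ratio(net)
```

## Numerical and design choices

* **Identity boundary**: percent identities are compared to thresholds with
  a $10^{-9}$ tolerance (exactness at printed boundaries beats strict
  float comparison).
* **Ties**: ambiguous primer assignments are unassigned; technical-replicate
  ties resolve lexicographically; lineage ids are assigned by decreasing
  size, then smallest node index.
* **Degenerate inputs**: empty profiles and empty subsets are errors where
  a statistic is undefined (MHSI, gene usage, Chao1) and empty results
  where a tally is natural (NN distribution, degree distribution, occupancy
  of an empty lineage list). NSDE of one clonotype is 0 by convention.
* **Rarefaction internals**: each bootstrap replicate draws one random
  permutation of the clone pool and reads off distinct-clonotype counts at
  every step, so each replicate's curve — and therefore the mean curve —
  is monotone by construction, and a fixed seed reproduces the result
  bit for bit. The analytic mode evaluates the exact hypergeometric
  expectation via `lchoose` (no SEM). Extrapolated points carry the
  classical Chao1 standard error scaled by the fraction of unseen richness
  accrued, which vanishes at the observed endpoint and reaches the full SE
  at the asymptote; interpolated and extrapolated uncertainties are labeled
  by `phase` and are not comparable quantities.
* **Nearest-neighbor bins**: 1%-wide, left-closed; the top bin is closed at
  100 so exact duplicates of distinct clonotypes cannot escape the
  histogram.
* **Seeds**: every stochastic stage takes a seed; the pipeline derives
  per-subset seeds from the run seed, and simulation restores the caller's
  RNG state on exit.

## Orchestration

`run_pipeline(run_config(...))` chains the stages over a directory of AIRR
TSVs or an in-memory table — filtering, replicate selection, per-subset
diversity, rarefaction, lineage networks, sharing, cross-individual
lineages — and writes one TSV per result family plus a `manifest.json`
echoing versions, seed and parameters. Two runs with the same inputs and
seed produce byte-identical bundles, and the manifest deliberately omits
timestamps for that reason. Stage toggles omit exactly their outputs.

## Known limitations

* Lineage inference is identity-based single linkage; tree-based
  reconstruction, germline reversion and model-based distances are out of
  scope.
* Richness estimation is Chao1-only (individual-based, single draw); Hill
  orders above 0 and sample-based multi-draw designs are not implemented.
* The analysis consumes clone tables; clone calling itself (alignment,
  assembly, PCR-error correction) is delegated to external tools.
* The public-data primer variant trims by located primer position but the
  package does not model multi-primer amplification biases.
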