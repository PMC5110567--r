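---
title: "Evaluating DNA barcode markers with barcodegap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcode markers with barcodegap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A DNA barcode is useful when sequences from the same species are more
similar to each other than to sequences from any other species — when there
is a *barcoding gap* between the distribution of intraspecific and
interspecific pairwise distances. `barcodegap` evaluates candidate barcode
markers (singly and in multi-locus concatenation) with the two standard
criteria used throughout the plant-barcoding literature:

* **PWG-distance criterion.** A species is discriminated when the minimum
  interspecific distance involving it is *strictly larger* than its maximum
  intraspecific distance. The classic formulation uses the uncorrected
  p-distance, so that is the default; the K2P-corrected variant is a flag.
* **Tree-building criterion.** A species is discriminated when all of its
  individuals form a monophyletic group in a neighbor-joining (NJ) tree
  built from Kimura 2-parameter (K2P) distances, with bootstrap support
  strictly above a threshold (default 50%).

The *discrimination rate* of a marker is the percentage of testable species
passing a criterion. The same machinery applies unchanged at any higher
grouping level (e.g. taxonomic sections), using the section column of the
metadata.

## Models and estimators

**Pairwise comparison.** For two aligned sequences, columns where either
sequence carries a gap, `N` or an IUPAC ambiguity code are excluded
(*pairwise deletion*; `deletion = "complete"` removes every such column for
all pairs first, which matches the complete-deletion convention of some GUI
packages). From the remaining columns we count transitions (A↔G, C↔T) and
transversions, giving proportions $P$ and $Q$.

**Distances.** The uncorrected distance is $p = P + Q$. The K2P estimator is

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q),$$

which corrects for multiple hits with distinct transition/transversion
rates. When either logarithm's argument is non-positive the pair is
*saturated*: the entry is undefined (`NA`), never clamped to a large
constant, and undefined pairs are excluded from means, minima/maxima and
histograms with a reported tally. $d \ge p$ always, with equality exactly at
zero — a property the tests verify both algebraically and numerically.

**Neighbor joining.** `nj_construct()` implements the Saitou–Nei
agglomeration: join the pair minimizing
$Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$, with the standard
split formula for branch lengths. Ties in $Q$ (exact floating-point ties)
are broken by the lexicographically smallest index pair in the current node
ordering, and joined nodes are appended at the end, so runs are reproducible
bit for bit. Negative branch lengths are kept as computed — this is what
makes the algorithm exact on additive matrices, which the test suite
verifies against an exhaustive topology-enumeration oracle for up to six
taxa.

**Bootstrap.** `bootstrap_supports()` resamples alignment *columns* with
replacement (the standard phylogenetic bootstrap — never distance entries),
rebuilds the distance matrix and NJ tree per replicate, and scores each
internal edge of the reference tree by the fraction of replicates containing
the same bipartition. Replicates with undefined distances are skipped and
tallied; supports are fractions of the effective replicate count.

**Monophyly.** Tested on the *unrooted* tree via bipartitions: a group is
monophyletic iff some edge has one side exactly equal to the group. This is
rooting-free and symmetric (a set and its complement are equivalent), which
matters because published barcoding trees are typically drawn rooted without
a stated outgroup. Singletons are trivially monophyletic; they are handled
by the shared `singleton_policy` (default `"exclude"`, since a species with
one individual has no intraspecific distance and the PWG criterion is
untestable on it — keeping denominators identical across the two criteria).
`"zero_intra"` is available for comparability with studies that score
singletons as discriminated.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `pwg_model` | `"p"` | distance used by the PWG criterion |
| `tree_model` | `"k2p"` | distance used for NJ and summary means |
| `deletion` | `"pairwise"` | site-exclusion mode |
| `bootstrap` | 1000 | bootstrap replicates |
| `support_threshold` | 0.5 | clade support must strictly exceed this |
| `singleton_policy` | `"exclude"` | see above |
| `bin_width` | 0.005 | gap-histogram bin width (substitutions/site) |

Pairwise deletion is the default because non-coding spacers accumulate many
indels; complete deletion would erase most columns of a gappy marker.
Distances are compared with exact floating-point comparison (a tie is a
tie); reports round distances to 4 decimals and percentages to 2.

## The synthetic-data generator

`simulate_dataset()` generates multi-marker datasets with known ground
truth so the whole pipeline can be exercised and calibrated without any
sequence downloads:

* a pure-birth (Yule) species tree rescaled to root-to-tip height
  `interspecific_depth / 2`;
* individuals attached to each species tip as a star of depth
  `intraspecific_depth / 2` (the simplest structure producing higher
  between- than within-species variability; a coalescent within species is
  future work);
* sites evolved independently under the Kimura two-parameter process
  (equal base frequencies — consistent with the distance model being
  evaluated) with transition/transversion ratio `kappa` (default 2);
* markers simulated independently with relative rates; the default
  four-marker ladder (rbcL 0.09, matK 0.18, trnS–trnG 0.57, ITS 1, at their
  canonical aligned lengths 497/636/366/346) is proportional to the mean
  interspecific divergences reported for these markers in maple barcoding,
  so slow coding chloroplast loci and the fast nuclear spacer behave
  qualitatively like their real counterparts;
* optional indel events inserted afterwards as spans shared across a random
  species subset, so the deduplicated indel-event count has known truth.

**Minimum split floor.** A raw Yule tree can place a speciation arbitrarily
close to the present, creating a species pair less divergent than the
configured within-species variation; no generator parameterization could
then guarantee a barcoding gap. Real barcoding studies face the same issue
and handle it by sampling design — recently diverged, hybridizing or
introgressing complexes are excluded. The generator mirrors that choice:
split heights are affinely compressed so the most recent split sits at
`min_split_frac` (default 0.2) of the tree height, i.e. every species pair
has expected divergence at least `0.2 * interspecific_depth`. Set
`min_split_frac = 0` for the unconstrained Yule process.

Defaults (`interspecific_depth = 0.05`, `intraspecific_depth = 0.006`,
21 species, 2–5 individuals each) emulate the ITS-scale divergences of a
maple-family barcoding study. What passing tests on such data show is that
the *estimators and criteria* behave correctly when their assumptions hold;
they do not show robustness to alignment error, ITS paralogy/concerted
evolution, introgression, or non-equal base composition, none of which the
generator emulates.

## Worked example

```{r, eval = FALSE}
library(barcodegap)

sim <- simulate_dataset(simulation_config(seed = 24, indel_rate = 5))
ec <- evaluation_config(
  sim$alignments, sim$metadata,
  combinations = list(c("trnS-trnG", "ITS"),
                      c("rbcL", "matK", "trnS-trnG", "ITS")),
  bootstrap = 100, seed = 11)
report <- run_evaluation(ec)
report$summary
render_reports(report, "barcode_eval")
```

The summary has one row per unit and level with the usual marker-table
columns (aligned length, SNPs, %SNP, indel events, mean inter/intra
distance, both rates); `render_reports()` additionally writes per-group
decision TSVs, gap-histogram series, newick trees with supports, and a run
log with seed and dropped-pair counts.

## Numerical and design notes

* Branch lengths survive newick round trips at full double precision inside
  `nj_construct()` (17 significant digits); file output uses the standard
  10-digit newick writer.
* Concatenation uses strict sample-id intersection, no missing-data
  padding; per-unit rates therefore have their own denominators, and the
  reports echo each unit's species count. How taxa should be matched across
  markers when individuals differ is a dataset-construction choice, not
  something the criteria define; strict intersection is this package's
  choice.
* Species/section labels come only from the metadata table, never parsed
  from FASTA headers (GenBank header conventions are too inconsistent for
  deterministic joins).
* The indel-event count deduplicates identical (start, end) gap spans
  across rows, the convention of population-genetics software that reports
  "indel events"; a gap-containing-column count is available via
  `method = "columns"`. Ambiguity codes never count toward polymorphism.
* Whether published marker tables used pairwise or complete deletion is
  rarely stated; both modes are provided and the default is documented
  rather than inferred as anyone's intent.
* Test and acceptance problem sizes: property tests run at 4–10 taxa;
  end-to-end runs use 21 species × 2–5 individuals with 25–100 bootstrap
  replicates — enough for supports at 0.01–0.04 granularity while keeping
  the suite fast. The bootstrap default for real analyses remains 1000.

## Known limitations

* Only the K2P/p distance family (no JC, TN93, GTR; no gamma rates).
* NJ only (no ML/Bayesian trees); supports are mapped onto the reference
  topology, no consensus tree is built.
* The generator's intraspecific structure is a star, not a coalescent, and
  it does not simulate hybridization, introgression, or concerted
  evolution.
* Undefined (saturated) distances abort tree building for that unit rather
  than being imputed; the report marks the unit's tree criterion absent.
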