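# barcodegap

Evaluation of DNA barcode markers by barcoding-gap and tree-based species
discrimination.

## What problem this solves

Plant barcoding studies ask: given a set of candidate markers (typically
the chloroplast loci *rbc*L, *mat*K, a non-coding spacer such as
*trn*S–*trn*G, and the nuclear *ITS* region), which marker — or which
multi-locus combination — best distinguishes the species of a group?
`barcodegap` is for researchers running that evaluation: it takes
per-marker aligned FASTA files plus a sample metadata table
(`sample_id`, `species`, `section`, `population`) and computes, for every
single marker and every requested concatenation:

* alignment statistics — aligned length, variable (SNP) sites, %SNP,
  deduplicated indel events;
* pairwise distances — uncorrected *p* and Kimura 2-parameter (K2P),
  with pairwise deletion of gap/ambiguous sites, and the
  intra- vs interspecific **barcoding-gap** histogram;
* the **PWG-distance criterion**: species *s* is discriminated iff
  min interspecific distance involving *s* > max intraspecific distance
  of *s* (strict inequality);
* the **tree-building criterion**: neighbor-joining on K2P distances,
  nonparametric bootstrap over alignment columns, and species counted as
  discriminated iff monophyletic with support strictly above a threshold
  (default 50%);
* discrimination **rates** (percent of testable species) for both
  criteria, at species level and — when section labels are present — at
  section level.

For the K2P estimator with transition proportion *P* and transversion
proportion *Q*:

    d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)

and for neighbor joining the pair minimizing
`Q(i,j) = (n-2) d(i,j) - Σ_k d(i,k) - Σ_k d(j,k)` is joined at each step,
with deterministic lexicographic tie-breaking.

A synthetic-data generator (`simulate_dataset()`) produces
species-structured multi-marker alignments under the Kimura two-parameter
substitution process with known ground truth, so the whole pipeline is
testable without downloading any sequences.

## Worked example

Simulate a study-shaped dataset (21 species, 2–5 individuals each, four
markers on the slow-rbcL → fast-ITS rate ladder) and evaluate two
combinations alongside the single markers:

```r
library(barcodegap)

sim <- simulate_dataset(simulation_config(seed = 24))
ec <- evaluation_config(sim$alignments, sim$metadata,
  combinations = list(c("trnS-trnG", "ITS"),
                      c("rbcL", "matK", "trnS-trnG", "ITS")),
  bootstrap = 100, seed = 11)
report <- run_evaluation(ec)
subset(report$summary, level == "species")
```

```
                    unit   level n_samples n_groups aligned_length n_snps
                    rbcL species        74       21            497     22
                    matK species        74       21            636     60
               trnS-trnG species        74       21            366     82
                     ITS species        74       21            346    133
           trnS-trnG+ITS species        74       21            712    215
 rbcL+matK+trnS-trnG+ITS species        74       21           1845    297
 pct_snp n_indels mean_inter mean_intra rate_pwg rate_nj
    4.43        0     0.0038     0.0005    28.57   28.57
    9.43        0     0.0109     0.0009    28.57   57.14
   22.40        0     0.0242     0.0028    57.14   85.71
   38.44        0     0.0470     0.0048    80.95   85.71
   30.20        0     0.0352     0.0038    85.71  100.00
   16.10        0     0.0182     0.0019   100.00  100.00
```

Each row is one evaluation unit: its aligned length, SNP count and
percentage, indel events, dataset mean inter-/intraspecific K2P distance,
and the two discrimination rates. The slow coding chloroplast marker
(rbcL-like) resolves few species, the fast nuclear marker (ITS-like)
resolves most, and concatenations resolve all 21 — the qualitative pattern
such evaluations find on real data. `render_reports(report, "outdir")`
writes the summary TSV, per-group decision TSVs for both criteria,
barcoding-gap histogram series, newick trees with bootstrap supports, and
a run log.

To analyze your own data, replace the simulated inputs with
`read_alignment()` on each per-marker aligned FASTA and `read_metadata()`
on your TSV — the package consumes already-aligned matrices and never
aligns sequences itself.

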