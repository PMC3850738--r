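# dockrank

Evaluation of scoring functions for protein–protein docking poses.

Protein–protein docking generates hundreds of candidate poses (decoys)
per complex; a scoring function must then rank the near-native poses
ahead of the incorrect ones. `dockrank` provides the benchmark machinery
for asking how well a panel of scoring functions does this, and — more
interestingly — whether two functions succeed on *different* complexes
and would therefore combine well:

* **CAPRI quality measures** per decoy against the native structure:
  fraction of native contacts (f<sub>nat</sub>), interface RMSD (IRMSD)
  and ligand RMSD (LRMSD), and the derived quality classes
  (incorrect < acceptable < medium < high), assigned by the standard
  boolean criteria, e.g. *high* iff f<sub>nat</sub> ≥ 0.5 and
  (LRMSD ≤ 1 Å or IRMSD ≤ 1 Å).
* **Contact-potential scoring** with pluggable 20×20(×bins) residue-level
  matrices under Cβ, centroid or minimum-heavy-atom contact definitions,
  in intermolecular-only or separable
  E<sub>complex</sub> − (E<sub>receptor</sub> + E<sub>ligand</sub>) mode.
* **Re-ranking and greedy leader clustering** of each case's decoys at a
  3 Å ligand-RMSD radius, keeping only the best-scoring member of each
  cluster as a ranked representative.
* **Benchmark statistics**: top-1/10/100 success counts and rates per
  quality threshold, conditional probabilities of finding a solution
  given that one exists, and difficulty-stratified variants
  (rigid-body vs. flexible cases).
* **Set-theoretic synergy**: for every pair of metrics, the union,
  symmetric difference and relative complement of the sets of complexes
  they "find" (near-native in the top 10), with complete-linkage
  clustering of the symmetric-difference matrix and cophenetic
  distances — large symmetric differences mark pairs of functions that
  capture different aspects of binding.
* **A synthetic benchmark generator** (toy helical complexes,
  rigid-body-perturbed decoys labelled by the real classifier, and
  scoring metrics with controllable informativeness and inter-metric
  correlation) so every statistic can be validated against known ground
  truth.

## Worked example

```r
library(dockrank)

# a synthetic case: native complex + 60 rigid-body decoys
native <- make_native(receptor_size = 12, ligand_size = 10, seed = 3)
ds     <- make_decoys(native, default_schedule(60), seed = 4, case_id = "demo")

# CAPRI quality of every decoy against the native
qt <- quality_table(ds)
table(qt$class)
#> incorrect acceptable     medium       high
#>        46          2          5          7

# score with the packaged exemplar contact potential, rank and cluster
cm <- example_contact_matrix()
st <- score_decoy_set(ds, list(contact_potential_metric(cm)))
rl <- rank_case(ds, st, cm$name, qt)
head(rl[, c("rank", "decoy_id", "score", "lrmsd", "class")], 3)
#>   rank decoy_id      score    lrmsd  class
#> 1    1    d0015 -29.016667 8.173777 medium
#> 2    2    d0009 -10.456667 3.142481 medium
#> 3    3    d0013  -9.283333 6.193897 medium
```

The ranked list contains one row per 3 Å cluster: rank 1 is the
best-scoring representative, and here the exemplar potential puts a
medium-quality pose (LRMSD 8.2 Å after clustering) first — the kind of
per-case outcome the benchmark statistics aggregate over many cases:

```r
res <- make_benchmark(20, list(synthetic_metric("strong", 0.9),
                               synthetic_metric("weak",   0.3)),
                      n_decoys = 40, seed = 1)
success_table(res)                 # top-1/10/100 counts and rates
conditional_probability(res, "strong", N = 10, q = "acceptable")
synergy_matrices(res)$symdiff      # which metrics find different cases?
```

`run_full(config, out_dir)` wires the whole pipeline (synthetic or
PDB-file inputs via a YAML config) into one reproducible output tree
with TSV tables, a Newick dendrogram and a JSON manifest.

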