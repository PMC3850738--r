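---
title: "Evaluating docking scoring functions with dockrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating docking scoring functions with dockrank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockrank)
```

## The problem

A docking search produces, per protein–protein complex, a few hundred
candidate poses ("decoys"). A scoring function assigns each pose a
number intended to rank near-native poses first. `dockrank` evaluates
panels of such functions on a benchmark of complexes: it labels each
decoy's quality against the experimental (native) structure, re-ranks
and clusters each case per scoring function, and aggregates success
statistics and pairwise complementarity measures. Everything downstream
of the decoys is deterministic given the inputs, so the whole analysis
is reproducible from a seed.

## Pose quality: fnat, IRMSD, LRMSD and the four classes

Three standard measures compare a decoy to the native complex:

* **fnat** — the fraction of the native's intermolecular residue–residue
  contacts present in the decoy. Two residues are in contact when any
  pair of their heavy atoms is within the contact cutoff (default 5 Å,
  the community convention; configurable, since the criteria are often
  cited without restating it).
* **LRMSD** — backbone RMSD over ligand residues after superposing the
  decoy's receptor backbone onto the native receptor (no second fit on
  the ligand). The superposition is the standard least-squares (Kabsch)
  fit via SVD with a determinant correction so reflections are never
  returned.
* **IRMSD** — backbone RMSD over the *native* interface residues (any
  residue of either molecule with a heavy atom within 10 Å of the other
  molecule, again the community convention) after superposing the decoy
  interface onto the native interface.

Backbone means N, CA, C, O; hydrogens are ignored everywhere, and a
backbone atom missing on either side of a native/decoy pair is dropped
from both so the selections stay index-aligned. From (fnat, LRMSD,
IRMSD) each decoy gets exactly one of four ordered classes —
*incorrect < acceptable < medium < high* — by evaluating the standard
boolean predicates from the highest class downwards:

* high: fnat ≥ 0.5 and (LRMSD ≤ 1 or IRMSD ≤ 1)
* medium: (fnat ≥ 0.5 and LRMSD > 1 and IRMSD > 1) or
  (0.3 ≤ fnat < 0.5 and (LRMSD ≤ 5 or IRMSD ≤ 2))
* acceptable: (fnat ≥ 0.3 and LRMSD > 5 and IRMSD > 2) or
  (0.1 ≤ fnat < 0.3 and (LRMSD ≤ 10 or IRMSD ≤ 4))
* incorrect: otherwise (equivalently fnat < 0.1, or LRMSD > 10 and
  IRMSD > 4)

The predicates partition the space, but evaluating highest-first guards
boundary ties; the test suite sweeps 10^5 random triples against a
literal re-encoding of the predicates to confirm totality.

```{r classify}
classify_quality(fnat = c(1, 0.45, 0.2, 0.05),
                 lrmsd = c(0, 4, 8, 12),
                 irmsd = c(0, 1.5, 3, 5))
```

## Contact-potential scoring

The scoring engine is generic over residue-level potentials: a 20×20
(per distance bin) symmetric energy matrix plus a contact definition
naming the residue representative — Cβ (CA for glycine), heavy-atom
centroid, or minimum heavy-atom distance — and the scoring bins.
Defaults follow each family's common conventions (Cβ ≤ 8 Å, minimum
heavy-atom ≤ 5 Å), configurable per matrix file since published
families differ. Two evaluation modes exist:

* **intermolecular** — sum over receptor–ligand residue pairs only;
* **separable** — evaluate a structure-level scorer on the complex and
  on the isolated receptor and ligand and take
  E_complex − (E_receptor + E_ligand).

For pairwise-additive potentials the two modes agree identically (the
intramolecular terms cancel), which the tests verify to 10⁻⁸; the
separable mode exists because many published scorers are only defined
at structure level. Unknown residue types map through a configurable
parent table (MSE→MET, ...) or are skipped with a warning.

The packaged exemplar matrix (`example_contact_matrix()`) is a
*synthetic* quasi-chemical-style matrix — hydrophobic pairs attract,
like charges repel — generated deterministically and shipped as a
plain-text file. It exercises the engine and gives sensible toy
rankings, but it is not a published potential; real analyses should
load their own matrices with `load_contact_matrix()`.

## Ranking and clustering

Per case and metric, decoys are sorted best-first — ascending for
energy-like scores, descending for count-like scores where positive
values mark promising solutions — with missing scores dropped and ties
kept in stable input order. The sorted list is swept greedily: a decoy
joins the first existing cluster whose *leader* is within the 3 Å
threshold, else founds a new cluster. Only leaders survive into the
ranked list. Membership is tested against the leader (not complete
linkage within clusters): that matches the sweep-in-score-order
semantics, and ties to multiple leaders resolve to the best-ranked one
for determinism.

The pose distance is the ligand backbone RMSD after receptor-to-receptor
superposition of the two decoys — the same frame-then-ligand
construction as LRMSD with a decoy as reference. Full-complex RMSD is
available via `make_pose_distance(ds, "complex_rmsd")` for users who
prefer that convention; the literature describes both.

## Benchmark statistics

`success_counts(results, metric, N, q)` counts cases whose top-N
representatives contain a pose of class ≥ q. Two denominators are
reported side by side: all benchmark cases (headline rates) and only
cases where a pose of class ≥ q exists among the generated decoys
(conditional rates) — both readings are in common use, so
`success_table()` labels them explicitly rather than choosing.
`conditional_probability()` defaults to N = 10 ("found" = in the top
10). Percentages are reported to the nearest integer
(`format_percent(76, 115)` is `66`), with raw fractions always kept.
Difficulty stratification pools the medium and difficult categories
into one *flexible* stratum, since those categories are smaller and
near-native poses are rarer there.

## Set-theoretic synergy

For each metric, the *found set* is the set of case ids with a
near-native (class ≥ acceptable by default) in its top 10. For a pair
of metrics, `pair_cardinalities()` returns |A∪B|, |AΔB|, |A∖B|, |B∖A|
and |A∩B|; a large symmetric difference means the two functions succeed
on different complexes and are promising to combine. The
symmetric-difference matrix is ordered by complete-linkage clustering
(delegated to `stats::hclust`, with an independent naive agglomeration
as test oracle), and cophenetic distances are read off the dendrogram.
The union matrix is similarity-like, so its clustering uses
`max(union) − union` as the dissimilarity — one of two defensible
readings; the symmetric-difference ordering can be reused instead via
`union_ordering = "symdiff"`. The asymmetric relative-complement matrix
is ordered by individual top-10 success rate, descending.

```{r synergy}
res <- make_benchmark(12, list(synthetic_metric("a", 0.9),
                               synthetic_metric("b", 0.9),
                               synthetic_metric("c", 0.2)),
                      n_decoys = 30, seed = 7)
synergy_matrices(res)$symdiff
```

## The synthetic generator: what it emulates, and what it does not

Real decoy benchmarks are large (on the order of 118 complexes × ~500
decoys); the generator emulates their *statistical shape* at desk
scale:

* **Natives** are two idealised helical chains (full backbone + Cβ)
  placed antiparallel and in contact, with at least 5 native residue
  contacts enforced at construction. Sequences are seeded draws over
  the 20 standard residues so matrix lookups are non-trivial
  (poly-alanine is available). Helices are the smallest structures with
  realistic backbone geometry and unambiguous contacts.
* **Decoys** are rigid-body ligand perturbations drawn from a banded
  schedule of translation/rotation magnitudes (defaults span 0.2–45 Å,
  weighted towards incorrect poses as in real docking output). Labels
  are always produced by the real classifier on the generated
  coordinates — never assigned — keeping generator and pipeline honest
  to each other. The default schedule is generous with near-natives
  (roughly a quarter of decoys), under which top-10 success saturates
  for informative metrics; `sparse_schedule()` is the hard preset (two
  near-natives per case) that keeps success rates away from 1, which is
  the regime where two equally informative metrics visibly find
  *different* complexes.
* **Scores** are monotone transforms of a latent (the quality ordinal,
  with LRMSD ordering poses within a class, so medium-vs-acceptable
  conditional behaviour is testable) mixed with seeded Gaussian noise
  on the normal-scores scale. The mixing weight is `2 sin(π ρ / 6)`,
  the bivariate-normal inversion of Spearman's ρ, so the realised rank
  correlation matches the requested informativeness within ±0.05 at
  n = 500. Metrics sharing a `noise_id` share their noise vector,
  planting correlated found sets (metric "families").

What the generator does *not* emulate: conformational flexibility,
side-chain packing, clashes, or any energy-landscape realism. Passing
tests therefore demonstrate that the evaluation machinery is correct
and well-calibrated on known ground truth — not that any potential
ranks real decoys well.

For calibration, `planted_success_experiment()` engineers a metric
whose per-case probability of placing a near-native in the top 10 is an
exact seeded coin flip (success plants the best near-native at rank 1;
failure pushes all near-natives behind every incorrect pose, beyond the
top 10 given the schedule's >10 scattered incorrect clusters). Over 500
cases the measured top-10 rate must recover p within 3 binomial
standard errors; the tests run exactly this at p = 0.6.

## Numerical and design choices

* Alternate locations: the first-encountered location per (chain,
  residue, atom name) is kept — the stated preparation convention for
  the decoy sets this package targets — rather than the lowest
  occupancy or the "A" label.
* Residue identity is (chain, resno, insertion code), preserved
  verbatim from the PDB numbering; no renumbering, so decoys and
  natives align by key.
* Contact bins are half-open intervals (lo, hi], so a pair exactly at
  the cutoff counts as in contact, and bin edges never double-count.
* Kabsch superposition requires ≥3 non-degenerate points and returns a
  proper rotation (det +1) always.
* Cluster tie-breaks: equal scores keep input order; a decoy within
  the threshold of several leaders joins the best-ranked one.
* Problem sizes in tests and the acceptance script (toy complexes of
  ~12+10 residues, 30–60 decoys/case, up to 500 cases) were chosen as
  the smallest scales at which the binomial tolerances of the
  calibration checks are meaningful.
* The exported functions (`run_full()` plus the per-stage functions)
  and the acceptance script are the package's interface; no shell
  entry point is shipped, as the intended use is scripted analysis.

## Limitations

* Only PDB-format input (no mmCIF); no hydrogen handling, side-chain
  repair or protonation — decoy sets are assumed preprocessed.
* The CAPRI cutoffs (5 Å contacts, 10 Å interface) are conventions the
  package defaults to, configurable where sources differ.
* No significance testing between metrics, and no combined/consensus
  scoring function is built — the synergy matrices indicate *which*
  pairs might combine well, not how to combine them.
* Clustering is leader-based by design; density- or hierarchy-based
  pose clustering is out of scope.
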