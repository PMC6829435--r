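---
title: "Methods: post-docking and post-MD analysis of protein-GAG binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-docking and post-MD analysis of protein-GAG binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagposelab)
```

## Scope and model

Glycosaminoglycans (GAGs) — heparin (HP), chondroitin-6-sulfate (CS6),
dermatan sulfate (DS) — are linear, periodic, highly anionic
polysaccharides. Characterising how they bind a protein receptor from
docking and molecular-dynamics (MD) output raises analysis problems that
generic tools handle poorly: docked poses of a periodic ligand can differ
by a register shift along their own axis; a pose has an intrinsic
direction (non-reducing to reducing end) whose orientation — the *polarity*
of the pose — is biologically meaningful; chains longer than the docking
engine can sample must be assembled from overlapping fragment poses; and
Ca²⁺ association emerges from trajectories as residence at coordination
sites rather than as a static annotation.

`gagposelab` implements that post-processing layer. It deliberately does
*not* dock, run MD, or compute MM-GBSA energies: docking poses, per-residue
energy decompositions and trajectory frames are its inputs, either from
external engines (via multi-MODEL PDB and CSV) or from the package's own
synthetic generators.

Conventions used throughout: coordinates in Å, energies in kcal/mol,
occupancies in ns; ring 0 of a chain is the **non-reducing end**; residue
numbers are 1-based as in PDB files. Poses are always compared in the
receptor coordinate frame — no superposition is ever applied, because
superposition would erase exactly the binding-site information the
analyses quantify.

## Pose clustering

From a raw docking run (typically 1000 poses per system) the 50 top-scored
poses are retained (`select_top_scored()`, deterministic tie-break by pose
id) and clustered with DBSCAN.

The distance between two poses of the same ligand is the root-mean-square
over the union of both directed nearest-neighbour distance sets, where
each atom may match any atom of the partner pose sharing its *type* — the
pair (ring chemical type, atom name):

$$ d(A,B) = \sqrt{\tfrac{1}{|A|+|B|}\Big(\sum_{a \in A}\min_{b \sim a}\lVert a-b\rVert^2
  + \sum_{b \in B}\min_{a \sim b}\lVert b-a\rVert^2\Big)} $$

Matching by type rather than by chain index is what makes the metric
appropriate for periodic ligands: a heparin-like chain shifted along its
own axis by one disaccharide period re-registers against its neighbour's
chemically equivalent rings and scores far below the index-matched RMSD
(the package's test suite asserts this against a brute-force oracle).
The union-of-both-directions form was chosen because it is symmetric —
a requirement for DBSCAN — and reduces to ordinary RMSD for unambiguous
equal-cardinality matchings. A directed variant is a one-line change but
is not offered as a user switch, to keep reported distances comparable.

DBSCAN follows the classic convention that the neighbourhood count
includes the query point, so a core point needs `m − 1` *other* poses
within `eps`. All iteration orders are fixed (ascending pose id; border
poses join the first claiming cluster), making labels reproducible.
Because suitable `(m, eps)` values are system-specific, `tune_clustering()`
emulates the manual per-system choice: it scans `m` ascending, then `eps`
ascending, and returns the first pair yielding 2–4 clusters while
clustering at least half of the poses; when nothing qualifies it returns
the nearest miss with a warning flag rather than failing.

## Pose polarity

A pose's axis is the unit vector from the centroid of its non-reducing
ring to the centroid of its reducing ring. Within a cluster, the
reference axis is the axis of the cluster's top-scored pose (deterministic
and cluster-local; a principal-axis alternative is available), and each
member is *parallel* when the dot product with the reference is ≥ 0 — the
zero boundary maps to parallel by a fixed, arbitrary convention. Counts
are reported as majority/minority (`"17/2"`-style), which makes the
presentation invariant to reversing every chain's ring order.

## Energy hotspots

Per-residue MM-GBSA-style decomposition tables are ranked by mean energy;
the top-10 most favorable residues form a cluster's hotspot set (ties
broken by ascending residue number — input tables carry no tie rule).
Hotspot sets are compared by their intersection cardinality
(`overlap_matrix()`), the "common residues in the top 10" summary; the
diagonal is the set size. Aggregation across the clusters of one GAG is
**pose-weighted** (each cluster's table weighted by the number of poses it
averages); since a cluster-weighted reading of "averaged per GAG" is also
defensible, that mode is provided explicitly and a regression test pins
the default.

Poses are flagged unstable when their mean binding energy is *strictly*
above −15 kcal/mol, so a pose exactly at the threshold counts as stable.
Binding energies between structural models are compared with Welch's
unequal-variance two-sided t-test (`stats::t.test` underneath, with the
degenerate zero-variance/equal-means case defined as p = 1); sample sizes
and variances of docking clusters differ enough that the pooled-variance
test would be the wrong default.

## Fragment-based chain assembly

Long chains (target dp 11) are built from docked trimer (dp 3) poses.
Trimers cut from a chain at consecutive start positions overlap by two
rings (one disaccharide) and alternate between two *phases* — the two ring
sequences a trimer window can have on an alternating HP chain. Fragment
`f2` may extend `f1` when the phases differ and the RMSD between `f1`'s
last two rings and `f2`'s first two rings (atoms matched by name, receptor
frame) is at most 1.0 Å. The growth is breadth-first from every phase-A
pose, pruned to 10⁵ partial chains by best combined score (the sum of
fragment scores — the simplest monotone choice), with overlap-ring
coordinates taken from the earlier fragment so results are independent of
discovery order. A dp-11 chain therefore uses exactly 9 fragments. The
1.0 Å overlap cutoff and the scoring rule are this package's own
documented defaults: the underlying fragment-growth idea is published, but
its exact geometric parameters are not reproducible from the literature
the package follows.

Assembled chains then pass a steric filter (any GAG–protein atom pair
< 2.0 Å, or atoms of non-adjacent rings < 1.5 Å, removes the chain) and a
duplicate filter: greedy leader clustering by ascending score at 4.0 Å
all-atom index-matched RMSD, no superposition. Representatives inherit a
member count, so cluster occupancy is preserved.

## Ca²⁺ site detection

Coordination is operationalised geometrically: in a frame, a residue
coordinates the ion when it contributes an oxygen atom (side-chain
carboxylate/amide/hydroxyl or backbone carbonyl) within 3.2 Å — the upper
end of the Ca–O coordination range — and an ion is bound only when at
least two such oxygens coordinate it simultaneously. Both numbers are
configurable; the source literature for this workflow gives no numeric
rule, so these standard values are package defaults. Per-frame
coordination sets are grouped into sites by Jaccard similarity ≥ 0.5
against the site's founding set — a fuzzy match is required because
coordinating sets drift as side chains rearrange. Occupancy is frame
count × frame interval, reported exactly (a 5-ns rounding mode is offered
for table-style output); sites under 10 ns are dropped as transients.
Sites are merged across MD replicas by the same Jaccard rule, yielding a
support count (k of n replicas), and predicted site lists can be matched
one-to-one against a reference list (≥ 2 shared residues, or ion positions
within 3.5 Å when residue sets are unavailable).

## The synthetic-data generators

Every analysis stage is exercised against generated inputs with planted
ground truth; all generators are pure functions of an explicit seed.

* **Receptor**: a deterministic pseudo-globule of 150 residues on a
  Fibonacci sphere lattice (radius 12 Å, ≈3.5 Å spacing), with backbone
  carbonyl oxygens and side-chain oxygen pseudo-atoms on D/E/N/Q/S/T/Y
  residues — the atom inventory ion detection needs.
* **Pose ensembles**: each planted cluster is a rigid placement of the
  ligand at a distinct surface site (centers ≥ 15 Å apart), members
  perturbed by isotropic Gaussian rigid jitter with 1 Å RMS displacement,
  a per-cluster fraction flipped end-over-end to plant polarity, scores
  normal with cluster-specific means.
* **Energy tables**: hotspot residues at −5 kcal/mol, background at 0,
  Gaussian noise sd 0.5 — a 10-sd separation, so top-10 recovery is
  essentially certain by construction.
* **Fragment libraries**: the 9 true trimers of a dp-11 chain (optionally
  jittered) buried among randomly placed decoys per phase.
* **Ion trajectories**: block-wise residence (one or two contiguous bound
  blocks per ion, not per-frame coin flips), matching the contiguous
  binding/unbinding seen in real trajectories; bound ions sit in a 2.4 Å
  shell of their site's side-chain oxygens, unbound ions wander ≥ 8 Å
  away. The generator *moves* the site residues' side-chain oxygens into
  that shell (side chains reorienting to coordinate the ion, which is
  also observed in real simulations); a static lattice could not
  otherwise guarantee the planted geometry. One ion is emitted per
  planted site, since several sites in one run can have occupancies
  that sum beyond the trajectory length.

What passing tests show — and what they do not: planted-truth recovery
demonstrates that the analysis operations are correct implementations of
their definitions under realistic geometry, not that the generators'
statistical structure matches any particular real docking landscape.
Real pose distributions have anisotropic, score-correlated scatter;
real energy decompositions have heavy-tailed noise and correlated
residues; neither is claimed here.

## Numerical choices and degenerate inputs

* Chain axes shorter than 1e-12 Å (coincident end centroids) raise a
  degenerate-geometry error rather than returning noise.
* PDB coordinates are written at the format's fixed 3-decimal width;
  values that cannot be represented raise an error instead of being
  silently truncated, and the write–read–write cycle is byte-identical.
* All tie-breaks (score ties, equal energies at rank 10, beam pruning)
  fall back to ascending ids, so every pipeline output is reproducible.
* Problem sizes used by the bundled analyses and tests — tens of poses
  per ensemble, 100-point clustering instances, 50 decoys per fragment
  phase, 1000-frame trajectories — were chosen as the smallest scales at
  which every planted structure is still unambiguously recoverable.

## Known limitations

* Ring geometry uses small fixed pseudo-atom templates, not full
  carbohydrate atom sets (GLYCAM naming, sulfate positions); no in-scope
  computation depends on the difference, but file output is accordingly
  schematic.
* The glycosidic-torsion plausibility of assembled chains is not checked;
  the original workflow filtered such geometry visually and refined it by
  MD, both outside this package's scope.
* Mixed-polarity binding sites split under the nearest-same-type metric
  for even-dp chains (flipped poses cannot re-register), so DBSCAN
  recovers them as separate one-sided clusters; the planted-truth
  polarity summary in the bundled analysis illustrates the difference.
* MM-GBSA energies, including the in-vacuo electrostatic components
  attached to ion sites, are ingested annotations — never recomputed.
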