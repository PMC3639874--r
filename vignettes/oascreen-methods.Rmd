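---
title: "Edge-weighted optimal-assignment similarity for virtual screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-weighted optimal-assignment similarity for virtual screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ligand-based virtual screening (VS) ranks a chemical library by similarity to
a single biologically active query molecule, hoping to enrich other actives at
the top of the list.  Not all parts of a query matter equally: atoms engaged
in crucial protein interactions should be conserved in a hit, whereas linker
regions are interchangeable.  `oascreen` implements a similarity measure that
can express this — the optimal-assignment (OA) molecular similarity with
per-query-atom *assignment-edge weights* — together with evolutionary
optimization of those weights against VS performance metrics, and a
redistribution transform that maps optimized weights back onto atoms for
visual interpretation.

## The optimal-assignment similarity

Two molecular graphs $A$ (atoms $a_1,\dots,a_m$) and $B$ (atoms
$b_1,\dots,b_n$) are compared in two steps.

**Atom similarity matrix.** Every atom carries a standardized vector of
physico-chemical descriptors (below).  The pairwise atom similarity
$S_{ij}$ combines a radial basis function (RBF) over the two descriptor
vectors with a recursive comparison of the atoms' topological neighborhoods:
the neighbors of $a_i$ and $b_j$ — each represented by its atom descriptors
concatenated with the descriptors of the bond connecting it to the center —
are matched by a small optimal assignment of their pairwise similarities, and
the recursion continues to depth 2.  The influence of a neighbor at
topological distance $d$ is damped by the decay

$$ d(a_i, nb) = \left(1 - \frac{\mathrm{dist}(a_i, a_{nb})}{3}\right)^2, $$

which is 1 at the center, $4/9$ at distance 1, $1/9$ at distance 2 and 0 just
beyond the depth-2 cutoff.  The center term and the decayed environment term
are combined as a weighted mean,

$$ s = \frac{(1-\lambda)\,c + \lambda\, d\, e}{(1-\lambda) + \lambda\, d}, $$

with mixing weight $\lambda = 0.5$ (configurable).  The normalization of this
mean — rather than a plain weighted sum — was chosen so that identical atoms
in identical environments score exactly 1, which in turn guarantees a unit
diagonal of the self-similarity matrix.  Isolated atoms fall back to the bare
RBF, so two neighbor-free atoms at descriptor distance $\delta$ score exactly
$\exp(-\gamma\delta^2)$.

**Assignment.** The OA similarity is the maximum over injective mappings
$\pi$ of the smaller molecule's atoms onto the larger molecule's atoms of the
summed mapped similarities,

$$ S(A,B) = \max_\pi \sum_{i=1}^{\min(m,n)} S_{i\pi(i)}, $$

solved exactly by the Hungarian method in $O(\max(m,n)^3)$ (a dense
shortest-augmenting-path solver in compiled code; a brute-force permutation
oracle backs it in the test suite).  Because the raw score grows with
molecule size it is normalized to $[0,1]$ by the geometric mean of the raw
self-similarities,

$$ S_{OA}(A,B) = \frac{S(A,B)}{\sqrt{S(A,A)\,S(B,B)}}, $$

and $S(X,X)$ equals the atom count because the diagonal is 1.

## Assignment-edge weights

For a fixed query $Q$ with atoms $q_1,\dots,q_m$, each assignment edge
starting at query atom $i$ is multiplied by a weight $w_i \ge 0$ subject to
$\sum_i w_i = m$:

$$ S_w(Q,B) = \max_\pi \sum_i w_i\, S_{i\pi(i)}. $$

Uniform weights ($w_i = 1$) recover the unweighted OA exactly.  The weighted
optimum is computed as the ordinary assignment over the row-scaled matrix
$\mathrm{diag}(w)\,S$.  The normalization of the weighted score is not
uniquely determined by the unweighted formula; we use the identity-mapping
weighted self-similarity of the query, $\sum_i w_i \cdot 1 = m$, so the
normalized weighted score is $S_w(Q,B)/\sqrt{m\,n}$ — this makes uniform
weights reproduce the unweighted normalized score bit for bit.

Optimizers search a *raw* vector bounded in $[-0.5, 0.5]^m$; the map onto the
constraint set shifts by $+0.5$ and rescales to sum $m$, with the uniform
vector as the degenerate fallback when every shifted entry is 0.  This keeps
the search space a plain box (every optimizer move is legal after clipping)
while the constraint is enforced inside the fitness evaluation.

## Descriptors

The original descriptor set of the expert system used by earlier OA work is
not reproducible; `oascreen` instead defines a dependency-free, documented
default that captures the same physico-chemical intent
(`default_descriptor_config()`):

* **atoms** ($k_a = 10$): Pauling electronegativity, atomic mass, heavy-atom
  degree, total hydrogen count, formal charge, aromaticity flag, ring flag,
  hybridization code, estimated partial charge (one-pass
  electronegativity-difference model), conjugation flag;
* **bonds** ($k_b = 4$): bond order (aromatic = 1.5), aromaticity, ring and
  conjugation flags.

Each descriptor is standardized by a *fixed* affine range declared in the
configuration (e.g. electronegativity over $[0.7, 4.0]$), never by
data-dependent scaling, so similarity values are stable across libraries.
Values are clipped to $[0,1]$; a descriptor that cannot be computed is imputed
at the neutral value 0.5 with a warning.

**Kernel width.** On this standardized scale the package uses
$\gamma = 8$ for both the atom and the environment RBF, i.e. a Gaussian
bandwidth of $0.25$ ($\gamma = 1/(2\sigma^2)$).  A much wider kernel (of the
order of the full descriptor range, $\gamma \approx 0.1$) makes chemically
distinct atoms nearly indistinguishable — carbon vs oxygen then score about
0.98 — which flattens the whole screening landscape; a bandwidth of a quarter
of the descriptor range keeps heteroatom substitutions (N vs O vs S) clearly
resolved while leaving graded similarity between related environments.  Both
widths and the mixing weight are configurable per run.

**Perception choices.** Molecules are parsed with OpenBabel (via
ChemmineR/ChemmineOB); hydrogens are suppressed and enter only as an atom
count descriptor.  Since the parser emits kekulized structures, aromaticity
is re-perceived with a simplified Hückel rule: a 5- or 6-ring is aromatic
when every member either carries a multiple bond (one $\pi$ electron) or is
an N/O/S lone-pair donor (two), and the count is 6.  This covers the benzene,
pyridine, pyrrole, furan, thiophene, indole, benzofuran and benzothiophene
chemistry exercised by the package; exotic aromatic systems (azulenes,
charged rings) are outside its scope.  Ring membership is derived from the
bridge structure of the bond graph.

## Optimizers

The fitness of a raw weight vector is $1 - \text{metric}$ (minimization) of a
complete VS run on an optimization dataset: normalize the weights, score
every library molecule, rank, and evaluate AUC or BEDROC.  Because the atom
similarity matrices do not depend on the weights they are precomputed once
per dataset; each fitness evaluation then costs one small assignment per
library molecule.

**Constriction PSO.**  Particles move by
$v' = \chi\,(v + r_1\phi_1 (x^h - x) + r_2\phi_2 (x^n - x))$ with
component-wise $r_1, r_2 \sim U(0,1)$, personal-best $x^h$ and
neighborhood-best $x^n$ attractors, $\phi_1 = \phi_2 = 2.05$ and the
Clerc–Kennedy constriction $\chi = 2/|2 - \phi - \sqrt{\phi^2 - 4\phi}|
\approx 0.73$.  The neighborhood is a 2D grid of Manhattan range 2 with
wrap-around (torus); grid dimensions are the most-square factorization of the
population size (30 → 5×6).  Initial positions are uniform in the box,
initial velocity components uniform in $[-0.2, 0.2]$; positions are clipped
to the box after every move; the update is synchronous.

**Differential evolution.**  Binomial recombination per
$u_{ij} = x_{a j} + F \sum_{k=1}^{b} (x_{r_{1k} j} - x_{r_{2k} j})$ when a
uniform draw is at most $CR$ or $j$ is the forced index, else $x_{ij}$.  The
base $x_a$ is a random individual (*DE/rand/1*, $b=1$), the current best
(*DE/best/2*, $b=2$), or the arithmetic combination
$x_i + \lambda(x_{best} - x_i)$ (*DE/current-to-best/1*, $b=1$, crossed over
against $x_i$ — the variant that mixes probabilistic and arithmetic
recombination).  Donor indices are mutually exclusive and exclude the target
(and the base individual for the best-based variants).  Defaults $F = 0.8$,
$CR = 0.6$, $\lambda = 0.6$, population 30.  Selection is greedy one-to-one
replacement (a candidate replaces its target iff not worse), applied
generationally.

Both engines record the best-so-far fitness after every single evaluation, so
a run's trace has exactly `budget` entries and is monotone; each run is fully
reproducible from one integer seed.

## Virtual-screening metrics

* **AUC** — trapezoidal area under the ROC curve, identical to the
  Mann–Whitney pair count with ties worth 1/2.
* **BEDROC** — exponentially rank-weighted enrichment: each active at rank
  $r_i$ of $n$ contributes $e^{-\alpha r_i/n}$; the sum is min–max rescaled
  between the best achievable (actives at ranks $1..n_A$) and the worst
  (actives at the bottom).  The default $\alpha = 53.6$ places 80% of the
  weight mass in the top 3% of the list.
* **ROCE** — sensitivity at the rank cutoff containing the top $x\%$ of true
  decoys (the first $\lceil x/100 \cdot N_{decoys}\rceil$ decoys), divided by
  the realized false positive rate $N^{x\%}_{decoys}/N_{decoys}$.
* **awROCE** — ROCE with every retrieved active weighted by the inverse of
  its chemotype cluster size and the sensitivity averaged over clusters,
  rewarding scaffold-diverse retrieval.
* **Chemotype discovery curve** — fraction of clusters discovered versus
  fraction of decoys passed.

**Tie policy** (the source protocols do not state one; this is a documented
package choice): cutoff and rank-based metrics sort decoys before actives
within a tied score (pessimistic), the AUC uses average ranks.  Every metric
is therefore deterministic and invariant to permutations of tied entries.

## Evaluation protocol

`make_splits()` draws label-stratified random 50/50 splits (stratification is
a package choice on top of plain randomization: it guarantees that both
halves contain both labels, hence that every metric is computable).
`run_experiment()` optimizes on the first half, evaluates externally on the
second half (the two halves are disjoint by id, enforced and tested), and
repeats over splits and multiruns.  Per split the best multirun is selected
by *optimization-split* fitness — never by test performance, which would leak
the external set into model selection.  Multirun stability is the per-split
standard deviation of the optimized metric averaged over splits; the
convergence point of a run is the first evaluation whose best-so-far
performance is within 1% of the final best (relative mode) or within a fixed
0.01 (absolute mode — the mode used by the package's own benchmark tests,
because at desk-scale budgets a metric-scale margin is not distorted by tiny
late improvements).

## Weight visualization

Because the atom similarity integrates depth-2 environments, a large weight
on atom $i$ certifies importance of $i$ *and its surroundings*.  For
rendering, each weight is redistributed over the depth-2 neighborhood
$N(a_i)$ (including the center at decay 1) proportionally to the decay:
first $d_{tot}(i) = \sum_{nb \in N(a_i)} d(a_i, nb)$, then every neighbor
receives $w_i\, d(a_i,nb)/d_{tot}(i)$.  The transform is linear and conserves
the total weight exactly; the result is min–max normalized to $[0,1]$ per
molecule (an all-equal vector maps to 1), and exported as an SDF data field
plus a plain-text radius table with radii linear between 0.2 and 0.8 Å.

## The synthetic planted-pharmacophore generator

To make every stage testable without external screening data,
`generate_planted_dataset()` builds a library in which the ground truth is
known by construction.  Actives are `decoration + cluster scaffold +
planted fragment` (default fragment: an indole attached to a carbonyl
group); each of the default 5 chemotype clusters has its own scaffold.
Decoys reuse exactly the same decoration and scaffold alphabets but end in
confusable tails — benzofuran-3-carbonyl and benzothiophene-3-carbonyl
(N→O/S swaps of the planted motif), indole *without* the carbonyl, naphthoyl,
and simpler acyl groups — so that under uniform weights the ranking is
informative but far from perfect (AUC roughly 0.75–0.9 across seeds at the
default 40 actives / 200 decoys), while concentrating weight on the
fragment's discriminative atoms (the pyrrole N–H, the carbonyl) leaves
substantial headroom.  The query embeds the fragment in its own small ethyl
ketone scaffold (13 heavy atoms).  A `label_noise` rate swaps labels between
random active/decoy pairs, monotonically degrading achievable performance.

What the generator does *not* emulate: property-matched decoys à la DUD,
3D structures and conformational flexibility, activity cliffs, assay noise
beyond label swaps.  Passing the package's statistical tests on this fixture
shows that the optimization machinery recovers a planted signal under the
stated conditions; it is not evidence about enrichment on real screening
decks.

## Problem sizes used by the test and acceptance suites

The original evaluation protocol (15000 evaluations × 10 multiruns × 10
splits per dataset) is a cluster-scale computation.  The package's own
benchmark suites run the same machinery at desk scale, a deliberate design
choice of the test harness: the planted fixture at 40 actives / 200 decoys
with 5 clusters, PSO/DE with population 30 and 1500 evaluations, one split
and one multirun per seed over 10 seeds.  Unit tests use a still smaller
fixture (12/40, 3 clusters) and budgets of 60–90 evaluations where only
bookkeeping is under test.

One caveat of the reduced scale: the *convergence point* statistic (first
evaluation within tolerance of a run's own final best) has a seed-to-seed
spread of several hundred evaluations when runs are truncated at 1500
evaluations, because a run that keeps crawling until the end "converges"
late relative to itself.  Orderings of optimizers by median convergence
point over 10 single runs are therefore noise-dominated at this scale, while
orderings by final fitness are stable; the benchmark suite documents this
where it applies.

## Numerical choices and degenerate inputs

* Assignment ties: any optimal mapping is accepted; tests assert scores, not
  mappings, wherever ties are possible.
* Similarity values are clamped to $[0,1]$ against floating-point drift.
* Disconnected molecules are allowed; topological distance across fragments
  is `Inf`, and the depth-2 machinery never sees it.
* `normalize_weights()` clips its input into the box before shifting, and
  falls back to uniform weights at a degenerate all-zero sum.
* A relative convergence point with a zero final best falls back to the
  absolute mode.
* Empty molecules, empty weight vectors, label-free datasets and
  cluster-free actives in clustered metrics all raise immediate errors.

## Known limitations

* The descriptor set is a documented stand-in with the same intent as the
  original 24+8 expert-system descriptors, not a reproduction; absolute
  similarity values are not comparable to other OA implementations.
* Aromaticity perception is a simplified Hückel rule (see above).
* Stereochemistry and 3D information are ignored.
* The partial-charge estimate is a one-pass electronegativity model, not a
  converged charge-equilibration scheme.
* Substructure matching in the fixture checker compares the heavy-atom
  skeleton and elements, not bond orders.
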