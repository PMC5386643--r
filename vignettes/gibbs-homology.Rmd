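---
title: "Gibbs homology: energy landscapes and knockout targets on PPI networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gibbs homology: energy landscapes and knockout targets on PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gibbsnet)
```

## The model

A cell's interactome is represented as an undirected simple graph $N = (V, E)$
over official gene symbols. Each patient contributes a transcription profile
used as a surrogate for protein concentration: mRNA and protein levels
correlate imperfectly (reported correlations across species and platforms
range from roughly 0.4 to 0.8), but differential expression is informative
enough that a transcriptome overlaid on a curated protein–protein interaction
(PPI) network gives a usable estimate of each node's chemical activity.

Raw measurements are put on a common scale in two steps, both per patient:

1. RNA-seq normalized counts are transformed as $e_i = \log_2(\text{count}_i + 1)$
   (microarray values are already log2 and skip this step);
2. the vector is min–max rescaled,
   $c_i = (e_i - e_{\min}) / (e_{\max} - e_{\min})$,
   so the most down-regulated gene gets concentration 0 (no transcript, no
   protein) and the most up-regulated gets 1.

The rescaling is computed over the patient's full measured gene vector,
*before* restriction to the network, and is invariant under positive affine
transforms of the log-scale values — so platform-wide scale or offset
differences cancel.

Each node then receives a Gibbs free energy

$$G_i = c_i \ln \frac{c_i}{\sum_{j \in N[i]} c_j},$$

where $N[i]$ is the **closed** neighborhood (node $i$ together with its
interaction partners). The denominator is at least $c_i$, so $G_i \le 0$
always: a node is a deep well when it is both highly expressed and embedded
in a highly expressed neighborhood. The network total is $G = \sum_i G_i$.
Natural logarithm throughout; the log2 above is only the count transform.

Three conventions make this total:

* $0 \cdot \ln(0/x) := 0$ — required, because rescaling forces at least one
  exact zero per patient;
* isolated nodes have ratio $c_i / c_i = 1$ and hence $G_i = 0$;
* self-loops are removed at parse time: $N[i]$ already counts $i$ once, and a
  self-loop would double-count it.

## Landscape filtration and the homology subnetwork

Sorting nodes by energy depth turns the network into a rugged landscape.
Raising a filtration plane from the deepest well captures, at each level, the
set of wells below the plane; the induced subgraph on the captured nodes is
the low-energy ("Gibbs homology") subnetwork — the persistent structure of
the landscape.

`gibbs_homology()` interprets its threshold as the **number of deepest wells
captured**. The alternative reading — an absolute energy cutoff — is exposed
as `mode = "energy"` for sensitivity analysis, but the node-count reading is
the default: the standard thresholds (8, 16, 32, 48, 64, 128) are small
dimensionless integers on networks whose totals are on the order of
$-10^3$–$-10^4$, and 32 captured hub nodes yield subnetworks with roughly
130–150 edges, the size at which the published per-patient tables sit. Ties
at the capture boundary are broken by ascending lexicographic symbol —
deterministic and auditable. Captured nodes that are isolated within the
subnetwork are retained (they contribute nothing to the Betti number).

Because capture order is a fixed ranking, captured sets at increasing
thresholds are nested and the homology energy (the sum of captured $G_i$) is
non-increasing in the threshold. Both properties are asserted in the test
suite; they are the defining behavior of the filtration, not incidental.

The reported `homology_energy` is the sum of *full-network* per-node
energies over captured nodes — the filtration captures existing wells, it
does not re-excavate them. Re-evaluating $G_i$ within the subnetwork
topology is available downstream through `knockout_scan()`'s
`recompute_energy` flag, where it is the default (see below).

## Rings, the Betti number, and knockouts

Complexity is measured as the number of independent rings of four or more
proteins: the first Betti number $b_1$ of the dimension-2 flag (clique)
complex, in which every 3-clique is a filled triangle. Triangles therefore
vanish and chordless cycles of length $\ge 4$ persist. Computation is exact:

$$b_1 = (|E| - |V| + C) - \operatorname{rank}_{GF(2)} \partial_2,$$

with $C$ the number of connected components and $\partial_2$ the
triangle-boundary matrix over GF(2). Rank decisions over GF(2) involve no
floating point. The package carries two independent implementations — a
pivot-reduction on sparse edge-index sets (`betti_number()`) and a dense
Gaussian elimination on the full $\partial_1, \partial_2$ matrices
(`betti_oracle()`, capped at 25 nodes) — and the test suite checks their
agreement on hundreds of seeded random graphs. Whether filled tetrahedra
(dimension-3 simplices) should also be included cannot be settled from the
method's published description; the dimension-2 complex is the declared
convention here, and it is the one under which 3-rings vanish and $\ge 4$-rings
are counted.

`knockout_scan()` removes each subnetwork protein in turn (with
replacement — the subnetwork is restored between knockouts), recomputing
$b_1$ and the subnetwork energy after each removal. All proteins achieving
the minimal post-removal Betti number are **equivalent targets**; ties are
genuine alternatives and all are reported, in lexicographic order. Note the
delta can be negative: removing a hub whose spokes fill the rim of a wheel
*raises* $b_1$ (the rim becomes an unfilled ring), and the scan represents
that faithfully.

Two bookkeeping conventions are declared rather than inherited, because the
source material leaves them open:

* **Energy recomputation.** With `recompute_energy = TRUE` (default), the
  post-knockout energy re-evaluates $G_i$ on the reduced subnetwork
  topology — removing a protein changes its neighbors' chemical potential.
  With `FALSE`, energies are partial sums of full-network values and a
  knockout simply subtracts the removed node's $G_i$.
* **Sign of the energy change.** Reported as `delta_gibbs = post − nominal`
  (removing a deep well typically gives a positive delta), with
  `abs_delta_gibbs` alongside, since published tables print the change with
  the opposite sign and an undeclared convention.

## Cohort aggregation

`pareto_counts()` credits **every** member of a patient's equivalent-target
set with one count — which is why total target instances exceed the patient
count whenever ties exist. `group_energy_comparison()` compares homology
energies between histology groups with a two-sided Mann–Whitney U test:
when $\binom{n_1+n_2}{n_1} \le 20{,}000$ the p-value is computed by
exhaustive enumeration of group assignments (exact even in the presence of
ties); larger groups fall back to the normal approximation. P-values are
reported unadjusted. The choice of a nonparametric test is this package's
declaration — energies are heavy-tailed sums, and no test was named in the
published comparison.

`threshold_sweep_stats()` repeats the whole per-patient pipeline at each
threshold and reports the mean and SD of the number of equivalent targets.
Low thresholds leave so little subnetwork complexity that many knockouts tie;
high thresholds usually isolate a single target. This is a tendency observed
on seeded synthetic cohorts, not an invariant, and the tests treat it as such.

## The synthetic-data generator

Real inputs at scale — a curated human interactome (~9.5k nodes, ~43k edges)
and hundreds of RNA-seq profiles — require downloads, so the package ships a
seeded generator producing both input types in the same formats the readers
consume:

* **Network:** preferential attachment with `edges_per_node = 2` (mean degree
  about 4, matching the curated human PPI's 2·43,086/9,561 ≈ 9.0 incident
  half-edges, i.e. mean degree ≈ 4.5), giving the heavy-tailed degree
  distribution characteristic of interactomes.
* **Expression:** integer counts drawn log-normal(meanlog = 6, sdlog = 0.5):
  median ≈ 400 with a right-skewed spread, a plausible model of *expressed*
  genes under library-size normalization. Counts are integer-rounded so the
  RNA-seq code path (`log2(count+1)`) is genuinely exercised.
* **Planted module:** optionally, two or more rings of length ≥ 4 sharing a
  single hinge node are wired in, attached to the main component by one edge
  from a ring node to a uniformly chosen background node, and over-expressed
  by a multiplicative `boost` (default 50). The hinge is recoverable ground
  truth: its removal collapses the ring count of the module, which is exactly
  what the knockout scan rewards.

The dispersion default deserves a note. The planted-module contract is that
boosted nodes occupy the top concentration ranks and form the deepest wells.
After min–max rescaling, the bulk concentration level is set by the spread of
the background draws relative to the boosted maximum: at sdlog around 1 the
background sits high enough that large hubs (whose closed neighborhoods carry
a lot of mass) out-deepen the boosted ring nodes, and the module is no longer
reliably planted. sdlog = 0.5 keeps the fixed boost dominant over
gene-to-gene dispersion, as a positive-control construction should. The
deliberate consequence: real transcriptomes are *more* dispersed and noisier
than this generator, so a passing recovery test demonstrates that the
mechanism (energy capture → ring topology → hinge knockout) is implemented
correctly — it does not certify recovery rates on real tumor data.

The `histology_shift` option of `generate_cohort()` separates groups
energetically by multiplying the counts of the top-degree-decile genes by
$2^{\text{shift}}$. A uniform shift of *all* counts would be a no-op — the
rescaling is affine-invariant in log space by design — so the shift targets
hub genes, which both raises their concentrations and deepens the landscape,
yielding detectably different group homology energies.

## Numerical and degenerate-input choices

* Energy accumulation tolerance: totals equal per-node sums to within 1e-9
  (checked); individual closed forms are reproduced to the same tolerance.
* Constant expression vectors cannot be rescaled and raise a
  degenerate-profile error; the generator perturbs a single count when a
  degenerate draw would otherwise occur (only possible at sdlog = 0 with no
  planted module).
* Duplicate gene symbols in one profile are averaged (arithmetic mean), with
  a message; max-collapsing was the alternative and either is defensible, but
  averaging is symmetric and order-independent.
* Unmeasured network genes default to concentration 0 (`missing_policy =
  "zero"`), consistent with "no transcript implies no protein", and
  contribute $G_i = 0$ by the continuity convention; `"drop"` instead
  restricts the working network to measured genes.
* Thresholds beyond the node count capture everything, with a warning;
  empty networks have Betti 0 and 0 components by convention.

## Problem sizes in the shipped tests

The test suite and the acceptance script run entirely on generated data:
oracle agreement on 200 random graphs of up to 15 nodes; filtration
persistence across the 8–128 sweep on 50 patients of a 200-node network;
planted-hinge recovery on 40 replicates of a 300-node network with two
planted 6-rings (boost 50, threshold = module size + 8); cohort statistics
on 60 patients at threshold 32. These sizes keep a full run in tens of
seconds while exercising every code path at the scale the method's logic
actually turns on (ring topology is local; the Betti computation is exact at
any size).

## Limitations

* Official-symbol string matching links expression to the network; no alias
  or identifier mapping is attempted.
* No interaction-confidence weighting, no directionality, no
  physical-vs-genetic evidence filter.
* Only $b_1$ of the dimension-2 flag complex is computed — no higher
  homology, no persistence pairing across continuous thresholds.
* Single-node knockouts only; combination perturbations are out of scope.
* The synthetic generator emulates degree heavy-tails and expression
  skew, not TCGA's normalization pipeline, batch structure, or the
  zero-inflation of lowly expressed genes.
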