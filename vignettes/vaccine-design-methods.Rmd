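---
title: "Epitope vaccine design as a team orienteering problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epitope vaccine design as a team orienteering problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evdesign)
library(dplyr)
```

## The design problem

An epitope-based vaccine delivers a set of short peptides (here 9-mers, the
typical MHC class I ligand length) chosen from the proteomes of the targeted
pathogens. Three delivery principles are in common use: an *epitope mixture*
(the peptides are delivered separately), a *string-of-beads* (the peptides
are concatenated into one polypeptide, which the proteasome must cleave back
apart at the junctions), and a *mosaic* (the peptides are merged at their
overlaps into a compact artificial antigen). A *cocktail* generalizes all
three to several polypeptides optimized jointly.

`evdesign` treats all of these as one combinatorial problem on a weighted
directed graph. Vertices are the candidate epitopes plus a terminus vertex
$s$ marking the N- and C-termini of each polypeptide; what the edge weights
mean is the only thing that changes between design kinds:

* **mixture** — all weights 0, no edge budget: only the choice of vertices
  matters;
* **string-of-beads** — the weight of edge $(i, j)$ is the negative
  proteasomal cleavage log-likelihood at the junction when epitope $j$
  follows epitope $i$ (plus a small penalty for cleavage at off-junction
  positions, which would destroy the flanking epitopes);
* **mosaic** — the weight is the number of residues that appending $j$ after
  $i$ adds once the two are merged at their longest suffix–prefix overlap,
  so a tour's weight *is* the assembled polypeptide's length in amino acids;
* **custom** — weights are read from a table, e.g. produced by an external
  spacer-design method for every ordered epitope pair.

The design then asks for $n$ vertex-disjoint simple tours through $s$, each
visiting at most $k$ epitopes with edge weight at most $h$, maximizing the
vaccine immunogenicity of the selected vertices. This is the team
orienteering problem, and it is NP-hard; the point of paying that price is
that selection and assembly are decided *together*, with optimality
certificates, instead of greedily selecting epitopes first and discovering
later that they cannot be assembled well.

### Immunogenicity model

Each epitope $v$ bound to MHC allele $a$ contributes independently:
$$I(P) = \sum_{v \in P} \sum_{a \in A} p_a\, i_{va},$$
with $p_a$ the allele's frequency in the target population and $i_{va}$ the
per-pair immunogenicity. Immunodominance between epitopes cannot currently
be predicted, hence the linearity assumption. $i_{va}$ is derived from
predicted binding: either the log-transformed IC50,
$i = \mathrm{clamp}(1 - \log \mathrm{IC50} / \log 50000,\ 0,\ 1)$ (1 nM or
stronger scores 1, 50 µM or weaker scores 0), or a flipped percentile rank
$100 - \mathrm{rank}$, or precomputed scores taken as-is. A pair is a
*binder* when its IC50 is at most 500 nM (boundary inclusive); binders drive
the coverage constraints and the population-coverage metric, not the
objective.

### Cleavage model

Junction cleavage is scored with a position-specific scoring matrix
$\psi(a, i)$ over offsets $i \in \{-4, \dots, +1\}$ around the scissile
bond: $\phi_C(s, k) = \sum_{i=-4}^{+1} \psi(s_{k+i}, i)$, positive meaning
cleavage is more likely than the prior. "Position $k$" denotes the bond
before the 0-based residue $k$, which makes the window the standard P4–P2′
convention. The junction edge weight combines the (negated) on-site score
with $K = 2$ flanking off-site scores weighted by $\beta = 0.1$:
$$w(e_{ij}) = -\phi_C(e_i e_j, \ell) + \beta \sum_{k=1}^{K}
  \left[\phi_C(e_i e_j, \ell-k) + \phi_C(e_i e_j, \ell+k)\right],
  \qquad \ell = |e_i|.$$
A negative weight marks a junction cleavage site. The *cleavage score* of a
construct is the negative sum of its edge weights — higher is better.

## The integer linear program

The tour structure is encoded with binary edge variables $x_{vwt}$ and
vertex variables $y_{vt}$ (consistency: in-degree = out-degree = $y$), one
departure and one return through $s$ per tour, and Miller–Tucker–Zemlin
integer node potentials $u_{vt} \in [1, |V|-1]$ that must increase along
used edges, which excludes subtours not passing through $s$. Side
constraints cover at least $\Theta_s$ pathogens and $\Theta_a$ alleles
(via indicator variables bounded by the incidence of selected epitopes) and
enforce a minimum average epitope conservation $\Gamma$, expressed as a
fraction of the pathogen panel and scaled internally by $|S|$ (conservation
is conventionally reported as a percentage).

Decisions worth noting, where the design was genuinely open:

* The per-tour edge budget $h$ sums over **all** tour edges, including the
  two terminus edges. For mixtures and string-of-beads the terminus edges
  weigh 0, so this is indistinguishable from summing inter-epitope edges
  only; for mosaics it is what makes a tour's weight equal its polypeptide
  length, which the assembler relies on.
* $h = \infty$ omits the budget constraint entirely rather than using a
  big-M, avoiding needless numerical degradation.
* The MTZ potential bound $[1, |V|-1]$ caps a single tour at $|V|-1$
  epitopes. Potentials only need to order the visited vertices, so with
  $k < |V|$ (every practical configuration) the bound is harmless; it is
  kept as the standard formulation.
* Objective modes: `immunogenicity` alone; `coverage` adds the number of
  covered pathogens; `conservation` maximizes average conservation and
  pathogen coverage together with immunogenicity at unit weights —
  immunogenicity is typically orders of magnitude smaller than the two
  count-valued terms, so it acts as a tie-breaker; `weighted` exposes the
  three weights directly.
* Ties between equal-objective optima are solver-dependent and not part of
  any contract; all tests compare objective values and constraint
  satisfaction, never tour identity.

The program is written in GNU MathProg (the model ships in
`inst/glpk/ev_design.mod`) and solved with GLPK's `glpsol`; per-instance
data files are generated on the fly. A time limit and a relative MIP gap
can be set in `design_config()`; with a nonzero gap the solver may stop at
a certified near-optimum (status `"feasible"`), and bit-stability of
outputs is then no longer guaranteed. Infeasible constraint sets raise a
classed error (`ev_infeasible`) rather than returning an empty design.

`brute_force_design()` is a deliberately independent oracle: it enumerates
every assignment of epitopes to tours, orders each tour by exhaustive
permutation, applies every constraint, and breaks ties lexicographically.
It refuses more than 9 epitopes or 2 tours. The test suite solves dozens of
randomized instances both ways and requires the objectives to agree to
$10^{-6}$.

## The Pareto frontier

For string-of-beads designs, immunogenicity and cleavage pull in different
directions. `pareto_frontier()` sweeps the trade-off with the augmented
$\varepsilon$-constraint method: two lexicographic solves establish the
cleavage-score range, $\varepsilon$ runs over an evenly spaced grid across
it (endpoints included), and each solve maximizes
$I(P) + \delta \cdot \mathrm{cleavage}$ subject to cleavage
$\ge \varepsilon$. The augmentation coefficient defaults to
$10^{-3} \cdot \mathrm{range}(I)/\mathrm{range}(\mathrm{cleavage})$, small
enough never to outweigh a true immunogenicity difference but enough to
discard weakly efficient solutions. A useful consequence: reordering a
tour's epitopes changes cleavage but not immunogenicity, so every returned
point carries the best ordering of its own epitope set — which is exactly
why the shuffle experiment (`shuffle_experiment()`) can never find a random
permutation with a better cleavage score. Whether to sweep the raw edge
weight or the cleavage score is a sign convention only; the cleavage score
is used because that is the quantity reported.

## Evaluation metrics

* **Population coverage**: the probability that a person carries at least
  one binding allele, $1 - \prod_i (1 - \sum_{a \in A_i} y_a p_a)^2$ over
  loci $i$ (two alleles per locus). Also reported relative to the panel
  maximum (all alleles bound), since no vaccine can exceed that ceiling.
* **Pathogen coverage**: how many input sequences contain at least one
  vaccine epitope.
* **Conservation**: the mean fraction of sequences containing each epitope.
* **Positional tracks**: on a gapped alignment, per-column Shannon entropy
  (bits) quantifies variability; epitope occurrences mapped through the
  alignment give per-column coverage counts and potential immunogenicity.
  Columns whose consensus is a gap are dropped (they represent minority
  insertions); consensus ties break by a fixed residue order. Gap
  characters within retained columns count as a 21st symbol by default
  (`gaps = "exclude"` drops them); the smoothing window defaults to 9
  columns, one epitope length — both are conventions, not contracts, and
  are exposed as arguments.

## Synthetic data: what it emulates, and what it does not

All tests and the acceptance script run on `synthetic_spec()` data:

* **Antigens** descend from one random ancestor by independent per-site
  substitution (default 20 sequences of 50 residues at rate 0.05, giving
  the within-gene diversity of a variable viral protein at toy scale). Low
  rates produce the conserved-region structure that mosaics exploit. There
  are no indels, no recombination, no phylogenetic correlation — so the
  generator is *not* a faithful viral evolution model, and passing tests
  say nothing about predictor accuracy on real sequences.
* **Alleles** (default 6 across the three classical loci) draw frequencies
  on a per-locus simplex scaled to 0.8, keeping the diploid coverage
  formula valid while leaving frequency mass outside the panel, as in
  reality.
* **Affinities** are log-normal IC50s (median 10 µM, log-sd 2 — the broad,
  weak-binder-dominated distribution binding predictors produce), with a
  Bernoulli fraction (default 0.1) forced below the 500 nM binder cutoff by
  truncated sampling, so the binder rate is controlled exactly.
* **The cleavage matrix** has zero-mean Gaussian entries (sd 0.3) plus an
  additive motif at offset $-1$ for hydrophobic/basic residues, emulating
  the proteasome's C-terminal preferences well enough that some junctions
  score positive and ordering genuinely matters.

Each generator call uses its own seed stream derived from the master seed,
so outputs are bit-identical per seed and independent across generators.

## Problem sizes and numerical choices

The randomized oracle-agreement suite uses instances of 6–8 epitopes, 1–2
tours and vertex budgets of 2–3, where exhaustive enumeration is exact and
fast; the frontier and shuffle experiments use 8–12 epitopes with budgets
of 4–6, the largest sizes at which every claim can still be verified
against full enumeration (720 orderings per epitope set). These sizes are a
choice about verifiability: the ILP itself scales to thousands of epitopes,
quadratically in variables, at the cost of solve time. Floating-point
comparisons use $10^{-9}$ slack on constraint boundaries and $10^{-6}$ on
objective agreement; the $\varepsilon$-constraint bound is nudged by a
$10^{-9}$ relative tolerance so that the lexicographic extreme remains
feasible at its own level.

## Limitations

The linear immunogenicity model ignores immunodominance; binding affinity
is a proxy for T-cell reactivity; mosaic designs are not cleavage-scored
(their processing is not modelled, so mosaic immunogenicity may be
optimistic); spacer *design* is delegated to external tools via the custom
edge table; and GLPK, while exact, will not match commercial solvers on
instances with tens of thousands of epitopes — pruning the candidate set
(e.g. to the top few thousand epitopes by immunogenicity, as the
command-line interface's `--top` flag does) is the practical remedy, and
designs built on subsets generalize well when conserved epitopes are
abundant.
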