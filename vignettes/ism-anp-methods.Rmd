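---
title: "Structuring and weighting risk-factor systems with ISM and ANP"
author: "ismanp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structuring and weighting risk-factor systems with ISM and ANP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ismanp)
```

## The problem

Injury-prevention studies framed by the Haddon matrix elicit large pools of
candidate risk factors (host, agent/medium, physical environment, social
environment), score their importance with expert Likert questionnaires, and
then need two things the raw scores do not give: the *structure* of the
factor system (which factors drive which) and the *relative weight* of each
factor inside that structure. This package implements the standard two-phase
answer: interpretive structural modeling (ISM) for the structure, and the
analytic network process (ANP) for the weights, with questionnaire
psychometrics in front and deterministic synthetic-data generators behind
every stage.

The bundled worked example, `drowning_fixtures()`, transcribes the printed
tables of a published application of this workflow to drowning risk in
preschool children: 18 common factors condensed from 50 questionnaire items,
four Haddon clusters, a printed reachable-set worksheet, a five-level
hierarchy, and reported global weights.

## Stage 1: psychometrics and exploratory factor analysis

The questionnaire stage treats 5-point Likert scores as numeric and works
from Pearson correlations (`item_correlations()`); polychoric correlations
are out of scope, matching common practice for importance-rating
instruments. Reliability and suitability statistics are the classical ones:

* **Cronbach's alpha** (`cronbach_alpha()`):
  $\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)$ with sample
  variances (denominator $n-1$) throughout. The population-variance variant
  differs only in the fourth decimal at questionnaire-scale $n$; one
  convention is fixed and documented rather than exposed as an option.
* **KMO** (`kmo()`): squared correlations against squared anti-image partial
  correlations from the inverse correlation matrix. On an exact identity
  matrix the statistic is 0/0; the package returns 0 with a warning, reading
  "no common variance" as "no sampling adequacy". A ridge option
  (`ridge = 1e-8`) is available for near-singular matrices and off by
  default.
* **Bartlett's sphericity** (`bartlett_sphericity()`):
  $\chi^2 = -(n - 1 - (2p+5)/6)\,\ln|R|$ on $p(p-1)/2$ degrees of freedom;
  requires $n > p$ and $|R| > 0$.

`efa()` performs principal-component extraction (eigendecomposition of the
correlation matrix), retains components by one of three rules, and
varimax-rotates the retained loadings. The default retention rule is the
Kaiser criterion read *strictly* (eigenvalue $> 1$; a component at exactly 1
is excluded), because that is how the rule is stated in the applications
this package mirrors; `"cumulative"` (smallest $k$ reaching a target
percentage, default 85%) and `"fixed"` are also available. Variance
contributions are reported as $100\lambda_j/p$ per item block with prefix
sums, which reproduces the layout of published initial-eigenvalue tables
computed *within* each Haddon dimension; `efa()` therefore accepts any item
subset, and whole-questionnaire runs are equally valid.

Rotation delegates to `stats::varimax()` without Kaiser row normalization,
so the rotation acts on raw loadings and the reported criterion
(`varimax_criterion()`) is exactly the quantity being maximized.
Orthogonality preserves row communalities to machine precision. One
numerical caveat is worth knowing: a loading matrix whose squared loadings
are perfectly balanced across factors (for example a simple structure
rotated by exactly 45 degrees) sits at a stationary point of the criterion,
and any gradient-based rotation, this one included, will legitimately not
move from it. Real data never sits there; constructed examples can.

Missing responses are rejected at ingestion rather than silently imputed;
studies of this kind report complete valid questionnaires only, and listwise
deletion, where wanted, is a one-line `na.omit()` before the call.

## Stage 2: interpretive structural modeling

Expert pairwise judgments arrive as V/A/X/O codes per factor pair
(`build_adjacency()`): V means the row factor influences the column factor
($a_{ij}=1$), A the reverse, X mutual influence, O none; unlisted pairs
default to O and the diagonal is 0. The reachability matrix is the Boolean
fixed point $M = (A+I)^k$ with $(A+I)^k = (A+I)^{k+1}$, computed by repeated
Boolean squaring (`transitive_closure()`); Warshall's algorithm would be an
equivalent implementation of the same contract.

`factor_sets()` reads the reachable set $R(F_i)$ off row $i$, the antecedent
set $Q(F_i)$ off column $i$, and their intersection. `partition_levels()`
iteratively extracts all factors with $R \cap Q = R$, removes them,
recomputes the sets on the remaining submatrix, and repeats. **Level
numbering:** this extraction rule places *sinks* — the factors that
influence nothing further, i.e. the direct consequences — in level 1, and
root causes in the last level. Some ISM literature numbers from the root
end; the choice here matches the published hierarchy the fixtures
transcribe, and is stated on every output rather than assumed.

Two behaviors are deliberate around imperfect inputs:

* Published reachable-set tables are sometimes not perfectly transitively
  closed (transcription or rounding of the underlying figures). The
  reconstruction entry point `reachability_from_sets()` therefore *checks*
  closure (`check_closure()` lists every violating triple) instead of
  assuming it, and `partition_levels()` runs on the matrix as given with a
  warning, so published worksheets can be reproduced verbatim. `reclose =
  TRUE` re-closes first; on the bundled fixture the partition is identical
  either way, which the test suite verifies.
* The bundled worksheet also has two internal inconsistencies that the
  package preserves rather than corrects: the printed antecedent set of F2
  omits F16 although F2 appears in the reachable set of F16 (the recomputed
  value is $\{1, 2, 16\}$), and the printed level table omits F8 entirely,
  while the extraction rule necessarily places it in level 3. Both are
  asserted explicitly in the tests so the discrepancy is visible, not
  papered over.

`hierarchy_digraph()` exports the model diagram: nodes grouped by level,
edges the *transitive reduction* of the strict reachability relation —
the minimal edge set with the same reachability, so risk reads as
transmitted stepwise along arrows. Reduction is well-defined only for
acyclic relations; mutual pairs raise an error rather than an arbitrary
choice. `write_dot()` emits deterministic Graphviz DOT with one
`rank=same` block per level.

## Stage 3: analytic network process

`build_network()` converts a relation matrix into the ANP network: an edge
$j \to i$ for every off-diagonal 1 at $(j, i)$, plus the Haddon cluster
assignment. The default input is the *reachability* matrix, so direct and
indirect influence both enter the network; passing an adjacency matrix
restricts to direct edges, and `extra_edges` admits inner dependences beyond
either.

**Supermatrix orientation.** Entry $(i, j)$ of the supermatrix is positive
iff factor $j$ influences factor $i$: column $j$ distributes $j$'s influence
over its targets, using the priority vector of the judgment matrix that
compares those targets with respect to $j$ (`assemble_unweighted()`). This
orientation is chosen because under it, and only under it, a factor that
nothing influences has an identically zero row, hence zero limit weight for
*every* choice of positive judgments — exactly the structural zeros the
published analysis reports for its four uninfluenced root/source factors
(F1, F8, F15, F16). Factors influencing nothing (sinks) receive an absorbing
diagonal 1 so every column sums to one; leaving their columns zero would
break the limit contract.

Local priorities use the eigenvalue method (`priority_vector()`): principal
eigenvector of the positive reciprocal matrix, normalized to sum 1.
Consistency (`consistency()`) is $CI = (\lambda_{\max} - m)/(m - 1)$,
$CR = CI/RI(m)$ with Saaty's random indices, gate $CR < 0.1$; $m \le 2$ is
consistent by construction and CR is defined 0. The RI table covers orders
1–15 (the classic ten values plus the published extension): a root-cause
factor that reaches most of an 18-factor network yields comparison matrices
of order above ten — the bundled network itself contains an order-13
criterion — so stopping at ten would make the method inapplicable to its own
motivating use case. Orders beyond 15 raise an error advising decomposition.

Cluster weighting (`cluster_weight_matrix()`, `apply_cluster_weights()`)
scales each block $W_{rc}$ by a cluster weight $a_{rc}$ and renormalizes
columns. Because columns distribute influence here, the clusters compared
for block-column $c$ are the clusters *receiving* $c$'s influence; with no
cluster judgments supplied, the linked clusters are weighted uniformly — the
fallback used whenever inter-cluster comparisons are unpublished. The
renormalization after blockwise scaling is required for column
stochasticity and is applied always.

The limit (`limit_supermatrix()`) uses repeated squaring with the fixed
point tested as $\lVert ZW - Z\rVert_{\max} < 10^{-10}$ (testing successive
squarings alone would accept the identity on a periodic chain), a cap of
200 squarings, and a Cesàro fallback averaging a window of 32 consecutive
powers for periodic or otherwise non-convergent chains; the method actually
used is recorded on the result. `global_weights()` takes any column when
all columns agree (irreducible case) and otherwise — the typical case for
acyclic networks with several absorbing sinks — the renormalized row means.

One structural fact follows and is worth stating plainly: a *pure power
limit* of an acyclic weighted supermatrix with absorbing sinks concentrates
all mass in the sinks, so every transient (mid-hierarchy) factor gets
weight 0. The published analysis this package mirrors reports a positive
weight for a mid-level factor, which a power limit of such a network cannot
produce; its software may use a different synthesis. The package exposes
both limit methods, records which was used, and makes no attempt to guess
an unpublished synthesis — consequently the bundled reproduction targets
the *structural* facts (which weights are zero) rather than the printed
numeric weights, whose expert judgment matrices were never published.

## Synthetic data: what it emulates and what it does not

`generate_responses()` draws standard-normal latent factors, forms items as
loading-weighted sums plus normal noise, z-scales, maps to mean 3 / SD 1,
rounds half-up and clips to 1–5. This emulates a Likert questionnaire with a
planted common-factor structure; it does not emulate acquiescence bias,
floor/ceiling clustering, ordinal thresholds, or respondent demographics.
Passing EFA-recovery tests on this generator shows the extraction and
rotation machinery recovers planted structure through Likert
discretization — not that any particular real questionnaire has that
structure. The discretization (round half-up, clip) is documented because
recovery quality depends on it.

`generate_judgment()` builds $p_{ij} = (w_i/w_j)\,e^{\varepsilon_{ij}}$ with
antisymmetric normal noise, so reciprocity is exact for every noise level
$\delta$; $\delta = 0$ gives a perfectly consistent matrix whose priority
vector is $w$ and whose CR is 0. Optional rounding snaps to the 1–9 scale
and its reciprocals, nearest in log space, choosing reciprocal pairs from
the scale itself so no floating-point drift enters. At $\delta = 0.1$ and
$m = 4$ the median CR across seeds sits under the 0.1 gate, which the tests
verify as a calibration property. `generate_random_dag()` draws a random
topological order and includes forward edges with a given density — acyclic
by construction. All generators are pure functions of their arguments
(seed included) and leave the global RNG stream untouched.

`seeded_judgments()` fills a whole network's judgment requirements with
consistent matrices from seeded log-normal weight vectors; it stands in for
unpublished expert comparisons when only structural conclusions are tested.

## Problem sizes and numerical settings

The test suite works at the scale the methods are designed for: the
18-factor published network end-to-end (including 50 reseeded ANP runs for
the structural-zero law), 1000 random digraphs up to $n = 6$ and 200 random
DAGs up to $n = 12$ against independent closure/partition oracles, and 20
replicated EFA recovery runs at $n = 500$ respondents. Tolerances:
reciprocity 1e-6 on input validation, eigen/limit fixed points 1e-10 to
1e-12, stochasticity 1e-9, oracle agreement 1e-9 or exact. Ties in ranking
share the smaller rank; ties in the transitive reduction and all output
orderings resolve by ascending factor index, so every artifact is
byte-reproducible from its inputs.

## Known limitations

* MICMAC driving/dependence analysis, fuzzy or grey ISM, BOCR structures,
  and interval/fuzzy ANP are out of scope.
* Polychoric correlations and confirmatory factor analysis are not
  provided; Likert scores are treated as numeric.
* Transitive reduction (and hence the exported diagram) requires an acyclic
  strict relation; networks with mutual influence export reachability but
  not a reduced diagram.
* The printed global weights of the bundled study are not numerically
  reproducible from published information (its judgment matrices are not
  public); the package reproduces the hierarchy, the worksheet, and the
  structural zeros, and reports its own seeded weights as such.
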