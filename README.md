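# ismanp

Structuring and weighting expert-elicited risk-factor systems, the way
Haddon-matrix framed injury-epidemiology studies do it: questionnaire
psychometrics and exploratory factor analysis condense Likert items into
common factors; **interpretive structural modeling (ISM)** turns pairwise
influence judgments into a multi-level hierarchy; the **analytic network
process (ANP)** converts the influence network plus Saaty judgment matrices
into global factor weights.

## The methods in brief

**ISM.** From V/A/X/O pairwise relation codes an adjacency matrix *A* is
built, and the reachability matrix is the Boolean fixed point
*M* = (*A* + *I*)^k with (*A* + *I*)^k = (*A* + *I*)^(k+1). Row *i* of *M*
gives the reachable set R(F_i), column *i* the antecedent set Q(F_i).
Factors satisfying R ∩ Q = R are extracted as a level, removed, and the
procedure repeats: level 1 holds the surface consequences (sinks), the last
level the root causes. The hierarchy exports as a rank-grouped Graphviz
digraph over the transitive reduction.

**ANP.** Factors are grouped into Haddon clusters; each factor's influence
is distributed over its targets by the principal-eigenvector priorities of
Saaty 1–9 judgment matrices (consistency gate CR = CI/RI < 0.1). The
unweighted supermatrix W0 is blockwise scaled by cluster weights and
column-renormalized to the weighted supermatrix W, and global weights come
from the limit W∞ = lim W^k (repeated squaring; Cesàro fallback for
periodic chains). In this package's orientation, entry (i, j) > 0 iff j
influences i — under which any factor nothing influences is *structurally*
forced to weight zero, whatever the judgments.

**Psychometrics.** Cronbach's α, the KMO sampling-adequacy measure,
Bartlett's test of sphericity, and principal-component EFA with strict
eigenvalue-> 1 retention and varimax rotation.

A deterministic synthetic-data generator covers every input (Likert
responses with planted loadings, reciprocal judgment matrices with
controlled inconsistency, random influence DAGs), and
`drowning_fixtures()` ships verbatim transcriptions of the printed tables
of a published ISM–ANP analysis of preschool drowning risk factors
(18 factors, 4 clusters, reachable-set worksheet, 5-level hierarchy,
reported weights).

## Worked example

```r
library(ismanp)

fx <- drowning_fixtures()
m  <- reachability_from_sets(fx$reachable_sets)   # M from the printed R(Fi)
partition_levels(m)                                # warns: sets not closed
#> ISM level partition (level 1 = surface):
#>   L1: F4, F5, F18
#>   L2: F3, F13, F17
#>   L3: F2, F6, F7, F8, F10, F11, F12
#>   L4: F1, F9, F14
#>   L5: F15, F16
```

Level 1 holds the direct consequences (risky behaviors F4, lack of
immediate protection F5, medical rescue F18); level 5 the root causes
(community safety system F15, family economic background F16). The printed
source table omits F8 from its level listing; the extraction rule places it
in level 3, which is what the package reports.

```r
net <- build_network(m, setNames(fx$factors$cluster, fx$factors$code))
net
#> ANP network: 18 factors in 4 clusters; 60 influence edges
#>   sources (uninfluenced): F1, F8, F15, F16
#>   sinks (influence no one): F4, F5, F18

res <- anp_pipeline(net, seeded_judgments(net, seed = 42))
head(res$weights[order(res$weights$rank), ], 5)
#>    factor    weight rank
#> 4      F4 0.4507...    1
#> 5      F5 0.4205...    2
#> 18    F18 0.1288...    3
#> 1      F1 0.0000       4
#> ...
```

The four source factors (F1, F8, F15, F16) get exactly zero global weight —
the structural-zero fact the published study reports — for *any* positive
judgments, because nothing influences them. With a pure power limit of this
acyclic network all remaining mass sits in the three absorbing sinks; the
seeded judgment matrices stand in for the study's unpublished expert
comparisons, so the split among the sinks (0.45/0.42/0.13 above) is
illustrative, not a reproduction of the printed weights.

The end-to-end wrapper writes every artifact (reachability CSV, factor-set
JSON, level table, DOT digraph, supermatrix stages, weight table,
manifest):

```r
run_pipeline(cluster_of = setNames(fx$factors$cluster, fx$factors$code),
             reachable_sets = fx$reachable_sets,
             judgments = "seeded", seed = 42, out_dir = "out")
```

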