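---
title: "Gravity-model centralities and SIR evaluation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gravity-model centralities and SIR evaluation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how gravispread's methods are defined, which
conventions were chosen where several were defensible, and what the test
suite does and does not establish.

## The model family

All centralities in the package instantiate one template, the truncated
gravity sum (`gravity_sum()`): node $i$ accumulates pairwise attraction
$\mathrm{coupling}(i,j)\, m_i(i)\, m_j(j) / d(i,j)^2$ over every node $j$
with $1 \le d(i,j) \le R$, where $d$ is the shortest-path hop count.
Pairs in different components contribute nothing. The models differ only in
mass and coupling:

| method | focal mass | attractor mass | coupling |
|--------|-----------|----------------|----------|
| G      | $k_s$     | $k_s$          | 1 (neighbourhood fixed at $d \le 3$) |
| IGC    | $k_s$     | $k$            | 1 |
| LGM    | $k$       | $k$            | 1 |
| GGC    | $S_p = e^{-\alpha C_i}k$ | same | 1 |
| KSGC   | $k$       | $k$            | $e^{(k_s(i)-k_s(j))/(k_{s,\max}-k_{s,\min})}$ |
| DKGM   | $k + k_s^*$ | same         | 1 |
| MCGM   | mixed $k$, $k_s$, eigenvector | same | 1 |
| SEGM   | $SE = e^{E(i)}k$ | same     | 1 |
| HVGC   | $HV$      | $HV$           | $e^{-c(i)}$ (focal node only) |

G+ and IGC+ post-process their base model by summing scores over
first-order neighbours.

HVGC's two ingredients address two failure modes of the others. The HV
index — the summed degrees of those neighbours whose degree reaches the
node's H-index — measures the *collective* strength of a node's strong
neighbourhood rather than a single scalar of the node itself. Burt's
constraint coefficient $c(i)$ measures tie redundancy; the factor
$e^{-c(i)}$ (applied to the focal node only, so attraction between a pair
is deliberately asymmetric) boosts structural-hole occupants — nodes whose
removal severs communities — that k-shell demotes because their degree
within any single community is low.

Assumptions inherited from the family: the graph is undirected, unweighted
and simple; all masses are non-negative; the inverse-square distance decay
is fixed, not fitted.

## Tunable parameters

* **Truncation radius `R`** (hops, default `"auto"`): resolved as
  $\max(1, \mathrm{round}(\langle d \rangle / 2))$, rounding half-up. The
  radius trades locality against cost; on small-world networks the
  resolved value is typically 1–2. For the packaged ten-node example the
  package uses $R = 1$, the value consistent with the fixture's reference
  HVGC scores. Model G ignores `R`: its distance-3 neighbourhood is part
  of its definition.
* **GGC penalty `alpha`** (dimensionless, default 2): the standard
  clustering attenuation of the $S_p$ mass.
* **SIR `beta`** (probability per infected-neighbour contact per step,
  default `"auto"` = the epidemic-threshold estimate
  $\beta_c \approx \langle k\rangle/(\langle k^2\rangle - \langle k\rangle)$)
  and **`lambda`** (recovery probability per step, default 1: one
  transmission round per infected node).
* **`runs`** (default 1000 replicates per seed node): the convention used
  throughout for spreading-capacity estimation.

## Numerical and procedural conventions

Several definitions admit more than one reading; the package fixes these
once:

* **K-shell bookkeeping.** A peeling "pass" removes *simultaneously* all
  nodes of residual degree $\le k$; $p(i)$ is the 1-based pass at which
  $i$ fell, $q(k)$ the number of passes of shell $k$, and the refined
  index $k_s^* = k_s + p/(q+1)$ lies in $[k_s, k_s+1)$. Isolated nodes
  take shell 0, matching the usual coreness convention.
* **Local clustering for degree $\le 1$** is 0 (the defining ratio is
  0/0); this also makes $S_p = k$ for leaves.
* **Constraint for degree-0 nodes** is 1 by convention (their gravity
  score is 0 regardless); on unweighted graphs the proportional tie
  strength reduces exactly to $p_{ij} = 1/k(i)$, which the implementation
  uses directly (the raw indicator-based definition is kept as a test
  oracle).
* **SEGM's importance $I(j)$** is evaluated globally at $j$ (denominator
  over $j$'s own neighbourhood), the literal reading, rather than
  renormalised within the focal node's neighbourhood.
* **Eigenvector centrality** is computed by power iteration on $A + I$
  from a uniform positive start, with unit-sum normalisation and a
  max-norm stopping rule (`tol = 1e-12`). The identity shift leaves the
  eigenvectors unchanged and guarantees convergence on bipartite graphs,
  where iteration on $A$ alone oscillates. On disconnected graphs the mass
  concentrates on the dominant component — acceptable here because the
  vector only enters MCGM through the ratio $x/x_{\max}$.
* **MCGM's mixing weight** uses `stats::median` (midpoint of the two
  central order statistics for even $N$).
* **Kendall's tau** defaults to the literal tied-pairs-dropped form: pairs
  tied in either list count to neither $n_+$ nor $n_-$ while the
  denominator stays $N(N-1)/2$ pairs. Consequence worth knowing: a
  self-comparison of a ranking *with ties* scores below 1 (42/45 for the
  ten-node example's HVGC, whose three leaves tie exactly). The
  tie-adjusted tau-b is always reported alongside.
* **Top-k tie-breaking** is deterministic by node input order (`R`'s
  stable sort); `ties = "all"` instead admits every node tied with the
  k-th score, enlarging the sets.
* **Mean distance on disconnected graphs** averages over reachable pairs
  only and reports the excluded pair count; KSGC's coupling degenerates to
  1 (with a message) when all shells coincide; degenerate inputs
  (empty edge lists, unknown nodes, $R < 1$, $\beta \notin [0,1]$) raise
  errors rather than guessing.
* **Exact ties propagate.** No jitter is ever added; symmetric nodes
  receive bit-identical scores.

## The SIR simulator

Discrete-time synchronous dynamics: at each step every infected node
attempts to infect each currently susceptible neighbour independently with
probability $\beta$ (a node attacked by $c$ infected neighbours escapes
with $(1-\beta)^c$), then the *pre-step* infected set recovers with
probability $\lambda$. Newly infected nodes start transmitting the next
step. With $\lambda = 1$ an epidemic on $N$ nodes lasts at most $N$ steps.
Spreading capacity is $F(i) = \langle N_r \rangle / N$ over replicates
seeded at $i$.

Each (node, replicate) pair seeds its own RNG substream derived
arithmetically from the base seed, so estimates are independent of loop
order and reproducible node-by-node.

The recovery schedule (recovery after the same step's infection attempts)
is the standard reading of "each infected node recovers with probability
$\lambda$"; with $\lambda = 1$ it gives every infected node exactly one
transmission round, which is what makes the $\beta = 1$ limit reach the
whole component.

On the packaged ten-node network the simulator's limiting behaviour is
exact ($F = 1/N$ at $\beta = 0$, $F = 1$ at $\beta = 1$), and at
$\beta = 0.3$ — the infection probability implied by the fixture's
reference capacities (e.g. $F(5) \approx 0.33$) — the simulated ranking
reproduces the reference ordering up to pairs whose true capacities differ
by less than Monte-Carlo resolution at 1000 replicates (nodes 3 vs 9, and
node 10 vs the three symmetric leaves). Exactly *at* the threshold
$\beta_c = 0.48$ the dynamics genuinely rank node 9 above node 3, so
concordance with HVGC is slightly lower there; the test suite records both
behaviours.

## What the synthetic generators do and do not show

`synthetic_graph()` provides Erdős–Rényi, Barabási–Albert,
Watts–Strogatz, and a planted two-block community generator whose bridge
nodes attach by a single edge to each dense block. These exercise the
regimes the methods care about — homogeneous baselines, heavy-tailed
degrees, high clustering, and community bridges (a degree-2 bridge lands
in the minimum shell of the graph with the zero-redundancy constraint
value 0.5, the configuration where HVGC and shell-based methods disagree).
They do *not* emulate degree–degree correlations, core–periphery layering,
or the sizes of real social networks, so passing property tests on them
shows correctness of the computations, not ranking superiority on real
data. The edge-list reader accepts any external network for that purpose.

## Problem sizes in the test suite

The suite checks every gravity model against an untruncated all-pairs
double-loop oracle on 100 random graphs of 10–30 nodes (agreement to
relative error $10^{-12}$), the k-shell peeling against independent
coreness on 120 random graphs, and the worked example at full precision;
SIR checks use 20–10,000 replicates depending on how sharp the asserted
expectation is. These sizes keep the whole suite under a minute while
leaving every assertion statistically comfortable.

## Known limitations

* Weighted and directed graphs are out of scope; masses and distances
  assume simple undirected topology.
* The truncation-radius heuristic is exactly that — on networks whose
  mean distance is large (e.g. grid-like infrastructure graphs) the
  empirically best radius can differ from $\langle d \rangle / 2$, and
  users should sweep `radius` explicitly.
* HVGC weighs HV mass and the constraint coupling equally; no tunable
  trade-off between them is exposed.
* The all-pairs distance matrix makes `gravity_sum()` $O(N^2)$ in memory;
  fine into the tens of thousands of nodes, not for web-scale graphs.
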