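---
title: "Excitable SER dynamics on graphs: model, predictors and measurement"
author: "sergraph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitable SER dynamics on graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sergraph)
```

## The model

`sergraph` simulates a minimal discrete model of excitable dynamics on an
undirected simple graph. Each node is in one of three states — susceptible
(S), excited (E) or refractory (R) — and all nodes update synchronously:

* **S → E** when at least $\kappa k_i$ of node $i$'s $k_i$ neighbours are
  excited. The parameter $\kappa \in (0, 1]$ is a *relative* excitation
  threshold: a node of degree $k$ needs $n = \lceil \kappa k \rceil$
  simultaneously excited neighbours, so high-degree nodes are *harder* to
  excite. We call $n$ the node's **barrier strength**. There are no
  spontaneous excitations.
* **E → R** always (one time step of activity).
* **R → S** with recovery probability $p \in (0, 1]$ per step, giving
  geometrically distributed refractory times with mean $1/p$. At $p = 1$
  the dynamics is fully deterministic.

The natural control parameter is $1/\kappa$: it is the largest degree a node
can have and still be excited by a *single* excited neighbour, so the
transition values of the dynamics can be read directly as degrees.

## The numerical experiment

All nodes start susceptible; a single input node is excited at $t = 0$. The
nodes are organised in **layers** by BFS distance from the input (no edge
can skip a layer), and an **output node** is drawn from the farthest layer.
We record the excitations accumulated at the output node during $T$ steps
(default $T = 300$, long enough that transients average out). Swept over a
grid of $1/\kappa$, the accumulated count traces a response curve with
three generic features:

* **point A**, the onset of propagation $1/\kappa_c$ — below it every
  input-to-output path contains a barrier and the count is 0;
* **point B**, the limit of self-sustained activity $1/\kappa_m$ — above it
  every node relays a single excitation, the signal crosses the layers once
  as a coherent front (each excited layer trailed by a refractory one), and
  the count is exactly 1 regardless of $T$;
* **level C**, the plateau between the two, where reentrant excitation of
  topological cycles keeps re-exciting the output node.

```{r response-curve}
g <- graph_er(80, 320, seed = 42)
lv <- layered_view(g, 1)
out <- select_output_node(lv, seed = 1)
rc <- response_curve(g, 1, out, inv_kappa = 1:50, p = 0.5, tmax = 40,
                     n_runs = 30, seed = 77)
head(merge(rc$mean, rc$deterministic), 12)
```

## Topological predictors of the two transitions

For the onset, the package computes the **minimax-path (bottleneck) degree**

$$k^\* = \min_{\text{paths input} \to \text{output}} \;
  \max_{v \in \text{path}} k_v ,$$

the largest degree on the easiest path, with a bottleneck variant of
Dijkstra's algorithm (never by path enumeration). The input node's own
degree is excluded — it is excited externally — while the output node's
degree is included, since the output must pass its own barrier; this
endpoint convention is fixed and the brute-force oracles in the test suite
use the same one. $k^{**}$ refines it by minimising over all output-layer
nodes. Both are **upper bounds** on the measured $1/\kappa_c$: when two
path branches of equal length deliver simultaneous excitations, a barrier
of strength 2 falls earlier than the single-excitation argument predicts
(the `diamond` fixture is the minimal example). For the limit of sustained
activity, the predictors are $k_{max}$ (largest degree in the input's
component) and $k_{max,1}$ (largest degree in the first layer): a node of
degree $> 1/\kappa$ that the front fails to excite leaves a susceptible
*hole* behind the refractory wake through which activity can travel
upward and establish cycling excitations.

```{r predictors}
transition_report(g, 1, out, seed = 11)
```

## Measuring the transitions

Both transitions are measured by bisection on $1/\kappa \in [1, N]$ under
the deterministic dynamics ($p = 1$ — the transition points do not depend on
$p$, which the test suite verifies against 30-run stochastic searches at
$p = 0.5$). The onset indicator is "the output accumulates at least one
excitation", the limit indicator "at least two" (amplification versus
single-record propagation). Numerical conventions, fixed once:

* bisection stops when the bracket is narrower than 0.25 and the midpoint
  is rounded half-up to the nearest integer; the underlying boundaries are
  rationals $k/j$ (barrier strengths only change there), so with this
  bracket the rounding is unambiguous in practice;
* the indicator is assumed monotone in $1/\kappa$; the final bracket
  endpoints are re-verified by direct simulation, and on violation the
  search falls back to a linear scan over the integer grid (status
  `"linear_scan"`). Amplification windows confined strictly between
  integer grid points would be missed by the upward probe that brackets
  the limit search; we have not observed one;
* a component without cycles cannot re-excite any node (the front leaves
  only refractory nodes behind), so the limit search returns the sentinel
  `"none"` for forests without simulating;
* stochastic ($p < 1$) indicators report whether *any* of `n_runs`
  repetitions crosses the count threshold, following the observation that
  the deterministic dynamics delimits the possibility space of the
  stochastic one;
* threshold comparisons use $\ge \kappa k$ directly, with a $10^{-9}$
  guard inside the ceiling so that exactly attainable products (e.g.
  $k = 5$, $\kappa = 0.2$) land on the correct integer;
* isolated nodes are legal but inert: they can never be excited.

## Mean-field theory

Averaging over the graph gives the evolution
$c_E(t+1) = c_S(t)\,H[c_E(t) - \kappa]$ with $c_R = c_E / p$, whose active
fixed point $c_E^* = p/(2p+1)$ exists for $\kappa < p/(2p+1)$. The raw
synchronous map has slope $-(1 + 1/p)$ at that fixed point, so direct
iteration overshoots, crosses the Heaviside gate and collapses to
extinction from generic starting densities; `iterate_meanfield_map()`
therefore applies damped (relaxation $1/(2+1/p)$) iteration as the
numerical cross-check, and the tests additionally verify the closed form is
exactly invariant under the undamped map.

A barrier of degree $k$ and strength $n = \lceil \kappa k \rceil \ge 2$ is
passed when at least $n$ neighbours are simultaneously excited. Treating
neighbours as independently excited with probability $c_E^*$ (the
mean-field closure) gives the binomial tail $P(\mathrm{Bin}(k, c_E^*) \ge
n)$; averaged over the degree distribution and summed over $n \ge 2$ this
is the multiple-excitation probability $P_m$, and $1 - P_m$ tracks the
reliability of the single-excitation predictor $k^\*$. Two interpretation
choices were open and are fixed as follows: the per-barrier probability is
a *tail* ($\ge n$), not a point mass — passing a strength-$n$ barrier
needs at least $n$ concurrent excitations — with the point-mass variant
available behind `tail = FALSE`; and the package's prediction-confidence
curve evaluates $P_m$ per trial at $\kappa = 1/k^\*$, the point where the
prediction is actually stressed (configurable via `multiple_excitation_probability()`
directly). In *front* mode only the $k^{in}$ links arriving from the
upper layer count; $\rho(k^{in}|k)$ has no closed form and is estimated
empirically from the layered view (`kin_distribution()`).

Finally, in the saturated regime the output node is re-excited by cycling
activity with mean period $2 + 1/p$ (one excited step, a mean $1/p$
refractory steps, one step to be re-excited), giving the capacity

$$a_{max} = \frac{T}{2 + 1/p},$$

equal to 100 for $T = 300$, $p = 1$. For $p < 1$ stochastic recovery can
occasionally beat the mean period, so simulated levels sit slightly
*above* $a_{max}$; for small $p$ the approximation degrades and $a_{max}$
is only an upper bound.

```{r amax}
a_max(1, 300)
saturation_level(3, n = 80, m_edges = 640, p = 1, tmax = 300,
                 grid = 1:50, seed = 61)$level
```

## Graph generation and its conventions

* **ER**: $G(N, M)$ uniform over simple graphs (via igraph). Graphs are
  *not* forced to be connected — the experiments operate on the input
  node's component and flag disconnection — unless `require_connected =
  TRUE` is requested for clean ensemble scans.
* **BA**: the construction is pinned to one convention so edge counts are
  deterministic: a complete core of $m$ nodes, then $N - m$ nodes attached
  with $m$ degree-proportional edges each (without replacement), giving
  $M = \binom{m}{2} + m(N-m)$. Scans that target an edge count choose $m$
  with `ba_m_for_edges()` and record the realized $M$. At $N = 80$ the
  hub-to-mean degree ratio is about 2.4–3.3 for $m = 8$ and grows as $m$
  shrinks; the tests assert the heavy tail against an edge-matched ER
  ensemble rather than a fixed large ratio, which small graphs do not
  reliably attain.

All randomness (graph sampling, node choices, stochastic recovery) derives
from a single root seed via `derive_seeds()`; deterministic runs draw no
random numbers at all and are bit-reproducible regardless of seeding.

## Study conditions and problem sizes

The default experiment parameters are the study conditions throughout:
$N = 80$ nodes, $T = 300$ steps, grid $1/\kappa = 1..50$, 30 stochastic
runs, edge counts scanned across $M \approx 100..2000$. The heavier
ensemble statements are exercised at reduced but regime-preserving sizes
chosen once: 10–20 graphs for the dense-graph claims ($M = 640$ saturation,
$M = 1800$ limit prediction), about 400 (graph, input) trials for the
upper-bound property, and 10 realizations per $M$ on a step-150 grid with
all input nodes (about 10,000 trials) for the density trend of the onset
prediction quality.

## What the generators do and do not emulate

The synthetic ensembles reproduce the degree heterogeneity, layer
structure and cycle content that drive the phenomena: barriers, holes,
reentry. They are still small random graphs: no degree correlations,
community structure, or spatial embedding, and the small-$p$ kink in the
saturation level is a finite-size effect at $N = 80$. Conclusions verified
by the test suite are statements about these ensembles; on real networks
(e.g. cortical area graphs) the same machinery runs via the edge-list /
GraphML readers, but the prediction qualities need not transfer.

## Known limitations

* The limit-of-activity measurement operationalises "amplification" as an
  output count $\ge 2$ within $T$ at $p = 1$; pathological graphs whose
  amplified window lies strictly between integer thresholds and away from
  the probe points would be mis-bracketed.
* `prediction_quality()` excludes sentinel trials (no propagation, no
  amplification) from its denominator and reports them separately; with
  denominators defined to include them the dense-graph qualities would be
  marginally lower.
* The mean-field closure ignores neighbour-neighbour correlations; its
  known failure mode (overestimating activity at small $p$) is inherited
  by $a_{max}$ and $P_m$.
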