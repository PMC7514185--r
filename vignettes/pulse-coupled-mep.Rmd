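---
title: "From coupling structure to effective interactions in pulse-coupled networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From coupling structure to effective interactions in pulse-coupled networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepnet)
```

## The scientific question

Networks whose nodes are binary in each sampling time bin — a neuron either
fires in a 10 ms window or it does not — are commonly summarized by the
probability distribution of their joint states. For $n$ nodes there are
$2^n$ states, and the standard way to compress this distribution is a
maximum-entropy (Boltzmann-form) model

$$
P_m(V) \;=\; \frac{1}{Z}\exp\!\Big(\sum_{k=1}^{m}\;
\sum_{i_1<\dots<i_k} J_{i_1\cdots i_k}\,
\sigma_{i_1}\cdots\sigma_{i_k}\Big),
\qquad V=(\sigma_1,\dots,\sigma_n)\in\{0,1\}^n,
$$

whose coefficients $J_{i_1\cdots i_k}$ — the *effective interactions* of
order $k$ — are the Lagrange multipliers that enforce the moment
constraints $\langle\sigma_{i_1}\cdots\sigma_{i_k}\rangle$ up to order
$m$. Empirically, very few of these coefficients are distinguishable from
zero in recordings from real networks. This package implements, end to
end, an explanation of that sparseness: **which effective interactions can
be non-zero is determined by the anatomical coupling graph**, provided the
external input of each node is independent of the others'.

The structural criterion is simple. Write $C(i)$ for the set of child
nodes of $i$ (nodes receiving a connection from $i$) and
$U_i = C(i)\cup\{i\}$. If two nodes $i,j$ are neither connected (in either
direction) nor share a common child — that is, $U_i\cap U_j=\emptyset$ —
then they are conditionally independent given the state of all other
nodes, and *every* effective interaction whose index set contains both $i$
and $j$ vanishes exactly. Consequently the subsets that can carry non-zero
interactions are exactly the **cliques of the dependency graph** that
links every pair with $U_i\cap U_j\neq\emptyset$.

## The pipeline

The package decomposes into six cooperating parts:

1. **Simulator** (`simulate_ifnet()`): conductance-based integrate-and-fire
   dynamics on a directed `coupling_graph`.
2. **Binning** (`binarize()`, `empirical_distribution()`, `moments()`,
   `shuffle_raster()`): spike trains to binary rasters to state
   distributions, plus surrogate data.
3. **Exact inversion** (`full_order_interactions()`,
   `recursive_interaction()`, `basic_form()`, `mep_distribution()`,
   `fit_low_order()`): effective interactions from distributions and back.
4. **Conditional-independence testing** (`delta()`, `delta_profile()`,
   `shuffle_null()`, `classify_pairs()`).
5. **Structure prediction** (`dependency_graph()`,
   `count_nonzero_orders()`, `sparseness()`, `er_experiment()`).
6. **Fixture generators** (`ring4_network()`, `product_distribution()`,
   `known_interaction_distribution()`,
   `markov_factorized_distribution()`, `sample_raster()`).

## The integrate-and-fire model

Each node carries a state variable $x_i$ (a dimensionless membrane
voltage) obeying

$$
\dot x_i \;=\; -\frac{x_i}{\tau}
\;-\;\big(g_i^{\mathrm{bg}}+g_i^{\mathrm{ex}}\big)\,(x_i-x_{\mathrm{ex}})
\;-\;g_i^{\mathrm{in}}\,(x_i-x_{\mathrm{in}}),
$$

where every conductance is a sum of kernels
$H(t-T)\,e^{-(t-T)/\sigma}$ over its input event times $T$: background
arrivals (a homogeneous Poisson process of rate $\mu$, each contributing a
jump $f$ with decay $\sigma_{\mathrm{ex}}$) and recurrent spikes from
excitatory/inhibitory parents (jumps $S^{\mathrm{ex}}_{ij}$,
$S^{\mathrm{in}}_{ij}$ with decays $\sigma_{\mathrm{ex}}$,
$\sigma_{\mathrm{in}}$). When $x_i$ reaches the threshold
$x_{\mathrm{th}}$ the node emits a spike, is reset to $x_r$, and is held
there for an absolute refractory period $\tau_{\mathrm{ref}}$. The
conductance form confines the voltage to
$[x_{\mathrm{in}}, x_{\mathrm{ex}}]$; `check_bounds = TRUE` asserts this
during integration.

Default parameters (the reference set used by all fixtures, in
`if_params()`): $\tau = 20$ ms, $x_{\mathrm{ex}} = 14/3$,
$x_{\mathrm{in}} = -2/3$, $\sigma_{\mathrm{ex}} = 2$ ms,
$\sigma_{\mathrm{in}} = 5$ ms, $x_{\mathrm{th}} = 1$, $x_r = 0$,
$\tau_{\mathrm{ref}} = 2$ ms, $\mu = 0.1\,\mathrm{ms}^{-1}$, $f = 0.1$,
integration step $dt = 0.1$ ms.

Numerical choices, in detail:

* **Integration.** Midpoint (second-order) Runge–Kutta on sub-intervals
  delimited by input events, never longer than $dt$. Conductance decay is
  applied analytically (exact exponentials), so only the voltage is
  integrated numerically. Halving $dt$ twice changes ring firing rates by
  $<0.1\%$, and the constant-drive firing period matches the closed-form
  solution of the resulting linear ODE to $10^{-5}$ relative error.
* **Threshold crossing.** Located by linear interpolation inside the
  sub-interval where the voltage first meets $x_{\mathrm{th}}$.
* **Event ordering.** Spikes generated inside a step are delivered to
  child nodes immediately after the step; simultaneous deliveries are
  processed in ascending node index. There are no synaptic delays.
* **Background streams.** One deterministic RNG stream per node, keyed by
  `(seed, node)`, so two networks that differ only in coupling see
  identical background realizations. Identical
  `(graph, params, duration, seed)` reproduce spike trains bit-for-bit.
* **Initial condition.** All voltages start at $x_r$; a 1000 ms transient
  is simulated and discarded before recording, since all downstream
  analysis assumes an equilibrium state.
* **Units of `f`.** The background magnitude is implemented as a
  dimensionless conductance jump of 0.1 per arrival. (Conductances here
  carry units of inverse time because the capacitance is normalized to
  one, so a printed value of "0.1 ms$^{-1}$" for a jump magnitude is the
  same number.)

With the reference parameters the simulator produces per-node equilibrium
rates of about 39–45 Hz on the ring fixture (mean $\approx 42$ Hz; nodes
receiving recurrent inhibition sit at the lower end). A useful closed-form
anchor: with the background clamped at a constant conductance $g$, the
single-node period is
$\tau_{\mathrm{eff}}\log\frac{x_\infty-x_r}{x_\infty-x_{\mathrm{th}}}
+\tau_{\mathrm{ref}}$ with
$\tau_{\mathrm{eff}} = (1/\tau+g)^{-1}$ and
$x_\infty = g\,x_{\mathrm{ex}}\tau_{\mathrm{eff}}$ — for $g = 0.02$ (the
mean background conductance $f\mu\sigma_{\mathrm{ex}}$) that is 21.8 ms,
i.e. 45.9 Hz; Poisson fluctuations lower this to the observed $\approx
41.6$ Hz for an uncoupled node. Had the voltage been allowed to integrate
through the refractory period instead of being clamped, the deterministic
period would be 19.8 ms ($\approx 50$ Hz); we clamp, as the model
specifies.

## Exact effective interactions

For the full order $m = n$ the unique maximum-entropy solution is the
observed distribution itself, and taking logarithms of the Boltzmann form
yields a triangular linear system over the subset lattice. Its solution is
the Möbius inversion

$$
J_A \;=\; \sum_{B\subseteq A} (-1)^{|A|-|B|}\,\log P(V_B),
\qquad \log Z = -\log P(0\cdots0),
$$

where $V_B$ activates exactly the nodes in $B$. `full_order_interactions()`
computes this with a fast zeta/Möbius transform in $O(n2^n)$;
`mep_distribution()` is the inverse (via log-sum-exp, so it cannot
overflow), and the round trip is the identity to $10^{-9}$ or better.

`recursive_interaction()` implements the same coefficients by a second,
independent route — the conditional log-odds recursion
$J_{1\cdots(k+1)} = J_{1\cdots k}^{(k+1\ \text{active})} - J_{1\cdots k}$
starting from $J_i = \log\frac{P(\sigma_i=1,\ \text{rest }0)}{P(0\cdots0)}$
— and the two routes are required to agree on every subset in the test
suite. The recursion also exposes why structure forces zeros: every $J_A$
with $\{i,j\}\subseteq A$ is a signed sum of *basic-form* terms
(`basic_form()`), differences of conditional log-odds of $i$ between
$\sigma_j=1$ and $\sigma_j=0$, which vanish identically when $i$ and $j$
are conditionally independent given the rest.

**Zero-probability states.** The inversion needs $P(V)>0$ for all $2^n$
states. An unsampled state is a hard error by default, naming the state —
silently regularizing changes the coefficients materially. An explicit
Laplace pseudocount (`pseudocount = alpha` spreads `alpha` occupancy
uniformly) is available and recorded in the result's metadata. The
analyses in this package use recordings long enough that all 16 states of
the 4-node fixtures are well sampled, so the default is never relaxed
silently.

**Low-order fits.** `fit_low_order()` solves the $m<n$ problem by
classical iterative proportional fitting: starting from the uniform
distribution, cycle through constrained subsets in subset-size order and
rescale the states containing each subset so its moment matches exactly
(each one-constraint update has the closed-form factor
$r = t(1-S)/[(1-t)S]$; no damping is needed). Convergence is declared
when the worst moment residual falls below `tol` (default $10^{-10}$).
With $m=1$ this reproduces the product of marginals after one sweep; with
$m=n$ it converges to the observed distribution; entropy decreases
monotonically as constraint order grows.

## Testing conditional independence in data

For a node pair $(i,j)$ and a state $H$ of the remaining $n-2$ nodes,

$$
\Delta_{ij}(H) \;=\;
\big|\,P(\sigma_i{=}1\mid\sigma_j{=}1,H)-P(\sigma_i{=}1\mid\sigma_j{=}0,H)\,\big|
$$

is zero for every $H$ exactly when the pair is conditionally independent.
Empirically $\Delta$ is never exactly zero, and no absolute cutoff is
defensible, so the package uses the null the field uses: **shuffled
surrogates**. `shuffle_raster()` permutes each node's bin sequence
independently and uniformly, preserving per-node totals (hence all first
moments) exactly while destroying cross-node correlations.
`shuffle_null()` repeats this `n_shuffles` times (default 10), recomputes
every statistic per surrogate, and reports the min–max envelope (all
shuffle values, matching how such nulls are plotted) together with
mean ± sd of both signed and absolute values, since either summary is in
use. A statistic is "consistent with zero" when it lies inside its own
envelope. Undefined $\Delta_{ij}(H)$ — an unsampled conditioning state —
is reported as missing, never as zero.

On 4-node ring simulations of $10^6$ ms (our standard problem size; a
full-scale run would be $>100\times$ longer), the observed max-over-$H$
$\Delta$ of the structurally independent pairs $\{1,3\}$ and $\{2,4\}$
falls inside the 10-shuffle envelope while all four adjacent pairs exceed
theirs by a factor of 2–4; likewise $|J_{13}|$, $|J_{24}|$ and every
third- and fourth-order $|J|$ sit inside their bands while the
adjacent-pair coefficients exceed them. Because the envelope is a max of
10 draws, a single null-distributed statistic still exceeds it about once
in eleven tries; the test suite therefore requires each statistic to fall
on the predicted side in at least 8 of 10 independent simulation seeds
rather than demanding joint success of all statistics at once.

## From anatomy to counting

`dependency_graph()` builds the undirected graph of potentially dependent
pairs ($U_i\cap U_j\neq\emptyset$); node sign is irrelevant here, and
"connected" means connected in either direction (a one-way edge
$i\to j$ already puts $j\in U_i$). `count_nonzero_orders()` counts the
cliques of this graph per size by exact depth-bounded recursive expansion
in a fixed vertex order (each clique extended only by higher-indexed
common neighbours, so every clique is visited exactly once), guarded by a
node-expansion budget that turns pathologically dense inputs into an
error rather than a hang. The counts are validated against an exhaustive
$2^n$ subset scan for $n\le 12$ and against an independent library
enumeration. `sparseness()` is the ratio of all predicted non-zero
interactions (orders $1$ through $n$ — every first-order coefficient is
generically non-zero; the constant $Z$ term is not counted) to $2^n$.

`er_experiment()` runs the ensemble version: directed Erdős–Rényi graphs
($n=100$, $p=0.05$ by default; each ordered pair connected when a uniform
draw falls below $p$), one dependency graph and clique count each, means
and standard deviations per order. With the default 20 networks (ensemble
size is an argument; 20 gives sub-second runtimes and standard errors far
below the effect being demonstrated) the per-order counts peak around
order 4–5 at roughly $10^4$, fall to essentially zero above order 11, and
the mean sparseness is $\approx 3.7\times10^{-26}$ — more than 24 orders
of magnitude below the $2^{100}$ possible interactions, which is the
quantitative sense in which a sparse coupling structure forces a sparse
coding by effective interactions. The per-pair dependency probability has
the closed form $1-(1-p)^2(1-p^2)^{n-2}\approx0.294$, a useful analytic
cross-check on the ensemble.

## What the fixtures do and do not emulate

* `ring4_network()` is the canonical demonstration: a directed 4-cycle
  with alternating excitatory/inhibitory signs, strengths 0.02, reference
  parameters. Its independent pairs $\{1,3\}$, $\{2,4\}$ follow from the
  ring topology alone and are invariant to orientation and to the sign
  assignment (which specific nodes are inhibitory is an assumption of the
  fixture, documented as such).
* `chain4_network()` is a second 4-node wiring whose *only* independent
  pair is $\{1,3\}$; its exact published counterpart is not fully
  recoverable, so the edge set is a configurable, documented guess.
* `markov_factorized_distribution()` draws a pairwise Markov random field
  on a given dependency graph: a positive distribution realizing exactly
  the conditional independences the graph predicts, used to verify the
  vanishing law ($|J_A|<10^{-8}$ for every non-clique $A$) without any
  simulation noise.
* `product_distribution()` and `known_interaction_distribution()` provide
  the independence null and exact ground truth for recovery tests.

Synthetic fixtures share the statistical structure the analysis assumes —
independent background inputs, equilibrium sampling, binary states — but
not the nuisances of real recordings: non-stationarity, correlated common
input (which can genuinely induce non-zero high-order interactions and is
out of scope here), electrode artifacts, or unobserved nodes. Passing
tests therefore demonstrate correctness of the machinery and internal
consistency of the theory, not robustness to those nuisances.

The structural prediction is an **upper bound** on the non-zero set:
dynamics can make a clique's coefficient small as well (for instance, a
mixed-sign triple whose excitatory and inhibitory influences nearly
cancel), so an interaction predicted "potentially non-zero" may still be
indistinguishable from its shuffle band in data. The converse direction —
predicted-zero coefficients staying inside the band — is the claim the
tests exercise.

## Problem sizes and runtime

Exact inversion and the forward model enumerate $2^n$ states and are
capped at $n=20$ by default (`n_cap`). Simulation scales linearly in
duration and event count: the $10^6$ ms ring run takes a few seconds. The
suite's reduced recording length trades statistical resolution of
high-order coefficients for runtime; the qualitative separation between
dependent and independent pairs is already unambiguous at this length,
while the absolute coefficient magnitudes of the full-length experiment
are not reproduced here and are not asserted anywhere.

## Known limitations

* No Monte-Carlo or pseudolikelihood fitting for large $n$: every exact
  routine enumerates $2^n$ states. Structure prediction, by contrast,
  scales to hundreds of nodes since it only counts cliques.
* The shuffle null destroys *all* cross-node correlation, so the
  sampling variability of high-order coefficient estimates under the null
  can differ slightly from that of the observed (correlated) data; the
  per-statistic 8-of-10 aggregation above absorbs this.
* Delays, plasticity, non-exponential kernels and correlated external
  inputs are out of scope by design.
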