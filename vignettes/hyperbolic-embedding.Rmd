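---
title: "Hyperbolic embedding of complex networks: models, likelihoods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperbolic embedding of complex networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperembed)
```

## The model

Scale-free, strongly clustered networks admit a geometric description on
the hyperbolic plane of curvature $K=-1$, represented natively as a
Euclidean disc in which a node's radial coordinate equals its hyperbolic
distance from the origin and angular separations are conformal. Radius
encodes *popularity* (degree), angle encodes *similarity*. The distance
between nodes $s,t$ is, to a very good approximation away from co-angular
pairs,

$$x_{st} = r_s + r_t + 2\ln(\theta_{st}/2),$$

with $\theta_{st}$ the shorter angular arc. `hyperbolic_distance()` offers
both this form and the exact law of cosines
$\operatorname{acosh}(\cosh r_s\cosh r_t-\sinh r_s\sinh r_t\cos\theta_{st})$,
which we evaluate through the cancellation-free rearrangement
$\cosh d = \cosh(r_s-r_t) + \sinh r_s \sinh r_t\,(1-\cos\theta_{st})$
(the naive form loses up to $\sim\!10^{-3}$ absolute accuracy at $r \ge 12$
because $\cosh^2 r - \sinh^2 r$ cancels catastrophically). For co-angular
pairs the approximate form diverges; we return the true value
$|r_s - r_t|$, which keeps likelihoods and routing finite.

### The popularity–similarity growth process

`sample_ps(n, m, gamma, temp, seed)` grows a network: node $t$ appears at
$r_t = 2\ln t$ with a uniform angle; every older node fades outward to
$r_s(t) = \beta r_s + (1-\beta) r_t$ with $\beta = 1/(\gamma-1)$; the
newcomer links to $m$ existing nodes with the Fermi probability
$p(x) = 1/(1+e^{(x - R_t)/(2T)})$, where $R_t$ is the current disc radius
(`disc_radius()`, with dedicated $T\to 0$ and $\beta = 1$ branches). The
temperature $T\in[0,1)$ tunes clustering: $T=0$ gives deterministic,
maximally clustered attachment; clustering decays roughly linearly to zero
as $T\to 1$.

Implementation choices:

* **Cold regime.** At $T = 0$ the Fermi function is a step, and "link with
  probability $p$" reduces to "link to the $m$ hyperbolically nearest
  predecessors". We implement that limit directly rather than rejection
  sampling a step function, which would loop forever on ties at the
  boundary.
* **Warm regime.** Links are drawn by rejection sampling over uniformly
  chosen non-neighbours. Attempts are capped at $100\,t$ per newcomer;
  on exhaustion we fall back to weighted sampling without replacement by
  acceptance probability. The cap is effectively never reached at the
  temperatures studied (expected attempts are $\mathcal{O}(t)$).
* **Fractional $m$.** Real networks have non-integer average degree
  (e.g. $2m = 12.22$); each newcomer draws
  $m_t = \lfloor m\rfloor + \mathrm{Bernoulli}(m-\lfloor m\rfloor)$,
  preserving the mean with integer link counts.
* **Lazy fading.** The fading rule applied to birth radii gives the closed
  form $r_s(t) = 2\beta\ln s + 2(1-\beta)\ln t$; we evaluate it on demand
  instead of updating all radii at every step. Reported coordinates are
  the final values at time $N$.
* Early newcomers with fewer than $m_t$ predecessors connect to all of
  them; the growth loop is compiled (Rcpp), making $N \sim 10^4$ networks
  a matter of seconds.

## LaBNE: the spectral draft

For a connected simple graph with adjacency $A$, degree matrix $D$ and
Laplacian $L = D - A$, minimising
$\tfrac12\sum_{ij}A_{ij}\lVert Y_i - Y_j\rVert^2 = \mathrm{tr}(Y^TLY)$
subject to $Y^TDY = I$ is solved by the two generalized eigenvectors of
$L y = \lambda D y$ with the smallest non-zero eigenvalues. Angles are
$\theta_i = \operatorname{atan2}(y_{2i}, y_{1i})$; radii come from the
degree ranking, $r_i = 2\beta\ln i + 2(1-\beta)\ln N$ (rank 1 = highest
degree); finally the angles are re-spread uniformly on $[0, 2\pi)$ in
their inferred circular order, which removes the angular crowding typical
of raw spectral coordinates.

Numerics: the problem is whitened to the symmetric
$D^{-1/2}LD^{-1/2}z=\lambda z$. Up to 2000 nodes we take the dense
symmetric eigendecomposition (exact, trivially robust to the multiple
eigenvalues of highly symmetric graphs); beyond that a block inverse-power
iteration on the sparse whitened Laplacian is used, with a Cholesky
factorisation of the shifted matrix and deflation of the known constant
mode $D^{1/2}\mathbf{1}$. Both routes are tested against a brute-force
solver of the non-symmetric pencil $D^{-1}L$ to $10^{-8}$ per eigenvalue.
The trivial mode is excluded by the relative threshold
$10^{-10}\max_i k_i$. Eigenvector signs are fixed so vertex 1 has a
non-negative entry; degree ties are ranked by ascending vertex index. Both
conventions are arbitrary but deterministic — embeddings are in any case
only defined up to rotation and reflection, and all accuracy checks in the
test suite score over the best global rotation/reflection.

## HyperMap: likelihood refinement by replaying growth

`hypermap_embed()` sorts nodes by decreasing degree, relabels them
$i = 1,\dots,N$, and replays hyperbolic growth: node $i$ is born at
$r_i = 2\ln i$, older nodes fade, and $\theta_i$ is chosen to maximise a
model likelihood over a candidate grid of spacing $\Delta\theta = 1/i$
(finer for later, lower-degree nodes).

**Link likelihood** (low-degree nodes): the Bernoulli likelihood
$\sum_{j<i} \alpha_{ij}\ln p(x_{ij}) + (1-\alpha_{ij})\ln(1-p(x_{ij}))$
with replay-time radii and disc radius, $p$ clamped to
$[10^{-12}, 1-10^{-12}]$. Candidates are searched in a local region
(default $\pm\pi/6$) around an initial estimate obtained by grid-searching
the likelihood restricted to the already-placed *neighbours* only — cheap,
since it involves $\mathcal{O}(\text{degree})$ terms per candidate.

**Common-neighbours likelihood** (nodes with degree $\ge k_{speedup}$,
default 10): a Gaussian likelihood of the *final* common-neighbour counts
$n_{ij}$,
$$\ln\mathcal{L} = (i-1)\ln\tfrac{1}{\sqrt{2\pi}}
  - \sum_{j<i}\ln\sigma_{ij} - \sum_{j<i}\frac{(n_{ij}-\mu_{ij})^2}{2\sigma^2_{ij}},$$
treating common neighbourship through each third node $k$ as an
independent Bernoulli event, so $\mu = \sum_k q_k$ and
$\sigma^2 = \sum_k q_k(1-q_k)$, floored at $10^{-6}$.

Because the observed $n_{ij}$ are counted in the final network, $\mu$ and
$\sigma^2$ must be evaluated in the **final configuration** (final radii,
final disc radius), and — crucially — nodes not yet placed in the replay
must contribute: the common neighbours of two hubs are mostly low-degree
nodes that are placed much later. For placed $k$ we use the exact product
$q_k = p(x_{ik})p(x_{jk})$. For unplaced $k$ (radius known, angle unknown)
we take the expectation over a uniform angle. With the approximate
distance, the Fermi probability towards a node at radius $r$ becomes
$p(\Delta\theta) = 1/(1 + (\Delta\theta/(a b_k))^{1/T})$ with
$a = 2e^{(R_N-r)/2}$ and $b_k = e^{-r_k/2}$, whose total angular mass is
$I = 2ab_k\,\pi T/\sin(\pi T)$. The expectation of the product of two such
profiles peaked at $\theta_i$ and $\theta_j$ is approximated by the
two-peak form
$$\mathbb{E}[p_{ik}p_{jk}] \approx
  \frac{p_{jk}(\Delta\theta_{ij})\,I_{ik} + p_{ik}(\Delta\theta_{ij})\,I_{jk}}{2\pi},$$
capped by $\min(I_{ik}, I_{jk})/(2\pi)$ and 1 (each factor evaluates the
opposite profile at the peak of the other; exact in the
well-separated-peaks limit). This closed form costs one `pow` per
node-candidate pair and makes the likelihood sensitive to
$\Delta\theta_{ij}$ from the very first placements. During development we
verified that omitting the unplaced-node term leaves early hub placements
essentially unconstrained and makes full HyperMap *less* navigable than
its own spectral draft, inverting the expected ordering of the methods;
with the term included, full HyperMap reaches 83–87% greedy-routing
success on $\gamma=2.5$, $T=0.9$ benchmarks (the test suite asserts the
qualitative orderings, and `scripts/acceptance.R` recomputes the
quantitative ones).

Ties in the grid search are broken towards the candidate closest to the
centre/initial angle, then towards the smaller angle — determinism again.
Correction-step post-processing of the original method is intentionally
not implemented (its effect is reported to be insignificant for the fast
hybrid variant). $T=0$ is rejected: the growth likelihood degenerates, so
cold networks are refined at a small positive working temperature (see
below).

## LaBNE+HM

`labne_hm_embed()` runs LaBNE, hands the draft angles to HyperMap, and
restricts *every* node's candidate search to a window $w$ around its draft
angle. $w$ trades accuracy for speed: near 0 the result is LaBNE, near
$2\pi$ it is full HyperMap. Windows can be set manually (the benchmark
analyses use $\pi/36$, $\pi/6$, $\pi/4$, $\pi/3$ for $T = 0, 0.3, 0.6,
0.9$) or by the `linear` ($w = 2\pi T$) / `quadratic` ($w = 2\pi T^2$)
policies, floored at $\pi/36$ so cold networks still probe a minimal
window. For $T = 0$ inputs the refinement stage runs at a working
temperature of $0.1$ — some positive temperature is required by the
likelihood, and a small value keeps the step-like geometry — while window
selection still uses the input temperature. The draft coordinates are
retained in the result (`$draft`) for diagnostics, and the per-node
refined log-likelihood provably never falls below the draft-angle
log-likelihood under the same conditioning (asserted in the tests).

## Evaluation

* **Greedy routing** (`greedy_route()`, `routing_report()`): each node
  forwards the packet to its neighbour hyperbolically closest to the
  target; delivery fails the moment a node would return the packet to the
  immediately previous hop (the loop rule — not a TTL; an $N$-hop cap
  merely guards against longer cycles, which the loop rule makes
  practically unreachable). Source–target pairs are sampled uniformly with
  replacement. Hop stretch is greedy path length over BFS shortest-path
  length. Routing distances use the approximate formula with an exact
  fallback whenever the approximation would undercut the radial bound
  $|r_1 - r_2|$ (near-co-angular pairs). Next-hop distance ties go to the
  smaller vertex index.
* **Connection-probability curves**
  (`connection_probability_curve()`): all $N(N-1)/2$ pairs binned by
  inferred distance (default bin width 1); per bin, the fraction joined by
  an edge. Good embeddings show a near-Fermi decay.
* **Temperature estimation** (`estimate_temperature()`): clustering of PS
  networks decays approximately linearly from its cold value to 0 at
  $T=1$. We generate replicas at $T=0$ with the target's $(N, 2m, \gamma)$
  (default 10; 3 suffice for $N\gtrsim 10^4$, where the clustering
  coefficient concentrates), average their mean local clustering into
  $\bar c_0$, and read the temperature off the line through
  $(0, \bar c_0)$ and $(1, 0)$: $T = 1 - \bar c/\bar c_0$, clamped to
  $[0, 1)$. Nodes of degree $<2$ contribute zero clustering.
* **Power-law exponent** (`fit_power_law_exponent()`): continuous Hill
  estimator with the half-integer correction,
  $\hat\gamma = 1 + n_{tail}/\sum\ln(k_i/(k_{min}-\tfrac12))$, with
  $k_{min}$ minimising the KS distance between the empirical and fitted
  tails (at least 50 tail points required). It is cross-checked against an
  independent `plfit` implementation in the tests.

## What the simulator does and does not emulate

The PS generator reproduces the features the embedding methods rely on:
power-law degrees with $\gamma\in[2,3]$, temperature-tuned clustering,
small diameters, and — critically — a ground-truth geometry against which
angular recovery and navigability can be scored exactly. It does *not*
emulate degree correlations beyond those the model induces
(disassortativity; real assortative networks such as webs of trust route
poorly regardless of embedding), community structure, noisy or missing
edges, or non-uniform similarity distributions. Passing the simulated
benchmarks therefore demonstrates correctness of the inference machinery
under the model's own assumptions, not performance guarantees on any
particular real network.

## Problem sizes and determinism

The test suite and the reproduction script run on desk-scale instances
chosen to exercise every code path: toy graphs ($\le 15$ nodes) for exact
oracle comparisons, $N = 300$–$500$ for benchmark embeddings,
$N = 2000$ for exponent recovery, and $N \approx 1.1$–$1.4\times 10^4$
cold replicas (3 each) for the real-network temperature table. A full
LaBNE+HM embedding at $N = 500$ takes 1–3 s; full HyperMap roughly
$10\times$ longer. All randomness flows through explicit seeds; identical
seeds give bit-identical networks, embeddings, and routing reports.

## Known limitations

* $\gamma$ is a required input to the embedding functions (it only shifts
  radii); the helper estimator covers the common case but KS-based cutoff
  selection is itself noisy on small networks.
* The unplaced-node term of the common-neighbours likelihood is a
  closed-form approximation of an angular integral; it is exact in the
  well-separated-peaks limit and degrades gracefully, but it is not the
  integral itself.
* The iterative eigensolver assumes a modest spectral gap above the
  constant mode; graphs that are nearly disconnected converge slowly
  (the dense path is unaffected).
* Embeddings are identified only up to rotation and reflection of the
  disc; compare coordinates across runs with that in mind.
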