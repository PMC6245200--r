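# hyperembed

Complex networks — protein interactomes, webs of trust, airport networks —
behave as if their nodes lived in an underlying hyperbolic space: popular
(high-degree) nodes sit near the centre of a hyperbolic disc, similar nodes
sit at nearby angles, and the probability that two nodes are linked decays
with the hyperbolic distance between them. Recovering node coordinates in
that space ("embedding" the network) enables greedy navigation, link
prediction, and a read-out of each node's seniority from its radial
position.

`hyperembed` is an R toolkit for this inference problem on undirected,
unweighted, single-component, scale-free networks. It provides:

- **A popularity–similarity (PS) network simulator** with ground-truth
  coordinates. Node `t` is born at radius `r_t = 2 ln t` with a uniform
  angle; older nodes fade outward via `r_s(t) = β r_s + (1−β) r_t`,
  `β = 1/(γ−1)`; links attach with the Fermi probability
  `p(x) = 1 / (1 + exp((x − R_t)/(2T)))`, where `x` is the hyperbolic
  distance `x_st ≈ r_s + r_t + 2 ln(θ_st/2)` and `T` is the network
  temperature controlling clustering.
- **LaBNE** — Laplacian-based network embedding: angles from the two
  eigenvectors with smallest non-zero eigenvalues of the generalized
  problem `L y = λ D y`, radii from the degree ranking
  (`r_i = 2β ln i + 2(1−β) ln N`), plus uniform angular re-spreading.
  Very fast; a spectral *draft* of the geometry.
- **HyperMap** (fast hybrid version) — maximum-likelihood embedding that
  replays the network's hyperbolic growth in degree order and places each
  node at the angle maximising either a link-based Bernoulli likelihood or
  a Gaussian likelihood of final common-neighbour counts, on a candidate
  grid of spacing `1/i`. Accurate but slow.
- **LaBNE+HM** — the hybrid: LaBNE drafts, HyperMap refines each angle
  inside a window `w` around the draft (`w = π/36 … π/3` depending on
  temperature, or `w = 2πT`, `2πT²` policies).
- **An evaluation suite** — greedy routing with the loop-drop rule and hop
  stretch, distance-binned connection-probability curves, network
  temperature estimation from the clustering coefficient against cold PS
  replicas (`T = 1 − c̄/c̄₀`), and maximum-likelihood power-law exponent
  fitting with KS-chosen cutoff.

Everything is tidyverse-friendly: coordinate tables are tibbles,
`tidy()`/`glance()` methods summarise results, `autoplot()` draws
embeddings, routing histograms, and connection curves.

## Worked example

```r
library(hyperembed)

# a 500-node PS network, average degree 10, gamma = 2.5, T = 0.3
net <- sample_ps(500, m = 5, gamma = 2.5, temp = 0.3, seed = 1)
#> PS network: 500 nodes, 2485 edges (m = 5, gamma = 2.5, T = 0.3)

# hybrid embedding: spectral draft refined in a pi/6 window
emb <- labne_hm_embed(net$graph, gamma = 2.5, temp = 0.3,
                      policy = "manual", window = pi / 6, seed = 1)
glance(emb)
#> # A tibble: 1 × 7
#>   method       n gamma  temp window  loglik runtime
#> 1 labne_hm   500   2.5   0.3  0.524 -26581.    2.09

# how navigable is the inferred geometry?
routing_report(tidy(emb), net$graph, n_pairs = 1000, seed = 1)
#> Greedy routing: 888/1000 delivered (88.8%), mean hop stretch 1.097

# estimate the temperature back from the clustering coefficient
estimate_temperature(net$graph, gamma = 2.5, replicas = 5, seed = 1)
#> Temperature fit: T = 0.362 (clustering 0.498 vs 0.779 in 5 cold PS replicas)
```

The routing report says that 88.8% of packets reach their target when each
hop simply forwards to the neighbour hyperbolically closest to the target,
and that successful greedy paths are on average only 9.7% longer than
shortest paths — the inferred coordinates encode real routing information.
The temperature estimate (0.36) recovers the generating temperature (0.3)
to within the resolution of the clustering–temperature line.

A command-line front end wrapping the same functions lives in
`inst/cli/hyperembed.R` (subcommands `generate`, `embed`, `route`, `curve`,
`estimate-temp`).

## Notes

- Methods vignette: `vignettes/hyperbolic-embedding.Rmd` documents the
  models, likelihoods, numerical choices and limitations.
- All inference is deterministic given a seed; degree ties, likelihood
  ties, and eigenvector signs are broken by fixed rules.
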