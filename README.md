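# heatrewire

Adaptive rewiring of weighted undirected networks driven by heat-kernel
diffusion — a structural-plasticity model in which a network continuously
reshapes itself in response to its own signal traffic, the way brain
networks are thought to rewire in response to neural activity.

## The model

A network is a weighted undirected graph with symmetric nonnegative
adjacency matrix **A** (zero diagonal). Signal traffic is modelled as heat
diffusion under the normalized graph Laplacian

```
L = D^{-1/2} (D - A) D^{-1/2},        h(τ) = exp(-τ L),
```

where `D` is the diagonal matrix of node strengths and `h(τ)ᵢⱼ` is the heat
transferred between nodes *i* and *j* after diffusing for time τ (the
*rewiring interval*). One rewiring step:

1. pick a pivot node *k* uniformly among nodes with `0 < degree < n − 1`;
2. with probability `p_random` pick a random non-neighbour `j₁` and a
   random neighbour `j₂`; otherwise pick the non-neighbour with the
   **most** heat transfer with *k* and the neighbour with the **least**;
3. delete edge `(k, j₂)`, create `(k, j₁)`, and move the deleted edge's
   weight onto the new edge.

Iterating this rule 4,000 times on a connected random network of 100 nodes
(mean degree 18.24, weights normal(1, 0.25) or lognormal(0, 1) normalized
to total weight = edge count) produces, depending on τ alone:

* **small τ** — *modular* networks: dense communities, high Newman
  modularity `Q`, degrees hugging the mean;
* **large τ** — *centralized* networks: a few heavy hubs, low `Q`, a large
  share of degree outliers (degrees outside `⟨k⟩ ± 3√⟨k⟩`);
* **a narrow transition zone** — maximal variability, where the same
  process can yield anything from highly modular to highly centralized.

The package implements the simulator (compiled core, ~0.7 s per 4,000-step
run at n = 100) plus the analysis battery around the transition:
τ-sweeps, inflection-point detection, perturbation distributions,
initial-vs-final modularity correlation, the two-stage experiment that
quantifies *specificity* (rewiring drives any starting pattern to one
class), *robustness* (rewiring preserves the starting class) and
*flexibility* (low R² of the `Q_8000 = α·Q_4000 + β` fit), and bootstrap
R² summaries.

## Worked example

```r
library(heatrewire)

g <- generate_initial_network(100, weight_spec("normal"), seed = 7)
n_edges(g)                 # 912  -> mean degree 18.24
total_weight(g)            # 912  (weights normalized to the edge count)

# fast rewiring rate: the network becomes modular
res3 <- run_rewiring(g, rewiring_config(tau = 3, p_random = 0.2, r = 4000, seed = 7))
detect_communities(res3$graph)$Q     # 0.7218105
outlier_proportion(res3$graph)       # 0.05

# slow rewiring rate: the same network becomes centralized
res5 <- run_rewiring(g, rewiring_config(tau = 5, p_random = 0.2, r = 4000, seed = 7))
detect_communities(res5$graph)$Q     # 0.1450418
outlier_proportion(res5$graph)       # 0.42
```

At τ = 3 the rewired network is modular (Q ≈ 0.72, 5 % degree outliers);
at τ = 5 it is centralized (Q ≈ 0.15, 42 % of nodes are outliers) — the
same initial network, the same rule, a single control parameter.

Locating the modular→centralized transition:

```r
sw <- tau_sweep("normal", p_random = 0.2, tau_grid = seq(3, 5.5, 0.25),
                reps = 10, r = 4000, seed = 99)
find_transition(sw$summary$tau, sw$summary$mean_outliers, "ascending_sigmoid")
# [1] 4.25   (the outlier curve's inflection; one grid step wide)
```

A command-line front end with subcommands `generate`, `rewire`, `sweep`,
`transition`, `perturb`, `correlate`, `two-stage` and `bootstrap-r2` is
installed at `inst/cli/heatrewire`; every invocation writes a JSON run
manifest sufficient to reproduce it bit-identically.

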