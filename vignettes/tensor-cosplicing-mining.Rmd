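---
title: "Tensor-based mining of frequent co-splicing clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor-based mining of frequent co-splicing clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fscmine)
```

## The problem

Alternative splicing is coordinated: groups of cassette exons regulated by
the same splicing factors rise and fall together in their *inclusion rates*
(the fraction of a gene's transcript output that contains the exon). Within
one RNA-seq dataset such a group appears as a densely connected, heavily
weighted subgraph of the *co-splicing network* — the graph whose nodes are
exons and whose edge weights are correlations between inclusion-rate
profiles across samples. A single dataset, however, produces many spurious
heavy subgraphs. The signature of genuine splicing modules is *recurrence*:
the same exon set forms a heavy subgraph in many independent datasets.

`fscmine` finds such **frequent co-splicing clusters (FSCs)**: pairs
(exon set, network set) such that the exon set induces a heavy subgraph in
every network of the network set.

## From transcript abundances to a network tensor

For exon $e$ of gene $g$ in sample $s$, the inclusion rate is

$$ r_{es} \;=\; \frac{\sum_{t \ni e} \mathrm{FPKM}_{ts}}
                    {\sum_{t \in g} \mathrm{FPKM}_{ts}}, $$

the abundance of transcripts containing the exon over the total abundance
of the host gene (`exon_inclusion_rate()`); it is undefined where the gene
is not expressed. Because lowly expressed genes give unstable rates,
`build_inclusion_matrix()` keeps an exon only when its host gene is
strictly above the 80th expression percentile of its sample in at least 6
samples (both settings are arguments).

`correlation_network()` turns one dataset's inclusion matrix into a
network: edge weights are Pearson correlations over pairwise-complete
samples, set to zero for pairs sharing fewer than `min_overlap = 4`
samples, and negative correlations are clamped to zero (weights must live
in $[0,1]$ for the heaviness objective below; an `"abs"` transform is
available for callers interested in anti-correlated splicing).
`assemble_tensor()` stacks $m$ networks over a shared exon universe into an
$n \times n \times m$ array $\mathcal{A} = (a_{ijk})$, each slice symmetric
with zero diagonal.

## The objective and its constraints

Memberships are continuous: a nonnegative vector $x \in \mathbb{R}^n$ over
exons and $y \in \mathbb{R}^m$ over networks. The mined quantity is the
*heaviness objective*

$$ H_\mathcal{A}(x, y) \;=\; \tfrac12 \sum_{i,j,k} a_{ijk}\, x_i x_j y_k
   \quad \text{s.t.} \quad f(x) = 1,\; g(y) = 1,\; x, y \ge 0, $$

with the mixed norms

$$ f(x) = \alpha \lVert x\rVert_p + (1-\alpha) \lVert x\rVert_2,
   \qquad g(y) = \lVert y\rVert_q. $$

The defaults $p = 0.8$, $\alpha = 0.2$, $q = 10$ encode the shape of the
patterns sought. The $L_p$ term with $p < 1$ drives most exon memberships
to exactly zero (clusters involve few exons out of thousands), while the
$L_2$ term keeps the surviving components comparable in magnitude, so the
pattern boundary is sharp. The near-$L_\infty$ norm on $y$ does the
opposite: it lets many networks carry similar weight, because a frequent
cluster should recur broadly rather than concentrate in one network.

## Multi-stage convex relaxation

The constraint $f(x) = 1$ is non-convex. Writing $u_i = x_i^2$,

$$ \bar f(u) = \alpha \Big(\sum_i u_i^{p/2}\Big)^{1/p}
             + (1-\alpha) \Big(\sum_i u_i\Big)^{1/2} $$

is concave in $u$, so each *stage* replaces $f$ by its tangent at the
current iterate — a quadratic surrogate with weights
$v = \nabla \bar f(u)$ (`refresh_relaxation_weights()`; a smoothing
constant $\varepsilon$ keeps $v$ finite at zeros). Within a stage the
solver alternates:

* **Exon step** (`update_exon_memberships()`): one reweighted power
  iteration $x_i' \propto \max\{0, (Wx)_i / v_i\}$ with
  $W_{ij} = \sum_k a_{ijk} y_k$, renormalised to $f(x') = 1$. Components
  below $\sqrt{\varepsilon}$ are truncated to exact zero: under the
  smoothed norm they are indistinguishable from zero, and truncation
  completes the collapse that the sparse $L_p$ term drives, giving the
  solution a well-defined support.
* **Network step** (`update_network_memberships()`): with
  $w_k = \tfrac12 x' A_k x$ fixed, the maximiser of $\sum_k w_k y_k$ over
  $\lVert y \rVert_q = 1$ is closed-form (Hölder):
  $y_k \propto w_k^{1/(q-1)}$.

Steps that decrease the objective are rejected, so the accepted-step trace
is non-decreasing; stages repeat until the weights stabilise.
`optimize_memberships()` wraps this with a deterministic uniform start plus
seeded random restarts.

```{r optimizer}
ent <- array(0.05, dim = c(30, 30, 6))
ent[1:6, 1:6, 1:4] <- 0.9                       # a planted heavy block
for (k in 1:6) { s <- ent[, , k]; s[lower.tri(s)] <- t(s)[lower.tri(s)]
                 diag(s) <- 0; ent[, , k] <- s }
tn <- network_tensor(ent)
sol <- optimize_memberships(tn, mining_config())
head(sort(sol$x, decreasing = TRUE), 8)
round(sol$y, 3)
```

## From memberships to discrete clusters

Ranking $x$ and $y$ gives candidate prefixes. A candidate pattern *occurs*
in a network when its average intra-cluster edge weight in that slice is at
least the heaviness threshold (default 0.4). Among prefixes of the ranked
exon list (restricted to strictly positive memberships),
`extract_representative_patterns()` keeps two representatives: the prefix
whose occurrence set is largest, and the longest prefix still occurring in
at least `min_networks` networks. This occurrence-based reading — rather
than averaging heaviness over all positive-membership networks — prevents
background networks from diluting a pattern that is genuinely heavy in a
subset of networks. Mining (`mine_all()`) then masks the pattern's edges in
the networks where it occurs and repeats, so overlapping clusters sharing
exons in *different* networks can still surface.

For small instances `heaviest_fixed_size_pattern()` enumerates all
$\binom{n}{k_e}\binom{m}{k_n}$ patterns, an exhaustive oracle used
throughout the test suite; `top_pattern(..., refine = TRUE)` additionally
polishes the ranked prefix by one-swap hill climbing, which closes most of
the gap to the oracle on dense unstructured tensors.

## Simulation benchmark

Because real mining runs depend on large external RNA-seq compendia, the
package judges itself on synthetic data whose truth is known.
`generate_background()` draws edge weights uniformly with a chosen mean
(default 0.1, matching weak background correlation after clamping);
`plant_cluster()` overwrites a random exon-subset/network-subset block with
a target heaviness plus clipped Gaussian noise. The default scenario —
200 exons, 20 networks, one 10-exon cluster planted in 8 networks at
heaviness 0.7 — is deliberately modest: large enough that a dense pattern
cannot be found by chance, small enough to run in seconds. A cluster
counts as detected when its exon Jaccard similarity to the truth is at
least 0.9 and its network Jaccard at least 0.8.

```{r benchmark}
r <- benchmark_run(seed = 1)
r$report$per_planted[, c("exon_jaccard", "network_jaccard", "detected")]
```

What this shows — and does not: recovery of a single well-separated
planted cluster demonstrates that the relaxation, extraction, and masking
machinery is sound, and sweeping the planted heaviness maps the detection
boundary. It does not certify behaviour on real data, where clusters
overlap, noise is structured, and the background is not uniform.

## Enrichment

`enrich_clusters()` collapses each cluster's exons to host genes and tests
overlap with annotation terms by the hypergeometric tail
(`hypergeometric_pvalue()`), with per-collection significance thresholds
and an optional maximum term size to exclude uninformative broad terms.
`baseline_fold_ratio()` compares the fraction of enriched real clusters to
size-matched random gene sets — the fold ratio that separates signal from
what enrichment finds by chance.

## Limitations

* Mining quality is judged against exhaustive oracles only at small sizes;
  at scale the relaxation is a heuristic with no global guarantee.
* The occurrence threshold couples extraction to the heaviness scale of
  the input networks; datasets with very different correlation structure
  may need a different threshold.
* The simulation background is unstructured; detection rates there are an
  upper bound on what structured real data would allow.
* Inclusion rates are taken from transcript-level quantifications as
  given; quantification uncertainty is not propagated.
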