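---
title: "Identifying driver pathways by coverage, mutual exclusivity and network connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying driver pathways by coverage, mutual exclusivity and network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverpath)
library(ggplot2)
```

## The problem and the model

Somatic mutations in a tumour cohort are summarized as a binary matrix
$A_{|P| \times |G|}$ over samples $P$ and genes $G$, with $a_{ij} = 1$ when
gene $j$ is altered in sample $i$ either by a point mutation or by a
significant copy-number call (the two channels are merged with an OR: a
cell is altered when *either* channel is non-zero; requiring both would
erase every gene lacking copy-number calls and contradicts the standard
union of SNV and CNA evidence). A *driver pathway* of size $K$ is modelled
as a gene set $M$ whose mutations are frequent across the cohort but
rarely co-occur within a sample — most tumours need only one hit per
pathway — and whose members interact in a protein–protein association
network.

Writing $\Gamma(g)$ for the support of gene $g$ (the samples in which it
is mutated) and $\Gamma(M) = \bigcup_{g \in M}\Gamma(g)$, the objective
maximized over $K$-subsets is

$$W(M) = \underbrace{\frac{|\Gamma(M)|}{\max_{g \in G}|\Gamma(g)|}}_{CO(M)}
 + \underbrace{\frac{1}{K}\sum_{g \in M} RHD(g, M)}_{ME(M)}
 + \underbrace{\frac{\sum_{i \ne j} w_{ij}}{K(K-1)}}_{N(M)},$$

with no trade-off weights between the three terms — the model is
parameter-free in that sense.

**Coverage** is normalized by the largest *single-gene* support in the
whole dataset, a fixed property of $A$, so $CO(M) > 1$ is legal and simply
means the set covers more samples than any one gene does. The denominator
deliberately ranges over all genes of $A$, not just $M$; the score of a
set therefore depends on the dataset it sits in.

**Mutual exclusivity** is built on the *relative Hamming distance*
$$RHD(g_j, g_k) = \frac{|\Gamma(g_j) \setminus \Gamma(g_k)|}{|\Gamma(g_j)|},$$
the fraction of $g_j$'s mutated samples not shared with $g_k$. It is
asymmetric: $RHD(g_j, g_k) = 0$ exactly when $\Gamma(g_j) \subseteq
\Gamma(g_k)$ — an *inclusion* relationship — and $1$ exactly when the
supports are disjoint. $RHD(g, M)$ averages the pairwise distances from
$g$ to the other $K - 1$ members, and $ME(M)$ averages those over the
members. The point of this construction is visible in the worked example
below: the classical maximum-weight-submatrix score
$2|\Gamma(M)| - \sum_j |\Gamma(g_j)|$ cannot see that a set's coverage is
carried entirely by one dominant gene, while $ME$ can.

**Network connectivity** averages the pairwise association weights of the
set. The weights come from two STRING-style channels — literature
(`F`) and experimental (`E`), raw integer scores in $[0, 999]$ normalized
by the printed maximum 999 so that the top score maps exactly to 1 — and
are combined as $w = \max(f, e)$ *when the experimental channel is
non-zero* and $0$ otherwise: experimental support gates the edge, so
literature co-mentions alone never create one. The diagonal of $W$ is
forced to zero so $N(M)$ averages off-diagonal pairs only, matching its
$K(K-1)$ denominator.

### The worked example

```{r example}
B <- example_inclusion_matrix()
tidy(B) |> head(3)
score_gene_set(B, genes = c("g1", "g2", "g3"), use_network = FALSE)
mwsm_weight(B, c("g1", "g2", "g3"))
detect_inclusions(B)
```

Gene `g2` covers samples 1–9 and swallows the supports of `g1` and `g3`
entirely (two inclusions). The classical weight is 5 — the same value a
perfectly exclusive, evenly covered triple would get — while
$ME = 16/27 \approx 0.59$ flags the redundancy.

## The search

Exhaustive search over $\binom{|G|}{K}$ subsets is infeasible at cohort
scale, so the optimizer is a partheno-genetic algorithm (single-parent
recombination, no crossover) seeded and constrained by two per-gene
clusters computed once up front:

* $c_1(g) = \{h \ne g : RHD(g, h) \ge \mu\}$ — genes sufficiently
  exclusive of $g$. The asymmetric direction (owner toward candidate) is
  kept exactly as defined; symmetrizing with a min or max would change
  which sets are reachable and is deliberately not done.
* $c_2(g) = \{h \ne g : w_{gh} \ge \nu\}$ — genes sufficiently connected
  to $g$.

A chromosome is a set of $K$ distinct genes. Initialization draws the
first gene roulette-style with probability proportional to support size,
then repeatedly draws from the pool
$\bigcap_{x \in X} c_1(g_x) \cap \bigcup_{x \in X} c_2(g_x)$ (members of
$X$ excluded — the written definition leaves this implicit, but duplicate
genes would break the chromosome contract), restricted to candidates whose
*mean* weight to the current members is at least $\nu$. An empty pool is a
failure signal, not an error: the population initializer retries, and
only gives up (with advice to lower $\mu$/$\nu$ or $K$) after a hundred
consecutive failures per slot.

Each generation applies roulette selection with elitism (the best-so-far
individual always occupies one slot, so the best-fitness history is
non-decreasing by construction) and then, independently with probability
`rr` per non-elite individual, a greedy recombination: drop either the
minimum-support member or a uniformly random member (an unweighted coin —
the operator is specified only as choosing "randomly"), then add the
largest-support gene from $\bigcap_{x \in \hat X} c_1(g_x)$ whose mean
weight to the $K-1$ survivors is at least $\nu$. Note the recombination
pool uses only $c_1$, without the $c_2$ union used at initialization;
that asymmetry is part of the operator's definition and is preserved.
If no candidate is eligible the chromosome is left unchanged. Two
reproducibility choices are ours: ties in the greedy add (equal support)
break toward the lexicographically smallest gene symbol, and the
constraint denominator after the drop is $K - 1$, the current set size.

Termination: a hard cap of `maxg` generations, or `maxt` consecutive
generations without improvement of the best fitness (`maxt` as early-stop
patience is the reading consistent with its use alongside `maxg` in
related single-parent searches; the alternative — counting restarts — has
no natural meaning here). `rr` itself is interpreted as the
per-individual recombination probability per generation, the standard
meaning of a recombination rate in this family of algorithms.

Defaults (`pga_control()`): $N = \lceil|G|/4\rceil$, `maxg = 1000`,
`maxt = 100`, `rr = 0.3`, $\mu = 0.7$, $\nu = 0.5$. All randomness of a
run — clustering draws nothing, but initialization, selection and
recombination do — flows from the single integer `seed`, so a run is
exactly reproducible.

```{r run}
inst <- simulate_driver_instance(seed = 7)
A <- filter_low_frequency_genes(inst$A)
fit <- find_driver_set(A, inst$W, pga_control(K = 3, seed = 1))
glance(fit)
autoplot(fit)
```

## Significance

An identified set is calibrated against chance with a permutation test:
`n_draws` (default 1000) uniform $K$-subsets of the post-filter gene
universe are scored with the same objective, and the p-value is the
fraction *strictly* exceeding the observed weight — ties do not count
against the observed set, and the resolution is $1/n_{draws}$. The null
draws are unconstrained by the clusters or the network: the null
hypothesis is "a random set of genes", not "a random feasible set", which
makes the test conservative about the search's own restrictions.

```{r sig}
st <- random_set_test(A, inst$W, fit$genes, n_draws = 1000, seed = 1)
glance(st)
```

## The synthetic generator

`simulate_driver_instance()` emulates the structure the model is designed
to detect, not real cohort data. A planted module of `k_true` genes
receives `coverage_frac` of the samples, partitioned round-robin so
coverage is balanced across the planted genes (mirroring the preference
for uniform coverage that motivates $ME$), with pairwise co-mutation
injected at `overlap_rate`. Background genes are independent Bernoulli
noise at `background_rate`; background association weights are
independent Uniform(0, `background_weight`), while planted pairs get
`within_weight`. Defaults — 200 samples, 50 genes, `k_true = 3`, 60%
module coverage, 2% overlap, 3% background mutation rate, weights 0.9
within / up to 0.3 outside — are sized like a single-cancer TCGA cohort
after frequency filtering, scaled to a gene universe where exhaustive
enumeration remains possible for validation.

What it does *not* emulate: long-tailed per-gene mutation rates,
patient-specific mutation burdens, correlated background (mutational
signatures), STRING's topology, or multiple overlapping pathways. Tests
passing on these instances therefore demonstrate correctness of the
machinery and recoverability of a clean signal, not performance on real
tumours.

Genes mutated in fewer than 0.5% of samples are dropped before any
analysis (`filter_low_frequency_genes()`; genes exactly at the threshold
are kept). Scoring a gene with an *empty* support is an error, never a
silent zero — such genes cannot survive the filter, so their appearance
signals a skipped preprocessing step.

## Numerical and validation choices

* All score identities are exact rational arithmetic in doubles; the
  component sum $W = CO + ME + N$ is checked to $10^{-12}$.
* The fast scorer used by the search and the permutation test reduces
  $ME$ and $N$ of a subset to sums over precomputed pairwise matrices
  ($ME(M) = \sum_{i \ne j \in M} R_{ij} / K(K-1)$, with
  $R_{jk} = RHD(g_j, g_k)$); the definitional functions remain the slow
  reference path, and the two are cross-checked in the tests against
  independent set-algebra oracles.
* Optimizer validation compares the search against brute-force
  enumeration on 12-gene instances (220 subsets), drawn from the planted
  generator at 60 samples. Planted structure is used deliberately: the
  cluster thresholds are part of the method, and on structureless noise
  the feasible space they induce need not contain the unconstrained
  optimum — an instance with a genuine exclusive, connected module is the
  setting the method defines itself on. Recovery experiments use the
  default 200 x 50 instance over 10 seeds; null calibration of the
  permutation test averages 200 replicates of 500 draws.
* Duplicate edges in an association file are a format error rather than
  silently max-merged or last-write-wins: a STRING extract should list
  each unordered pair once, and duplicates usually mean a corrupted
  concatenation.

## Limitations

* $K$ is an input, not inferred; comparing fits across $K$ needs an
  external criterion (the permutation test is per-$K$).
* The greedy add step is deterministic given the dropped gene, so
  population diversity rests on the drop coin, roulette selection and
  initialization; on instances whose optimum contains no high-support
  gene the search can stagnate in local optima — the oracle-equivalence
  suite bounds how often this happens at small scale only.
* The coverage term is unbounded above and can dominate the other two on
  matrices with a weak maximum-support gene; this is a property of the
  model, not of the implementation.
* The permutation null resamples gene *labels* only; it inherits the
  observed support-size distribution but ignores per-sample mutation
  burden.
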