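---
title: "Chaperone-client co-expression networks: models, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaperone-client co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochapnet)
```

This vignette is the package's own account of its science: the model behind
each stage, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, the numerical choices, and the design
decisions that were genuinely open.

## 1. The inference model

The working hypothesis is biological: if a client protein's folding depends
on a particular mitochondrial chaperone, the two transcripts should be
co-regulated, and that co-regulation should recur across tumour types rather
than appear in a single cohort. The pipeline therefore estimates a
chaperone-client interaction network in three steps, each deliberately
conservative:

**Rank correlation with a hard gate.** Per cohort, the Spearman coefficient
between every chaperone and every client is the Pearson correlation of
average-ranked expression values; ranks make the statistic invariant to any
strictly increasing transform, so FPKM, log-FPKM, or rescaled units all give
identical results. The two-sided p-value uses the t approximation with
$n - 2$ degrees of freedom, which is accurate at cohort sizes in the
hundreds; an exhaustive permutation oracle in the test suite confirms that at
tiny $n$ the approximation orders pairs exactly as the exact null does. A
pair survives only if $p < \alpha / (n_{\text{chap}} \cdot n_{\text{client}})$
(Bonferroni over the per-cohort family; with the canonical 15 x 1142 panels
and $\alpha = 0.05$ this is $2.9 \times 10^{-6}$) *and* $r > 0$ — negative
co-expression is not evidence of a folding dependency. Everything else
becomes exactly 0.

**Median aggregation.** The pan-cancer weight of a pair is the cell-wise
median of its per-cohort filtered values, zeros included. This induces a
majority rule: with an odd number of cohorts $T$, a pair is retained iff it
is significantly positively correlated in at least $\lceil (T+1)/2 \rceil$
cohorts. The rule is a consequence of including zeros in the median, not an
extra parameter, and the tests assert it by brute-force recount. Even cohort
counts use the conventional mean-of-middle-two (unconstrained by the
13-cohort design this emulates).

**One definition of "interacts".** Strict positivity of the pan-cancer
weight defines edges of the bipartite network, membership in the pairwise
client-set (Venn) partitions, and the degree summaries. Using a single rule
everywhere keeps the counts mutually consistent
($|both| + |only_a| = \deg(a)$, etc.).

## 2. The map equation and its search

A partition $M$ of the network's nodes is scored by the two-level map
equation: the expected per-step description length, in bits, of a random
walk encoded with one codebook per module plus an index codebook,

$$L(M) = q\,H(Q) + \sum_i p_i^\circlearrowright H(P^i),$$

where node visit rates are $p_\alpha = s_\alpha / 2W$ (strength over twice
the total edge weight — the stationary distribution of an undirected
weighted walk), module exit rates are $q_i = \text{cut}_i / 2W$,
$q = \sum_i q_i$, $p_i^\circlearrowright = q_i + \sum_{\alpha \in i}
p_\alpha$, entropies are base 2, and $0 \log 0 \equiv 0$. Partitions that
trap the walker in dense regions need fewer bits; the best partition
minimises $L$. Two closed forms anchor the implementation: a single module
gives $L = H(\{p_\alpha\})$ exactly, and two disjoint unit-weight triangles
under the component partition give $L = \log_2 3 \approx 1.585$ bits. $L$ is
invariant under global edge-weight scaling and node relabeling; both are
asserted as properties.

The bipartite graph is treated as an ordinary undirected weighted graph for
flow purposes — the walker simply follows weighted edges — and the code is
two-level only (flat partitions), since the structures of interest here are
flat module sets. No teleportation is used; the observed networks are
connected enough that the stationary distribution is well defined on each
component, and $L$ handles multiple components naturally.

**Search.** Exact minimisation is combinatorial, so `detect_communities()`
uses a seeded greedy search written in C++: starting from singletons, sweep
nodes in seeded random order, moving each to the neighbouring module (or a
fresh module) that most decreases $L$; when a full sweep improves $L$ by
less than $10^{-10}$ bits, attempt greedy module merges; alternate until
neither phase improves. The best of `n_restarts` independent sweep orders is
kept, and the result is explicitly compared against the single-module and
all-singleton partitions, so the returned $L$ never exceeds either baseline.
Ties between candidate target modules break toward the lowest module label,
which together with the seeded sweep order makes the search fully
deterministic given `(network, n_restarts, seed)`.

**Oracle.** `exhaustive_partition_search()` enumerates every set partition
(restricted-growth strings; Bell numbers) for graphs of up to 10 nodes and
returns the global minimum, with ties broken by fewer modules then
lexicographic assignment. On every small fixture in the suite the greedy
search attains the oracle minimum to within $10^{-12}$ bits. This is the
package's guard against search pathologies; published community-detection
tools are not used as a dependency, so the contract is on $L$ itself.

## 3. The permutation null

Any community-detection method returns *some* partition, so the question is
whether the observed network's partition is better than expected for random
chaperone-client associations with the same marginal behaviour. The null
preserves two things exactly:

* **Degrees** — the binary incidence matrix is randomised by the curveball
  algorithm: repeatedly pick two chaperone rows, collect the clients held by
  exactly one of them, and swap a uniformly random re-split of those
  exchangeable clients between the rows. Every trade preserves all row and
  column sums; the test suite verifies, on a fixture whose fixed-margin state
  space is enumerable by brute force, that the chain's empirical distribution
  over states is uniform. The default number of trades is 5 x (number of
  chaperone rows) — the original curveball recommendation, since the source
  analysis names none — exposed as `n_trades_factor`.
* **Weights** — the observed multiset of edge weights is redistributed as a
  uniformly random bijection onto the shuffled one-cells, so the null
  network has exactly the observed weights, only in random places.

Each replicate is then re-optimised with the same `n_restarts` as the
observed fit (equal search effort on both sides of the comparison), giving
$L^{sim}_1, \dots, L^{sim}_N$.

**Direction of the p-value.** "Non-random modular structure" means random
networks should rarely admit a partition as *good* — as low in $L$ — as the
observed one. The default p-value is therefore
$p = \#\{L^{sim}_i \le L^{obs}\} / N$ (`random_at_least_as_good`). The
opposite count ($L^{sim}_i > L^{obs}$) appears in some printed formulas of
this analysis style while the surrounding prose describes the probability of
a random network with a *better* partition; the two disagree, and the prose
reading is the one under which small p supports non-random structure, so it
is the default here. The printed direction remains available behind
`direction = "as_printed"`. No +1 small-sample correction is applied (the
counting formula has none); a raw count of 0 is reported as "< 1/N" in
human-readable output while JSON keeps the exact value.

Replicate RNG streams are derived from `(seed, replicate index)`, so the
ensemble is reproducible and independent of execution order. On
structureless networks (planted generator with `w_in == w_out` and equal
edge probabilities) the observed matrix is, conditional on its margins,
exchangeable with its curveball randomisations, so the p-value should be
uniform; the acceptance suite checks this with a Kolmogorov-Smirnov test
over 50 outer seeds at `n_sim = 99`.

## 4. What the synthetic generator emulates — and what it does not

`generate_cohort_bundle()` emulates the *regime* of a pan-cancer study:
$T$ cohorts (default 13) of $n$ samples (default 200), a chaperone panel
(default 15) and client panel loading on $K$ latent module factors (default
3), with log-space generation: an assigned gene's log-expression is
`within_module_loading` x its module's factor + `cross_module_loading` x the
mean of the other factors + Gaussian noise (`noise_sd`, default 0.3), then
exponentiated, giving positive, right-skewed, FPKM-like values. Defaults
`within = 0.9`, `cross = 0.05` give a loading ratio well above 10, i.e. the
strong-separation regime in which module recovery is asserted;
`frac_unassigned_clients = 0.15` plants a minority of noise-only clients to
exercise the dropped-node path (the analogue of clients co-expressed with no
chaperone). Chaperones are assigned to modules round-robin so every module
contains at least one chaperone, matching the structure of the observed
networks and making module naming (by busiest chaperone) well defined.

Deliberately **not** emulated: library-size and batch effects, tumour
purity, heavy-tailed outliers, gene-length biases, or realistic correlation
spectra within modules. A green test on this generator establishes that the
pipeline's statistics and search behave as specified on data with known
truth — not that the biological conclusions of any particular study are
correct, and not that TCGA-scale counts are reproduced. The headline numbers
of the motivating analysis (967 interacting proteins, 4649 interactions,
module sizes 422/451/94) depend on the real TCGA matrices and are outside
what synthetic data can or should reproduce. (That analysis also reports
967 + 176 = 1143 proteins against a 1142-gene panel; the off-by-one is
unexplained there and no attempt is made to reproduce it.)

`generate_planted_network()` skips expression entirely and emits the
weighted bipartite matrix directly — within-module cells present with
probability `edge_prob_in` at weight `w_in` (±10% jitter, so weights are
distinct and description lengths effectively continuous), cross-module cells
with `edge_prob_out` at `w_out`. It is the fixture for the community and
null-test stages, including the acceptance benchmark (15 x 90, K = 3,
`w_in = 0.6`, `w_out = 0.05`, `p_in = 0.9`, `p_out = 0.1`).

## 5. Numerical choices and degenerate inputs

* Spearman p-values: t approximation with $n - 2$ df; $|r| = 1$ maps to
  $p = 0$; exact permutation reserved for the test oracle.
* Constant genes (zero rank variance): $r = 0$, $p = 1$, flagged — never an
  NA that could leak into a median.
* A gene in both panels: the self-pair is flagged ($r = 1$, $p = 0$) and
  zeroed by the filter so it cannot become a self-loop; cross-pairs are
  kept.
* Duplicate gene ids are a hard error unless `dedupe_first = TRUE` (silent
  aggregation hides corruption).
* Greedy convergence: a sweep improving $< 10^{-10}$ bits stops the phase;
  move acceptance requires an improvement $> 10^{-12}$ to be robust to
  floating-point noise; oracle comparisons use $10^{-12}$ bits.
* Constant clustering profiles get distance 1 to everything and are
  flagged; chaperone-by-chaperone distance matrices are symmetrised before
  `hclust`.
* TSV artifacts serialise numbers at 17 significant digits, so re-running a
  fixed config reproduces byte-identical files (asserted via manifest
  digests).
* All seeded entry points snapshot and restore the caller's RNG state.

## 6. Open design decisions, as resolved

* **Bonferroni family**: per-cohort ($n_{\text{chap}} \times
  n_{\text{client}}$ tests), not pooled across cohorts — this is the reading
  that reproduces the canonical $2.9 \times 10^{-6}$ threshold exactly.
* **Null replicates re-optimise** the partition (rather than re-scoring the
  observed partition on the randomised network): the null is "what L would a
  fresh analysis of a random network achieve", matching equal-effort
  comparison.
* **Clustering parameters**: linkage and distance are not dictated by the
  problem; average linkage on $1 - r$ (or $1 - w$ for the square chaperone
  matrix) is the common default for correlation heatmaps and is what
  `cluster_profiles()` uses, with single/complete linkage available. Exact
  leaf orders are therefore not comparable across implementations and are
  not asserted anywhere.
* **"Open gate" configurations**: with the significance threshold pushed to
  1 the filter keeps every positive correlation, the network is dense and
  unstructured on independent data, and the null p-value is large — this
  forced behaviour is covered by a pipeline test. Note that feeding
  $\alpha = 1$ through the Bonferroni division would still give a *small*
  per-test threshold; an open gate is a statement about the corrected
  threshold, so that is where the test applies it.
* **Module naming**: by the highest-degree chaperone inside each module;
  modules without a chaperone keep their numeric label.

## 7. Known limitations

* The greedy search is exact only against the oracle regime (<= 10 nodes)
  and the planted fixtures; on adversarial large graphs it inherits the
  usual local-search caveats, mitigated by restarts and baseline guards.
* The two-level code cannot represent hierarchical module structure.
* The t approximation is anti-conservative at very small cohort sizes
  (n < ~10); cohorts that small are outside the intended regime.
* The curveball chain's mixing time is fixture-dependent; 5 x rows is a
  recommendation, not a guarantee, which is why `n_trades_factor` is a
  parameter.
* p-values are lower-bounded by 1/`n_sim`; claims below 0.001 need more
  than 1000 replicates.
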