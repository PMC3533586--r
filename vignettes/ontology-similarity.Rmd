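---
title: "Measuring concept similarity over biomedical taxonomies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring concept similarity over biomedical taxonomies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontosim)
```

## The problem

Biomedical vocabularies — clinical ontologies, indexing thesauri,
meta-compendia that merge dozens of source vocabularies — define concepts
and relationships between them. Many applications need to quantify how
similar or related two concepts are: a similarity between *myocardial
infarction* and *angina pectoris* should be high, between *myocardial
infarction* and *hay fever* low. `ontosim` implements the knowledge-based
approach: all information comes from the structure of the concept graph
itself (and optionally from corpus frequencies of concepts), never from
raw text, so the measures work wherever a hierarchy exists.

Two families are covered. *Similarity* proper is computed over the
taxonomy — the acyclic, rooted subgraph of hierarchical (is-a,
broader-than) relationships. *Relatedness* is a weaker notion (a wheel is
related to a car without being a kind of car) and is computed by
personalized PageRank over an undirected graph that may also include
non-hierarchical relations.

## From raw relationship files to a taxonomy

`read_edge_list()`, `read_obo()` and `read_rrf_relations()` parse a
concept graph from, respectively, a minimal tab-separated child–parent
format, OBO 1.2 documents, and pipe-delimited relationship tables in the
style of UMLS MRREL (the column map and the set of labels counted as
hierarchical are caller configuration, so any licensed release can be
ingested without this package shipping any of it).

`build_taxonomy()` then derives a valid taxonomy:

* **Cycle removal.** Real vocabularies contain occasional cycles among
  hierarchical relations. We traverse the child-to-parent graph
  depth-first, visiting concepts and parent lists in lexicographic order,
  and drop any edge that points back into the active traversal stack.
  This is deterministic — two builds of the same input remove the same
  edges, which are reported in `removed_edges` — but it is *a*
  minimal-intervention convention, not the only one; nothing downstream
  depends on which edge of a cycle is dropped beyond reproducibility.
* **Rooting.** If more than one concept has no parent, a synthetic root
  `VROOT` is added above them (sources that are already single-rooted are
  left untouched). This guarantees every pair of concepts has at least
  one common subsumer, so no measure needs a "disconnected" sentinel.
* **Caches.** Depth (node count of the shortest parent path, root = 1;
  the minimum is taken over parents, matching the shortest-path reading
  used by all path measures), per-concept leaf-descendant counts,
  subsumer-set sizes, the maximum depth `d` and total leaf count
  `max_leaves` are all precomputed; pairwise ancestor traversals are
  memoized per taxonomy.

Two conventions deserve a note because the literature leaves them open.
A leaf concept is its own (only) leaf descendant, so `n_leaves >= 1`
everywhere and the intrinsic IC below stays finite, with leaves getting
maximal IC. And `subsumers(c)` contains `c` itself plus all ancestors via
any parent path.

## Information content

Intrinsic IC needs no corpus:
`IC(c) = −log[(|leaves(c)|/|subsumers(c)| + 1)/(max_leaves + 1)]`.
The root has IC exactly 0, and IC increases strictly along every
parent-to-child edge (leaves can only shrink, subsumers strictly grow) —
a property the test suite asserts on every generated taxonomy.

Corpus IC starts from raw per-concept occurrence counts (e.g. how often
an indexing term was applied to a literature database; any
`concept<TAB>count` file is accepted). Counts are aggregated over each
concept's descendant *set* — a descendant reachable through several
parent paths is counted once, which matters in multi-parent hierarchies;
the textbook recursive formulation double-counts on DAGs and is
deliberately not used. IC is then `−log(freq(c)/freq(root))`. Two choices
here are this package's own: normalizing by the root's aggregated mass
(so corpus IC is non-negative with root 0, mirroring the intrinsic
scale), and capping zero-frequency concepts at the maximum finite IC
observed rather than infinity, which keeps every downstream measure
defined. Smoothing schemes beyond the cap are out of scope.

Natural logarithms are used throughout. Most formulas are base-invariant;
the IC form of Leacock–Chodorow is not, so the base must be pinned — `e`
is the conventional choice for IC.

## The measures and their conventions

All similarities land in `[0, 1]` with self-similarity exactly 1:

* `sim_path = 1/p` and `sim_lch = 1 − log(p)/log(2d)` depend only on the
  shortest-path node count `p`, hence produce identical rank orderings:
  their Spearman correlations against any benchmark coincide. The scaled
  LCH form divides the historical `log(2d) − log(p)` by the constant
  `log(2d)`, which cannot change ranks — the package exposes only the
  scaled form.
* `sim_wupalmer = 2·depth(lcs) / ((p − 1) + 2·depth(lcs))` uses the LCS
  on the shortest path (when the path-minimal and IC-maximal subsumers
  differ, the path-based measure gets the path-based subsumer). The
  `p − 1` in the denominator — rather than the sum of the two separate
  paths to the LCS — makes identical pairs score exactly 1.
* `sim_lin`, `dist_jc`, `sim_lch_ic = 1 − log(dist_jc + 1)/log(2·ic_max + 1)`
  and `sim_path_ic = 1/(dist_jc + 1)` use the common subsumer with
  maximal IC. Lin's ratio is defined as 1 for identical concepts even at
  the root, where IC is 0 and the ratio is formally 0/0; a non-identical
  pair whose ICs are both 0 scores 0. `dist_jc >= 0` is guaranteed
  whenever IC is monotone along ancestry (always for intrinsic IC, and
  for corpus IC by the aggregation order); a negative distance raises a
  hard error rather than being clamped silently.
* Tie-breaks: among equally short paths the deeper subsumer wins, then
  the lexicographically smallest id; among equal-IC subsumers the
  lexicographically smallest. The source literature never specifies
  these; they only matter for reported LCS identities, not for `p` or IC
  values.

`similarity_matrices()` computes all-pairs matrices in one pass (shared
pairwise structure, PPR for all seeds as a single matrix iteration) and
is the workhorse behind the acceptance checks.

## Personalized PageRank relatedness

The concept graph is made undirected — either taxonomy-only edges
(`mode = "taxonomy"`) or all relationships (`mode = "all"`); comparing
the two quantifies what non-hierarchical relations contribute. For a seed
concept the stationary equation `P = cMP + (1 − c)v` is solved by power
iteration, `v` the indicator of the seed, `M` column-stochastic, damping
`c = 0.85` (the conventional default). Relatedness of a pair is the
cosine of their two PPR vectors — in `[0, 1]` since the vectors are
non-negative, and 1 for identical seeds.

Numerical conventions: probability mass reaching an isolated vertex has
nowhere to flow and is returned to the *seed* (not spread uniformly),
preserving personalization semantics; vectors are truncated below
`1e-12` and renormalized after convergence. The shipped defaults
(`tol = 1e-9`, `max_iter = 100`) are kept as stated even though the L1
residual of power iteration decays like `0.85^k ≈ 9e-8` at `k = 100`,
i.e. the tolerance is not reachable within the cap and the documented
non-convergence warning fires on default settings. The returned vector is
still accurate to about `1e-7` — comfortably inside the `1e-6` agreement
bound against a dense linear solve that the test suite enforces — so
this is a cosmetic wart retained for contract fidelity; pass
`max_iter = 200` if you want the warning gone.

## Benchmark evaluation

`read_benchmark()` reads `concept1<TAB>concept2<TAB>rating` files (the
shape of the public clinical-concept rating sets, which are not bundled —
some are license-restricted and none are needed for testing).
`evaluate_benchmark()` scores each pair with each measure and reports the
Spearman rank correlation with the ratings. Pairs containing concepts
missing from the taxonomy are *skipped and counted*, never scored 0:
coverage differences are part of the result, so `n` is always explicit.

Spearman is computed as the Pearson correlation of average-tie rank
vectors (exact under ties). The Fisher r-to-z test
(`z = (atanh r1 − atanh r2)/sqrt(1/(n1−3) + 1/(n2−3))`) is the
independent-samples form; correlations of different measures on the same
benchmark are in fact dependent, so treat its p-values as indicative — a
dependent-correlations correction is deliberately out of scope.

## The synthetic world and what green tests establish

No real vocabulary ships with the package, so all testing runs on:

* `toy_T0()` — a frozen five-concept taxonomy whose every structural
  quantity, IC value and measure score is verified against hand-derived
  numbers to four decimals.
* `random_dag()` — seeded generators where concept `i` draws 1–3 parents
  among earlier concepts, guaranteeing acyclicity and single-rootedness
  by construction; optional labelled extra edges emulate non-taxonomic
  relations. Sizes in tests span 10–50 concepts (200 for the PageRank
  oracle), deliberately small: the generators target correctness, not
  the multi-million-node scale of real meta-thesauri.
* `synthetic_benchmark()` — ratings are a strictly increasing transform
  (`10·sim`) of a generating measure plus Gaussian noise of chosen sd on
  that 0–10 scale. Noise-free benchmarks must be recovered at Spearman
  exactly 1; mean recovery over 10 seeds must fall as noise grows.

Independent brute-force oracles (matrix-relaxation path distances,
transitive-closure descendant sums, a dense `(I − cM)P = (1−c)v` solve,
O(n²) rank counting plus the raw Pearson sum formula) share no code with
the production paths they check.

A green suite therefore establishes the analytic contracts — bounds,
self-similarity, symmetry, IC monotonicity, rank equivalences, oracle
agreement — on graphs with realistic *local* structure (multiple
parents, diamonds, cycles to remove). It does not establish anything
about correlation magnitudes with human raters on real vocabularies:
those depend on licensed data outside this package's world.

## Numerical fine print

* Analytically equal Jiang–Conrath distances computed through different
  operand orders can differ by ~1 ulp, and logarithms may collapse some
  of these near-ties back into exact ties; rank-equivalence tests
  therefore round shared distance vectors to 10 decimals (far above ulp
  noise, far below any genuine gap) before ranking.
* A handful of four-decimal example values in older write-ups are
  double-rounded (e.g. `1/3.0794` quoted as `0.3248` where the unrounded
  distance gives `0.32473`); the tests pin closed forms instead.
* Taxonomy artifacts (`save_taxonomy()` / `load_taxonomy()`) are
  versioned serialized R objects; a corrupted file or a future format
  version produces an explicit error, never silent garbage.

## Known limitations

* No term-to-concept mapping, synonym handling or NLP: inputs are
  already-coded concept identifiers.
* All-pairs shortest paths are computed on demand (memoized per
  taxonomy), not precomputed; `similarity_matrices()` covers the batch
  case at desk scale.
* The distributional context-vector family of relatedness measures is
  not implemented, and PageRank edge weighting by relation type is not
  supported.
* The Fisher comparison caveat above.
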