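---
title: "Inferring tumor phylogenies with mutation losses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tumor phylogenies with mutation losses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dollotree)
```

## The problem

Single-cell DNA sequencing gives, per cell, a call for each candidate
somatic mutation: present (1), absent (0) or missing (no coverage). The
calls are noisy — allelic dropout turns true 1s into 0s with probability
$\alpha$ (commonly around 0.1), amplification artifacts turn true 0s into
1s with a much smaller probability $\beta$, and a fraction $\gamma$ of
entries is missing altogether. Classical tumor phylogenetics assumes the
infinite-sites model (each mutation gained once, never lost), but copy
number deletions can remove an acquired mutation, on one or several
branches. `dollotree` therefore fits the **Dollo(k)** model: each mutation
is gained exactly once and lost at most $k$ times. $k = 0$ is the perfect
phylogeny; $k = 1$ (the default, and the best-supported regime in the
literature) allows one loss per mutation.

## Likelihood

Writing $I$ for the observed incomplete matrix and $F$ for the predicted
complete genotype matrix, independence of per-entry errors gives the
log-likelihood

$$\ell(F) = \sum_{c}\sum_{m}\log P\!\left(I[c,m] \mid F[c,m]\right),$$

with the conditional table in `error_rates()`; missing entries contribute
exactly zero. For $F[c,m]\in\{0,1\}$ each term is linear in $F[c,m]$:
an observed 1 contributes $\log\beta + F\,\log\frac{1-\alpha}{\beta}$, an
observed 0 contributes $\log(1-\beta) + F\,\log\frac{\alpha}{1-\beta}$
(`objective_coefficients()`). Rates are clamped to $[10^{-9},
1-10^{-9}]$ so noise-free data (useful for testing and sanity checks)
never produce $-\infty$; the clamp is far below any realistic rate and
does not affect real analyses. Per-entry rate overrides
$\alpha_{c,m},\beta_{c,m}$ are supported in the library API — they enter
only as constants, so nothing else changes; the command line exposes the
global rates only.

## From trees to matrices: the extended matrix

A Dollo(k) phylogeny is a rooted tree whose non-root nodes are labeled
with mutation gains $m^+$ or losses $m^-_l$; the state of a node is the
set of mutations gained but not re-lost on its root path, and a cell
attached at a node is predicted to carry exactly that state. Rather than
searching tree space directly, the search runs over the **extended
matrix**: one gain column and $k$ loss columns per mutation, with the
defining identity $F(c,m) = E(c,m^+) - \sum_{l\le k} E(c,m^-_l) \in
\{0,1\}$. A complete binary matrix corresponds to a directed perfect
phylogeny exactly when no two columns are *in conflict*, i.e. no pair of
columns exhibits all three of the row configurations $(0,1)$, $(1,0)$ and
$(1,1)$; applying this criterion to the extended matrix characterizes the
matrices $F$ explainable by a Dollo(k) tree. `is_conflict_free()` and
`check_dollo_completion()` implement the two halves of this reduction.

Conflicts are checked on unordered column pairs — the $(0,1)$
configuration on $(p,q)$ is the $(1,0)$ configuration on $(q,p)$ — which
halves the bookkeeping without changing the feasible set. All distinct
column pairs participate, including a mutation's own gain/loss pairs;
those pairs can never become conflicting (a loss implies its gain in every
cell, so the $(0,1)$ configuration cannot arise) and therefore cost
nothing.

## The exact search

`build_model()` assembles the full 0–1 program: binary $E$ over extended
columns, linked binaries $F$, and per-pair configuration indicators $B$
with activation constraints and the cap $B_{01}+B_{10}+B_{11}\le 2$; the
objective is the linearized likelihood. `solve_ilp()` optimizes it with
the package's own exact branch-and-bound, written for this structure:

* **Branching unit.** For each (cell, mutation) pair the extended row
  fragment has exactly $k+2$ feasible states — absent; present; or gained
  and lost via copy $l$. This enumerates precisely the assignments
  satisfying the linking constraint, so the $F$ variables never need to
  be branched on.
* **Constraint propagation.** Configuration counters per unordered column
  pair are updated incrementally as entries are assigned; a branch is
  abandoned the moment some pair accumulates all three configurations.
  This enforces exactly the $B$-constraint block (a $B$ variable is 1 iff
  its configuration count is positive), without materializing the
  $\Theta(n m^2 (k+1)^2)$ constraints.
* **Bound.** Running objective plus the suffix sum of per-entry maxima —
  admissible, and tight on low-noise data where the per-entry optimum is
  almost always feasible.
* **Incumbent.** The all-zero completion (every cell at the germline) is
  feasible for every input, including under a loss cap, and is installed
  as the initial incumbent; a timeout therefore always returns a feasible
  solution, with status `"feasible-timeout"` instead of `"optimal"`.
* **Symmetry.** Loss copies of one mutation are interchangeable, so a
  cell may only reuse an open copy or open the lowest-indexed unused one.
  This prunes relabelings of identical solutions; it never removes an
  optimum.
* **Loss cap.** `max_losses` bounds the number of *realized* loss columns
  (columns carried by at least one cell — equivalently, loss nodes of the
  resulting tree); the search skips options that would open a column
  beyond the budget.

The search is deterministic: option order is by objective contribution,
ties broken toward the absent state and lower loss copies, and entries are
visited row-major. Every returned solution is re-checked in R:
conflict-freedom, the extended-matrix identity, and agreement of the
solver objective with an independently recomputed likelihood to $10^{-6}$.

Exact search is exponential in the worst case — the underlying decision
problem is NP-complete — so noisy instances beyond roughly a thousand
entries should be run with a `timeout`; the incumbent is then the starting
point for hill climbing, which does the heavy lifting on large inputs.

## Extracting a tree

`tree_from_extended_matrix()` is the classic directed perfect-phylogeny
construction: nonzero columns sorted by decreasing count of 1s, ties
broken by original column order; identical columns share one edge,
realized as a chain of single-label nodes in column order; all-zero
columns (unused loss copies, never-observed gains) are simply absent. The
construction is deterministic, so tests can be bit-exact. When several
distinct trees explain the same matrix — a real phenomenon once losses are
allowed — the package treats the matrix, not the tree shape, as the object
of correctness: extraction is validated by reproducing every row's
genotype from its node state.

Cells may attach to any node, not only leaves: attaching to an internal
node is equivalent to attaching to an implicit empty leaf child and keeps
trees uncluttered. `best_attachment()` scores all nodes per cell in one
matrix product and breaks ties toward the smallest node id; because cells
are independent, per-cell optimality is global optimality for a fixed
tree.

## Hill climbing

The SPR neighborhood of a tree (prune the subtree at $u$, reattach under
$v$) is quadratic in tree size, so each iteration samples
`neighbor_samples` = N random valid moves uniformly (by enumeration of the
valid pairs, which is exact and cheap at these sizes) and evaluates each
by `best_attachment()`. A move can strand loss nodes — their mutation is
no longer gained above them, or a second loss of the same mutation now
precedes them; these are contracted in a single top-down pass that
re-derives validity from the running state, which handles cascades
correctly. Contraction is checked over the whole tree, not only the moved
subtree: reattachment can in principle invalidate a loss outside the
moved part, and checking both sides is free and always safe. Since loss
nodes are only ever removed, every neighbor is again Dollo(k).

Acceptance is strict — plateaus do not move, preventing seed-dependent
drift across equally scoring trees — and the search stops after
`max_iterations` = M batches regardless of acceptance. Defaults N = 30,
M = 100 let a 100-cell × 30-mutation refinement finish in about half a
minute; the acceptance checks in the test suite use M = 30 for the same
instance size, which is already enough to improve a 10-second incumbent
substantially. With a fixed seed the whole trajectory is reproducible.

## The simulator

`simulate_scs()` emulates the benchmark generation protocol: a random
clonal tree of S subclones grown by uniform parent choice; each mutation
assigned to a uniform subclone (multi-gain subclones become chains in
mutation-index order; empty subclones share their parent's node); then
`n_deletions` loss nodes, each attached as a new child of a uniformly
chosen clone-level node that still carries an eligible mutation, deleting
a uniformly chosen mutation present in the parent's state and not deleted
before — so deleted mutations are pairwise distinct and the ground truth
is Dollo(1) by construction. Cells attach uniformly with replacement over
the clone-level nodes — germline, subclones and deletion nodes alike:
normal cells are real in published datasets, deletion clones must be
observable or losses would be unrecoverable, and an empty subclone keeps
its own sampling weight through its representative node. Noise is applied
per entry: flip by $\alpha$/$\beta$ first, then mask to missing with
probability $\gamma$ (the order is observationally irrelevant, since
masking hides the flip; masking last keeps the missing rate exactly
$\gamma$ for every entry). Defaults are the study conditions: S = 9,
100 cells × 30 mutations, 5 deletions, $\alpha = 0.1$, $\beta = 10^{-4}$,
$\gamma = 0.1$.

What the simulator does *not* emulate: doublets, clone-size-weighted cell
sampling, copy-number events beyond point losses of single mutations, or
locus-specific error rates. Passing tests on simulated data therefore
demonstrate correctness of the method under its own model assumptions,
not robustness to every artifact of real SCS data.

The deletion-placement distribution ("random positions") is stated only by
reference in the source protocol; uniform choice over eligible clone-level
nodes is this package's interpretation and is documented as such.

## Accuracy measures

`ad_f_measure()` and `dl_f_measure()` compare trees through their gain
nodes only, matching the fact that these standard measures ignore
deletions. A mutation pair is ancestor–descendant (ordered) when one gain
is a proper ancestor of the other, different-lineage (unordered) when
neither is; pairs gained at the same node fit neither definition and are
excluded from both universes (relevant only for trees imported from other
tools — this package's trees carry one label per node). Scores are
balanced F1 over preserved pairs. Conventions for degenerate cases: a
precision or recall with empty denominator is 1 when the other set is
empty too, else 0; F of (0, x) is 0. A mutation absent from an inferred
tree contributes its truth pairs as unpreserved, keeping recall honest.

## Numerical and testing choices

* Natural logarithms everywhere (the base cancels in argmax).
* Rate clamp $10^{-9}$; solver objective cross-check tolerance $10^{-6}$;
  strict-improvement epsilon $10^{-12}$ inside the search.
* Deterministic tie-breaks throughout: column order in extraction,
  smallest node id in attachment, option order in the search.
* Problem sizes in the test suite are chosen so every oracle is
  exhaustive where it claims to be: the solver is compared with a full
  enumeration of all Dollo(1) state families at 3 mutations × 4 cells
  (58 distinct families); noise-free recovery uses 5 subclones,
  30 cells × 8 mutations with 2 deletions; hill-climbing monotonicity
  uses ten full-size (100 × 30) instances with a 10-second solver budget;
  simulator statistics pool 100 full-size replicates, where the
  3-standard-deviation binomial bands on the empirical rates are about
  $\pm 0.003$.

## Known limitations

* Proving optimality on noisy instances is practical up to roughly a few
  hundred entries; beyond that, use a timeout and rely on the refinement.
  (The formulation itself is not the bottleneck; the problem is hard.)
* Without a loss cap the likelihood is indifferent between explaining an
  absent call by "never gained here" and "gained then lost", so solutions
  may realize more losses than the ground truth while fitting equally
  well; `max_losses` exists precisely to inject prior knowledge, at some
  cost in search difficulty.
* $\alpha$ and $\beta$ are inputs, not estimated from data.
* Tree comparison is mutation-centric; cell-lineage measures and
  deletion-placement accuracy are out of scope.
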