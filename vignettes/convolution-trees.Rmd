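---
title: "Exact inference on sums of discrete variables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact inference on sums of discrete variables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convtree)
```

## The inference problem

In mass-spectrometry proteomics, a peptide whose sequence occurs in
several proteins (a *degenerate* peptide) creates shared evidence: its
observation tells us something about every protein that could have
produced it, and those proteins compete to explain it ("explaining
away"). When a database contains many splice variants or close
homologs, essentially all proteins in a connected subgraph share
evidence, the moralized graph contains one giant clique, and generic
junction-tree inference is exponential in the clique size.

The saving structure is that, under the standard noisy-or emission
model, the shared data depend on the proteins only through *how many*
of them are present, not on which ones. `convtree` works with exactly
this structure: a problem is an ordered set of discrete leaves
$X_1, \dots, X_n$ (binary for protein inference, but any finite state
count is allowed), each with a prior and a folded unique-evidence
likelihood, plus one shared likelihood vector indexed by the total
$D = \sum_i X_i$ (or, with scaling nodes, $\sum_i c_i X_i$). The target
quantities are the per-leaf posteriors
$P(X_i = x \mid \text{data})$, the posterior distribution of the
total, and the probability of the data.

## The noisy-or evidence model

Each peptide has an emission probability $\alpha$ (a present parent
protein generates it), a noise probability $\beta$ (it appears with no
parent), and a PSM score $s$, the probability that it matched an
observed spectrum. The peptide is absent with probability
$(1-\beta)(1-\alpha)^x$ when $x$ of its parents are present, so the
likelihood of its data is

$$L(x) = s\,\bigl(1 - (1-\beta)(1-\alpha)^x\bigr) +
        (1-s)\,(1-\beta)(1-\alpha)^x .$$

`noisy_or_unique_likelihood()` evaluates this at $x \in \{0, 1\}$ for a
peptide unique to one protein; `noisy_or_count_likelihood()` evaluates
it at $x = 0, \dots, n$ for a peptide shared by $n$ proteins with
common parameters. That second form is the *clustering identity*:
marginalizing over which proteins are present is replaced by
marginalizing over the count. The test suite verifies the identity
against an oracle that enumerates present *sets* and multiplies
absence probabilities over the set, never using the count form.

```{r}
pep <- noisy_or_peptide(alpha = 1, beta = 0, score = 0.35)
noisy_or_unique_likelihood(pep, states = 2)
```

## Three exact engines

All three engines consume the same `adder_problem` and return the same
`posterior_result`; they differ only in cost.

**Power-set enumeration** (`posteriors_by_enumeration()`) visits every
joint configuration, weighting it by
$\prod_i \pi_i(x_i)\,u_i(x_i) \times S(\sum_i x_i)$, and accumulates
the evidence and every per-leaf numerator in a single pass. It is the
correctness oracle for everything else and refuses state spaces larger
than $2^{22}$. Per-leaf weights are normalized with a tracked log scale
so the joint table cannot underflow near that cap.

**Quadratic forward–backward** (`posteriors_chain()`) unrolls the sum
one leaf at a time over layers of partial sums, with edge weights
$w_i(x) = \pi_i(x)\,u_i(x)$:

$$\ell_{i+1}(k) = \sum_x \ell_i(k - x)\, w_{i+1}(x), \qquad
  r_i(k) = \sum_x r_{i+1}(k + x)\, w_{i+1}(x),$$

with $\ell_0$ a point mass at 0, $r_n$ initialized with the shared
likelihood, and out-of-bound indices treated as zero. The posterior is
the three-factor path sum
$P(X_i = x \mid \text{data}) \propto \sum_k \ell_{i-1}(k)\, w_i(x)\,
r_i(k + x)$ — there is no division by priors anywhere, so states with
prior 0 or 1 are handled exactly. Time and table space are quadratic
in $n$ for binary leaves. In raw (unnormalized) mode,
$\sum_k \ell_i(k) r_i(k)$ is the same total evidence at every layer,
a conservation law the tests check; the default mode renormalizes each
layer with a tracked log scale so the engine survives thousands of
leaves.

**The probabilistic convolution tree** (`posteriors_convtree()`)
replaces the chain by divide and conquer: leaves are paired
left-to-right, pairwise sums are paired again, and so on to the root,
which carries the total. Messages are whole distributions:

* *Down:* each node's joint-with-data-above is the convolution of its
  two parents' messages (base case: $\pi_i \odot u_i$ at the leaves).
* *Up:* the likelihood-given-data-below for the left parent is the
  correlation $\sum_r b(l + r)\,a_R(r)$ of the node's below-message
  $b$ with the right parent's above-message $a_R$ — a convolution with
  one operand reversed, sliced starting at index $|R| - 1$ to drop the
  shift (the up pass represents subtraction, which reverses indices).
  The slice bounds follow from requiring that output index $l$
  corresponds to $\text{sum} - \text{other} = l$; they are validated
  against the brute-force oracle rather than derived from any closed
  reference.
* Every posterior is the normalized elementwise product of a node's
  above- and below-messages.

Large dense convolutions go through the FFT, so the whole pass is
sub-quadratic in time and the stored messages total $O(n \log n)$
— the package asserts both *structurally* (a global multiply-add
counter and a message-length census) rather than by wall clock.

```{r}
p <- generate_problem(6, seed = 3)
cmp <- compare_engines(p)
cmp$decimal_places
```

## Numerical choices

* **Message normalization.** Only proportionality matters between
  layers, so every inter-layer message is normalized; the discarded
  scales accumulate in log space and `log_evidence` is reported from
  the root contraction. This keeps a 32768-leaf problem comfortably in
  double precision.
* **FFT versus direct convolution.** Direct convolution is used when
  the shorter operand has fewer than 64 entries or either operand has
  less than 10% nonzero density; otherwise the FFT path is taken
  (padded to a power of two). The two paths agree entrywise to
  `1e-10` and the choice never affects results, only cost. A hybrid
  strategy for vectors decomposable into non-overlapping dense blocks
  would be faster still for structured sparsity; only the
  dense/direct heuristic is implemented.
* **Round-off hygiene.** FFT output of nonnegative inputs can dip
  microscopically below zero; entries with magnitude below
  $10^{-12}\times$ the largest weight are clipped to zero, while a
  larger negative raises an internal-consistency error instead of
  flowing into "probabilities".
* **Contradictions.** An all-zero message (evidence that excludes
  every achievable value) aborts with an error naming the node, from
  `pmf_normalize()` upward.
* **Scaling nodes.** Multiplying a leaf by an integer $c$ permutes and
  pads its support (`pmf_scale_support()`); each scaling node stores
  that permutation so the backward step is a table lookup — an exact
  inverse with no extra convolution and no round-off. $c = 0$
  detaches the input.
* **Counting mode.** `count_tuples()` runs the same tree with
  unnormalized integer weights and forces direct convolution, so
  counts are exact integers, then read per-variable solution counts
  off the up pass.

## Padding and tree shape

When $n$ is not a power of two the leaf layer is padded with dummy
variables whose prior is a point mass at 0 with no evidence, which
provably changes nothing: a point mass at zero is the identity element
of convolution. The dummies here are *single-state* leaves (support
$\{0\}$), so the padded supports are exactly the real supports and no
truncation or renormalization of internal posteriors is ever needed;
the padding-invariance tests compare the padded tree against the
unpadded enumeration oracle at $n \in \{3,5,6,7,9\}$. Leaves are
paired in input order — any pairing is exact, so determinism wins.
Padding at most doubles the leaf count and does not change the order
of the runtime.

## Cascades, 2-D problems, and counting

Evidence need not all hang off one total. A `cascade_spec()` describes
adders over subsets of inputs — including other adders — with optional
integer coefficients per edge and an evidence likelihood on any
adder's value. Down messages multiply each input's contribution by its
own evidence before convolving; up messages multiply the incoming
likelihood by the node's evidence before correlating with the sibling.
The cascaded structure must be a tree: a node feeding two adders
creates a loop after moralization, which this engine rejects by
pointing at the offending node (merging such variables or embedding
the tree in a junction tree is deliberately out of scope). Adders with
more than two inputs are expanded into balanced pairwise sums
internally.

The 2-D variant (`posteriors_convtree_2d()`) is the same algorithm
with two-dimensional convolutions on the way down and 2-D correlations
with a contiguous submatrix slice on the way up — useful when each
variable carries two additive quantities at once, such as a
discretized mass and a valence in elemental decomposition. The
algorithm generalizes to any dimension the same way.

## The problem generator

`generate_problem()` emulates the randomized benchmark conditions the
engines are compared under: $n$ binary proteins, one unique noisy-or
peptide each with $\alpha$, $\beta$, and PSM score drawn uniformly
from $[0, 1]$, protein-specific priors drawn uniformly from
$[10^{-6}, 1 - 10^{-6}]$, and shared evidence that is by default an
arbitrary categorical likelihood over the count $0..n$ (uniform
entries, normalized to sum to one). The prior bounds keep no state
exactly impossible while still exercising numerical stability at
extreme priors; the full-width uniform ranges are the least
informative choice for benchmarking and are configurable and recorded
in the generator metadata of every problem file. A model-faithful
`"shared-peptides"` mode instead multiplies the count likelihoods of
1–9 shared noisy-or peptides (a uniform integer draw).

What the generator does *not* emulate: real search-engine score
distributions (which are far from uniform), peptides shared by
*subsets* of proteins (expressible via cascades, but not generated
randomly), correlated priors, and database-level graph structure.
Passing tests therefore demonstrate algorithmic exactness under the
stated model, not end-to-end identification accuracy on real spectra.

## Problem sizes used by the checks

The shipped verification suite runs the three-way comparison on twenty
generated problems with $n \in 2..12$, cross-checks chain against
convolution tree at $n \in \{64, 256, 1024\}$ over five seeds each,
validates scaling/cascading/2-D/counting against exhaustive
enumeration at oracle-friendly sizes ($n \le 8$ leaves, up to six
counting variables), asserts the structural space and work laws at
$n = 1024$ and $2048$, and completes one $n = 32768$ problem to
demonstrate desk-scale reach where a quadratic table would need on the
order of $10^9$ cells. These sizes were chosen so the whole suite runs
in a few minutes on one core while still crossing the boundary where
enumeration and the quadratic engine stop being usable.

## Known limitations

* Loopy cascades (a node feeding two adders) are rejected, not solved;
  junction-tree integration with convolution-tree cliques is out of
  scope.
* Supports are dense contiguous integer ranges; very sparse or
  continuous quantities must be discretized and may waste space.
* The evidence accumulates in log space but individual likelihood
  vectors are plain doubles; likelihoods spanning more than ~300
  orders of magnitude within one vector will underflow.
* Wall-clock timings reported by `compare_engines()` and
  `bench_engines()` are informational; no test asserts them.
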