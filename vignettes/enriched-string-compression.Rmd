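---
title: "Compressing k-mer sets as enriched string sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressing k-mer sets as enriched string sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esskit)
```

## The model

A canonical k-mer set *K* (odd k, so no k-mer equals its own reverse
complement) is classically stored as a spectrum-preserving string set
(SPSS): strings of length ≥ k whose k-mer content is exactly *K*, once
each. Any SPSS induced by a vertex-disjoint path cover Ψ of the compacted
bidirected de Bruijn graph has weight (total characters)

$$ weight = |K| + |\Psi|\,(k-1), $$

because each of the `n − |Ψ|` cover edges glues away one duplicated
(k−1)-mer. A cover, however, can use at most two edges per vertex; at
branching vertices the remaining edges still witness duplicated
(k−1)-mers. `esskit` removes those too, by *absorbing* whole paths into
other paths and replacing each absorbed path's redundant (k−1)-prefix
with a one-character marker:

* `[` ... `]` delimit an embedded (absorbed) child string;
* `+` stands for the k−1 outer characters immediately left of the `[`;
* `-` stands for their reverse complement.

An edge of the compacted graph qualifies as an *absorption edge* when it
connects an **internal** vertex of one cover path (the parent) to an
**endpoint** vertex of another (the child), attached at the child's outer
side so the shared (k−1)-mer is removable from the child's spelling
boundary. Per absorption the representation trades k−1 nucleotides for 3
characters — a saving of k−4.

Absorptions must form a forest: each path absorbed at most once, no
cycles. Among all spanning out-forests of the absorption digraph D
(paths as nodes, parent→child arcs), the encoder uses one with the
maximum number of arcs. The optimal construction condenses D into its
strongly connected components, takes one "starter" node from each source
component, and grows a depth-first forest from the starters; the forest
then has exactly `n_sc` trees (the number of source components), which is
simultaneously the minimum tree count and the maximum arc count. The
output therefore satisfies, exactly,

$$ weight = |K| + 3\,|\Psi| + n_{sc}\,(k-4), $$

which the encoder asserts on every run, alongside the instance lower
bound $|K| + 3\beta + C(k-4)$ (β a path-cover lower bound, C the number
of connected components) that no admissible cover/absorption scheme can
beat.

```{r}
K <- kmer_set(c("TCG", "CGT", "GTT", "GTA", "TAA"), k = 3)
ess_compress(K)
```

## Orientation conventions

Everything downstream of the k-mer counter works on a bidirected graph:
each vertex has two sides, side 0 at the front of the forward label and
side 1 at the back. A path step visits a vertex in an orientation `o`
(0 = forward, 1 = reverse complement); the occurrence's front is side
`o`, its back side `1−o`, and consecutive steps `(u,o_u) → (v,o_v)` use
the edge `{(u, 1−o_u), (v, o_v)}`. From this single rule follow the
greedy cover's side bookkeeping, the absorption-edge eligibility test,
and the insertion geometry of the encoder:

* an absorption edge on the **back** side of the parent occurrence sees
  the shared (k−1)-mer verbatim in the parent spelling → marker `+`;
* on the **front** side it sees the reverse complement → marker `-`;
* the child is flipped so the removable (k−1)-mer is its spelling's
  prefix, and the bracket group is spliced immediately after the shared
  occurrence, so the decoder's rule — replace markers, then hand each
  bracket group the rightmost k−1 *outer* characters left of its `[` —
  inverts the construction. Sibling groups spliced at one point do not
  interfere, because bracketed characters are not outer characters.

Splices are applied right-to-left so positions stay valid, and the
parent's own prefix→marker substitution happens last; insertion points
always lie at index ≥ k because the parent vertex is internal, so they
never fall inside the substituted prefix. When the shared (k−1)-mer is
its own reverse complement (possible, as k−1 is even) both markers
decode identically and `+` is chosen.

## The greedy cover

The cover is built by scanning the compacted graph's edges in
lexicographic order of (smaller endpoint label, larger endpoint label,
side pair) and merging the two incident paths whenever the edge joins
currently-free outer endpoint sides of two distinct paths. This is a
deterministic path-cover heuristic of the same family and asymptotic
quality as published greedy covers; exact string-for-string parity with
any particular published tool is not a goal (set-level output equality
and the weight identities are). Paths are stored flip-normalized
(smaller of first/last label first) and vertices are content-addressed
by their canonical labels, so every stage is deterministic without
seeds.

The lower bound β is computed from dead-end sides: every edge-free side
must be an exposed path endpoint, each path exposes two, and each
connected component needs one path, giving
`β = Σ_components max(1, ⌈d_c/2⌉)`. This is a valid bound but can be
looser than matching-based bounds from the literature; bound-gap numbers
reported by this package are therefore conservative (the gap can read
larger than published gaps on comparable data).

## Tip-restricted mode

`ess_tip_compress()` trades compression for simplicity: only *dead-end*
vertices (tips — one edge-free side, typically sequencing-error
artifacts, transcript ends, or coverage gaps) are absorbed, each into an
adjacent non-dead-end vertex. Tips get dedicated singleton paths; the
greedy cover runs on the tip-free subgraph; the forest has depth ≤ 2, so
brackets never nest and no recursion is needed. The encoding drops the
marker: a bracket group implicitly means "the k−1 outer characters to my
left, then my content" — 2 characters per absorption.

One design decision deserves a note, since published descriptions of
this scheme leave the 2-character encoding's details open. Under the
prepend-only decoding rule just stated, a tip whose shared (k−1)-mer
lies at the *front* of the neighbouring occurrence is not encodable: the
characters preceding any insertion point adjacent to that vertex are the
reverse complement of every prefix the reoriented tip can present. (No
marker means no way to signal "reverse complement of the context".)
`esskit` therefore only absorbs tips attached at the *back* of their
neighbour's occurrence, choosing per tip the smallest eligible
neighbour/edge, and leaves the rest as roots — an extension of the
"skip tips with no eligible neighbour" rule. The cost is bounded: an
unabsorbed tip keeps its full spelling, and the mode remains strictly
better than its own cover's SPSS whenever any absorption happens. A
chain with tips on both ends, for instance, absorbs exactly one of them
(the two tips sit on opposite sides of the middle occurrence). There is
no closed-form weight theorem for tip mode; the implementation instead
verifies `weight = |K| + |Ψ|(k−1) − (k−3)·(#absorbed)` by direct
accounting on every run.

```{r}
fx <- fixture_graphs()$tip_chain
K <- kmer_set(fx$g$labels, fx$k)
ess_tip_compress(K)
```

## Synthetic data

The simulator emulates the regime the method targets: a uniform random
genome, uniform read starts, both strands equally likely, i.i.d.
substitution errors. Defaults (100 kb genome, 100 bp reads, coverage 10,
1% error, k = 21) produce compacted graphs with a large fraction of
dead-end unitigs, the structure that separates the full encoder, the tip
encoder, and plain unitigs. These are the conditions used by the test
suite and `scripts/acceptance.R`; they were chosen once as a realistic
desk-scale stand-in for read datasets — small bacterial-scale coverage
and error figures — and the problem sizes keep the whole suite in the
minutes range. What the simulator does *not* model: indels, quality
values, non-uniform coverage, repeats beyond chance, paired ends. Tests
passing on this generator therefore validate the algorithms and their
identities, not performance claims on real libraries.

Hand-built fixtures (`fixture_graphs()`) pin down the encoder's corner
cases independently of the greedy cover, by injecting forced covers: a
single absorption (`TCGT[+AA]T`), multiple children of one vertex
(consecutive bracket groups, one with a `-` marker), three-level
recursion, a mutual-absorption 2-cycle (resolved by the SCC machinery),
tip chains, isolated vertices, and a perfect-cycle component (broken
deterministically at its smallest label, since a pure cycle has no
maximal-unitig decomposition otherwise).

## Numerical and degenerate-input choices

* **Odd k only.** Even k admits self-reverse-complementary k-mers, for
  which "canonical" is ill-defined; rejected at the API boundary.
* **Ambiguous bases** split input sequences into ACGT-only runs
  (k-mer-counter convention) rather than erroring.
* **Loops** (a vertex overlapping itself, including palindromic-boundary
  loops) are kept as edges but never extend unitigs, never merge cover
  paths, and never absorb.
* **Perfect cycles** break at the lexicographically smallest label.
* **Counting is exact and in-memory**; abundance filtering is a simple
  `count ≥ min_count` threshold.
* The decoder is iterative (explicit stack) so deeply nested outputs
  cannot exhaust the call stack; the encoder assembles strings bottom-up
  in decreasing forest depth for the same reason.

## Known limitations

* The greedy cover is a heuristic; `|Ψ|` (hence the weight) is near- but
  not provably minimal, and β is a conservative bound, so reported
  bound gaps overstate the true distance to optimal.
* Tip mode's back-side eligibility rule (above) absorbs a subset of the
  tips a 3-character encoding could.
* In-memory processing targets desk-scale data (up to a few hundred
  thousand k-mers comfortably), not multi-terabyte k-mer databases.
* The package writes plain text (optionally gzip/xz-wrapped); no
  specialised nucleotide entropy coder is integrated.
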