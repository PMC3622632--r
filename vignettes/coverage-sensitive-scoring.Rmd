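---
title: "Coverage-sensitive scoring of predicted genome templates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-sensitive scoring of predicted genome templates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagescore)
```

## The problem

Short-read data cannot, by itself, disambiguate genomic regions built
from long, highly similar repeats — the KIR cluster on human 19q13.4 is
the canonical example, with haplotypes that differ in gene presence and
copy number while all genes share substantial sequence identity. When a
*predicted* sequence (a "template": the output of an assembler, a
database haplotype, or a hand-built hypothesis) is to be judged against
a read set, the obvious score — sum over reads of the best alignment
cost — is blind to a crucial signal: a template with a spuriously
duplicated repeat absorbs the repeat's reads perfectly well, it simply
absorbs them at the *wrong coverage*. Two templates can tie on
alignment quality while only one of them explains where the reads
actually pile up.

`sagescore` scores a template by jointly optimising alignment quality
and coverage plausibility, and ships a synthetic generator of
repeat-structured haplotypes so the whole pipeline can be exercised and
tested without any external data.

## The model

Reads form a set $X$, template segments a set $Y$. A *many-to-many
matching* $M \subseteq X \times Y$ selects (read, segment) pairs, and
its cost is

$$w(M) = \sum_{(x,y) \in M} w_m(x,y) \;+\; \sum_{z \in X \cup Y} w_c(z, c_M(z)),$$

where $c_M(z)$ is the number of pairs incident to $z$, $w_m$ is the
alignment cost of placing read $x$ in segment $y$ (infinite for
non-candidates), and $w_c(z, i)$ charges element $z$ for being covered
$i$ times. The template's score is the minimum of $w(M)$ over all
matchings — lower is better. In the genomic instantiation:

* each read pays `unmatched_penalty` (default 100) at coverage 0, zero
  at coverage 1, and is forbidden (infinite cost) beyond — a read maps
  at most once;
* each segment of length $\ell$ pays $f(i) = |\lambda - i|^p$ at
  coverage $i$, with expected coverage
  $\lambda = \ell \cdot |R| / |G|$ (reads times segment share of the
  genome), exponent $p = 2$ by default;
* $w_m$ is the cheapest candidate placement of the read starting inside
  the segment: per mismatch cost 30, concordant mates summed, a
  lone/discordant end surcharged by 90 (the cost of a fully mismatched
  100 bp end), giving per-pair costs in $[0, 180]$ plus surcharges.

This is a strict generalisation of classical bipartite matching: with
edge costs $-1$ and coverage costs $\{0{:}0, 1{:}0, \ge 2{:}\infty\}$
the optimum is minus the maximum matching size
(`encode_bipartite_matching()`). The general problem is intractable,
but all cost tables above are *convex* in the coverage, and the convex
case reduces exactly to min-cost integer flow.

## The exact solver

`build_network()` lays out a five-layer network
$s \to C^X \to X \to Y \to C^Y \to t$. The $i$-th difference edge of
element $z$ carries cost $w_c(z,i) - w_c(z,i-1)$ with unit capacity, so
pushing $k$ units through $z$ accumulates exactly
$w_c(z,k) - w_c(z,0)$ — *provided* cheaper difference edges fill
first, which convexity guarantees (difference costs are non-decreasing;
this is asserted at build time). Candidate edges $(x, y)$ carry
$w_m(x,y)$. With $\Delta = \sum_z w_c(z, 0)$ the cost of the empty
matching, a minimum-cost flow $f^*$ of *unconstrained value* satisfies
$\mathrm{score} = w'(f^*) + \Delta$, and the optimal matching is read
off the saturated $(x,y)$ edges.

Numerical and design choices:

* **Free flow value.** The solver (`min_cost_free_flow()`, Rcpp)
  augments along successive shortest paths while the cheapest residual
  $s$–$t$ path is negative; path costs are non-decreasing over
  augmentations, so stopping at the first nonnegative path minimises
  over all flow values. Negative edge costs are the *normal* case here
  (an unmatched-read penalty appears as a $-100$ difference edge), so
  initial node potentials come from a Bellman–Ford pass over the
  topologically ordered edge list; Dijkstra with reduced costs and
  early exit at the sink runs thereafter.
* **Infinite costs are absent edges.** Coverage beyond a table's end
  (e.g. a read covered twice) and non-candidate pairs are represented
  by omitting edges, never by big-M costs; exactness is preserved and
  the network stays small.
* **Determinism.** Nodes and edges are laid out in a fixed order
  (reads by id, segments by coordinate, difference layers by index) and
  heap ties resolve by node index, so repeated runs return the
  identical matching. An instance with no candidate pairs degenerates
  to an edgeless network whose optimum is the empty matching.
* **Self-check.** After every solve, the score is recomputed directly
  from the returned matching via the cost function; a relative
  discrepancy beyond $10^{-6}$ raises an internal-consistency error.
* **Oracle.** `brute_force_csm()` enumerates all $2^{|pairs|}$
  subsets (bound: 20 pairs) and is the independent ground truth the
  solver is tested against on hundreds of random convex instances; ties
  break lexicographically for reproducibility (any optimal matching is
  equally valid; the tie rule exists only so tests are stable).

The solver's complexity is one shortest-path run per matched read,
which on the published scale (~25,000 reads, 166 segments, ≤ 10
candidates per read) completes in minutes on one CPU in this
implementation; the tests include exactly that scale.

## From alignments to an instance

`load_placements()` accepts SAM/BAM (SAM converted on the fly via
`Rsamtools::asBam`): one record per candidate placement of each end,
per-end cost in a configurable tag (default `XC`), candidates linked by
`HI`, concordance taken from the proper-pair flag. Positions are
0-based half-open internally; a placement belongs to the segment
containing the leftmost aligned base of the *first mate*, regardless of
strand, even when the alignment extends past the segment boundary.
Several placements of one read inside one segment collapse to the
cheapest. Unmapped reads are retained — they matter, because they pay
the unmatched penalty. Diploid templates are scored as the
concatenation of their two haplotypes (multi-record FASTA inputs are
concatenated; multi-reference SAM positions are offset by header
order), the simplest reading consistent with the global
$\lambda = \ell |R| / |G|$.

Decisions the alignment format does not pin down, exposed as
parameters rather than guessed: the concordance window is
`insert_mean` ± 4 `insert_sd` with opposing orientations (shared by the
simulator's mapper and the SAM reader); a read pair whose ends both map
but never concordantly contributes one surcharged placement *per mapped
end*; the naive baseline uses the same placement costs (including
discordant surcharges) so the two scores share a scale, and unmapped
reads contribute the unmatched penalty to the naive score too —
without that, the naive score would reward templates that fail to map
reads.

## The baseline and the outputs

`naive_score()` is the coverage-blind comparator: sum of each read's
best placement cost. `score_template()` returns both scores, the
optimal matching, and the per-segment coverage profile (counts,
$\lambda$, and mean squared deviation). `rank_templates()` orders
candidate templates ascending; `normalize_second_best()` rescales a
score row so the second-best lands at 1 and the worst at 0 — the scale
on which a template would be judged if the truly best one were absent
from the database. Degenerate rows are defined explicitly: two-template
rows map best to 1 and worst to 0; an all-equal row maps to all 1.

## What the simulator emulates — and what it does not

`make_block_library()` models a repeat family as mutated copies of one
random ancestor; the per-copy substitution rate $\mu$ is solved from
the target pairwise identity $p$ via
$(1-\mu)^2 + \mu^2/3 = p$ (two copies agree at a site if neither
mutated, or both mutated to the same base). All blocks in a library
share one length so identity is measurable on the ancestor frame.
`haplotype_architecture()` + `render_haplotype()` compose blocks with
deterministic spacers into haplotypes that differ in block presence and
copy number — the KIR-like situation. `simulate_reads()` draws pair
counts from a Poisson at the target coverage, insert sizes from a
truncated normal (400 ± 40 by default), and substitutes bases uniformly
at 0.5% by default. `exhaustive_map()` reports *every* placement of
every end within 3 mismatches (pigeonhole seed-and-extend: of $k+1$
disjoint seeds, one must be exact), mirroring an all-alignments mapper
run.

Defaults mirror the published experimental setting: 100 × 2 bp pairs,
mismatch cost 30 with at most 3 mismatches per end (hence the 0–180
per-pair range and the 90 discordant surcharge), 1000 bp segments,
unmatched penalty 100, quadratic coverage cost.

Deliberately *not* modelled: indels and structural read errors (the
mapper is Hamming-exact, which keeps the cost scale interpretable),
empirically calibrated error profiles, base-quality emission beyond a
placeholder, and GC or positional coverage bias. A green test on this
generator therefore establishes the *method* — that joint
alignment + coverage optimisation separates architectures that
alignment alone cannot — not performance on any particular instrument's
reads.

## Known limitations

* Non-convex coverage costs are out of scope; only the brute-force
  oracle can evaluate them, and only at toy sizes.
* The alignment cost scale of real mappers varies by tool and version;
  real BAM input needs a cost tag on the stated 0–90 per-end scale
  (the parameter file documents the mapping).
* The solver's running time grows with the number of matched reads
  times shortest-path cost; far beyond the published scale (hundreds of
  thousands of reads) a specialised implementation would be warranted.
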