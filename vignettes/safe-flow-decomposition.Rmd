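---
title: "Safe and complete paths in flow decompositions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Safe and complete paths in flow decompositions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safeflow)
```

## The model

A *flow graph* is a DAG with a unique source $s$, unique sink $t$, positive
edge flows $f(e)$, and conservation $f_{in}(v) = f_{out}(v)$ at internal
vertices. A *flow decomposition* is a multiset of weighted $s$–$t$ paths
whose per-edge weight sums reproduce the flow; in RNA assembly the flow is
the superposition of a gene's transcripts and the decomposition sought is
the transcript set itself. Because decompositions are far from unique, a
decomposition-based assembler can report paths no transcript supports. The
safety framework inverts the question: report exactly the paths that occur
(as subpaths) in *every* decomposition.

A path $P$ is *$w$-safe* when every decomposition routes at least $w$ units
of flow through the whole of $P$, and *safe* when it is $w$-safe for some
$w > 0$. Safety here is a local property. Define the *excess flow* of
$P = u_1 e_1 u_2 \cdots e_k u_{k+1}$,

$$
f_P \;=\; f(e_1) - \sum_{i=2}^{k}\bigl(f_{out}(u_i) - f(e_i)\bigr)
      \;=\; f(e_k) - \sum_{i=2}^{k}\bigl(f_{in}(u_i) - f(e_{i-1})\bigr),
$$

the flow entering the path's first edge minus the worst-case leakage at its
internal vertices (equivalently, mirrored at the last edge). The two forms
agree by conservation, and $P$ is $w$-safe iff $f_P \ge w$. A single edge
has excess $f(e) > 0$, so every edge is safe. Appending an edge $(u, v)$ at
the end of a path reduces the excess by $f_{out}(u) - f(u,v) \ge 0$;
prepending reduces it by $f_{in}(v) - f(u,v)$. Excess is therefore
monotonically non-increasing under extension, which is what makes *maximal*
safe paths well defined and cheap to find.

`safeflow` asserts the diverging/converging identity on every excess-flow
evaluation, keeps a per-graph `safety_index` of $f_{in}/f_{out}$ so
verification is $O(|P|)$, and exposes the extension deltas directly
(`extend_delta`) for incremental scans.

## Enumeration

All maximal safe paths are found by scanning any flow decomposition with
two pointers. Every maximal safe path is, being safe, a subpath of some
path of the decomposition at hand; on each decomposition path the scan
grows a window on the right while the excess (updated in constant time via
the deltas) stays positive, emits the window when the right pointer is
stuck, and then advances the left pointer. A window is suppressed when its
right end does not exceed the previously emitted one: a safe window strictly
nested in a longer safe window is always right-extensible, so such windows
are exactly the duplicates the scan must skip. The emitted windows are the
host-maximal safe subpaths, each pointer advances at most once per edge,
and the whole scan is linear in the decomposition's total size.

Host-maximality is weaker than graph-maximality: a window stuck on its host
may extend through an off-host edge of higher flow. Such a window is,
however, a strict subpath of a maximal safe path that appears on *another*
host. Deduplication therefore removes any window whose edge-id sequence is
a duplicate **or an arbitrary contiguous substring** of another window —
interior containments included, not only prefixes and suffixes, because an
interior containment is precisely what a host-maximal-but-not-graph-maximal
window produces. After dedup the expanded window set equals the maximal
safe path set, independently of which decomposition seeded the scan (a
property the test suite checks by seeding with both the minimum-edge
peeling and greedy-width). Matching operates on edge-id sequences with
delimiters, so parallel edges and multi-digit ids are unambiguous.

The *concise representation* groups the surviving windows per host,
merging overlap-or-touch runs into one minimal-length host subpath plus
window offsets. On a worst-case family (ladder with a unit-flow crossbar
layer; `worst_case_graph`) every window spans its whole host and the
representation is as large as the decomposition; on a best-case variant
with two equal-flow parallel-edge pairs (`best_case_graph`) it collapses to
$O(n + m)$ while the decomposition grows superlinearly. The acceptance
suite measures both over ladder depths $k \in \{4, 8, 16\}$. The
published construction pins particular flows on the figure's side edges;
since only its asymptotic contract matters here, the package uses a
calibrated variant — unit flow on the crossbar edges, chain flows derived
by conservation — and tests the contract itself.

## Decompositions and baselines

Two decomposition algorithms are provided. *Minimum-edge peeling* extends
the globally smallest-residual edge to $s$ and $t$ through
positive-residual edges and peels it at that residual; the chosen edge is a
global minimum, so the peel is feasible and zeroes an edge, giving at most
$m$ paths. *Greedy-width* repeatedly peels the widest (maximum-bottleneck)
path, found by dynamic programming over the topological order. All
tie-breaks — minimum-edge selection, extension steps, widest-path
predecessors, topological order — resolve to the smallest edge or vertex
id, so both algorithms are deterministic without a seed. The published
experiments use the Catfish implementation of greedy-width, whose tie rule
is unspecified; on tied instances the two may differ, though both are valid
by the decomposition verifier.

The safe baselines are *unitigs* (maximal paths whose internal vertices
have unit in- and outdegree) and *extended unitigs*: every edge is extended
left while its first vertex has indegree exactly 1 and right while its last
vertex has outdegree exactly 1, then substring-deduplicated. The extension
is purely degree-based, yet every extended unitig has positive excess. A
DAG is a *funnel* when no merge vertex (indegree $\ge 2$) reaches a fork
vertex (outdegree $\ge 2$), including the degenerate same-vertex case;
detection is a single marking sweep in topological order. On funnels the
flow decomposition is unique and extended unitigs are already safe and
complete — both directions of this equivalence are exercised empirically on
generated funnels and non-funnels.

## Metrics

Following the subpath-based evaluation used for partial assemblies rather
than the exact-match precision of assembler benchmarks: a reported path is
*correct* if it is a subpath of some ground-truth transcript; *weighted
precision* is the length of correct reported material over all reported
material. *Maximum relative coverage* of a transcript is the longest single
contiguous stretch of any one reported path inside it, relative to its
length, averaged over transcripts — segments are never merged across gaps
or across paths. The *F-score* is the harmonic mean, 0 when both terms are
0. Lengths count vertices in node mode or sum per-vertex base lengths in
base mode, and the artificial global source/sink are stripped before any
comparison so they inflate nothing. In base mode the longest stretch is
maximized in bases directly, since the base-longest and node-longest
stretch can differ. An empty report has precision 1 (vacuously correct) by
convention, so degenerate inputs do not break the safe algorithms' precision
invariant. The metrics layer works on vertex sequences and rejects graphs
with parallel edges; splice graphs built by superposition are always
simple.

Because the simulated ground truth is itself a flow decomposition, every
safe path is a subpath of some transcript, so both safe algorithms have
weighted precision exactly 1 on every error-free instance. This is kept as
a tested invariant (and recomputed by `scripts/acceptance.R`) rather than
assumed.

## The simulator

`simulate_splice_instance` emulates error-free splice graphs: an ordered
backbone of exons (backbone size uniform on 10–30), transcripts as distinct
increasing exon subsequences (each exon skipped independently with
probability 0.3; duplicates redrawn), abundances drawn lognormally and
superimposed, with a global source/sink. The published simulation protocol
samples expression from a lognormal with "mean and variance" both $-4$; a
negative variance is impossible, so the package follows the simulator that
protocol cites and reads the parameters as log-space location $\mu = -4$
with $\sigma^2 = 4$ — both configurable. Raw abundances are scaled by 1000
and integerized as $\lfloor \cdot \rceil + 1$ so all flow arithmetic is
exact; a float mode retains the raw draws for stress tests. Exon base
lengths are uniform on 50–300 bp, a typical exon-length range. With a fixed
seed the instance is reproduced byte for byte, and the generator draws in a
documented order (backbone size, transcripts, abundances, lengths).

What the simulator does *not* emulate: read errors and coverage noise (the
graphs are exact superpositions), genomic exon coordinates from real
annotation, and the empirical transcript-per-gene and splice-pattern
distributions of the human transcriptome. Consequently coverage and
F-score levels on simulated datasets depend on the chosen ensemble and are
not comparable to numbers computed on annotation-derived datasets; the
dataset-independent claims — perfect safe precision, the funnel
equivalence, the coverage dominance of the complete safe set over extended
unitigs — are what the tests establish. Datasets are simulated with
complexity $k$ uniform on $[2, 35]$, the complexity range over which the
published evaluation stratifies, and funnel instances (trivial for every
algorithm) are filtered out by default, with their encountered fraction
reported.

## Numerical choices and degenerate inputs

Integer weights are detected automatically; whole-number doubles are exact
under the additions/subtractions performed here (magnitudes stay far below
$2^{53}$), so integer mode compares excess flows, conservation and
decomposition residuals exactly. Otherwise a relative tolerance of
$10^{-9}$ (scaled by total flow) applies to conservation checks, safety
thresholds and residual tests. Paths are nonempty edge-id sequences;
zero-edge paths are rejected everywhere, as safety of a bare vertex is
undefined. Graphs with several sources or sinks are rejected unless
explicitly augmented with a global source/sink carrying each original
terminal's flow, the same construction the simulator uses. Zero-flow
graphs cannot be represented (weights must be positive), so the
decomposition verifier treats an empty path set as valid only for an
edgeless graph.

The brute-force oracle used in testing enumerates *all* integer flow
decompositions as nonnegative integer weightings of the full
source-to-sink path list satisfying the per-edge flow equations — complete
and duplicate-free by construction — and answers $w$-safety straight from
the definition. It is exponential and guarded (total flow $\le 8$, $m \le
12$ by default); the guard sizes keep the acceptance sweep of 200 random
graphs within a couple of minutes while still covering thousands of
path/weight queries.

## Problem sizes used by the tests

Unit and property tests run on the hand-checked fixtures, a few hundred
guarded random graphs, and simulated instances with $k \le 20$. The
acceptance checks use 200 oracle-guarded random graphs for the
verification/enumeration equivalence, $10^4$ random paths for the
formulation identity and the incremental-update identity, 100 funnels and
100 non-funnels for the completeness equivalence, ladder depths
$\{4, 8, 16\}$ for the scaling contrast, and a 200-instance simulated
dataset for the dataset-level precision of the safe algorithms. These
sizes were chosen as the smallest at which each property is exercised
across its combinatorial variety.

## Known limitations

* The enumeration is linear in the decomposition size $\lVert P \rVert$,
  not output-sensitive; beating that bound requires abandoning
  decomposition-seeded scans altogether.
* Expanding the concise representation can be quadratically larger than
  the representation itself; evaluation pipelines that accept windows
  should prefer them.
* The metrics layer requires simple graphs (no parallel edges), matching
  splice-graph instances; the safety and enumeration layers fully support
  parallel edges.
* Funnel *contraction* (reducing funnels to single-path instances) is not
  implemented — funnels are detected and filtered only.
* Path-cover-based safety and global max-flow-based verification are out
  of scope; the excess-flow criterion subsumes the latter's role here.
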