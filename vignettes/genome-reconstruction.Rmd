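---
title: "Reconstructing rearranged cancer genomes from interval adjacencies and read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing rearranged cancer genomes from interval adjacencies and read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prego)
```

## The model

A cancer genome is modelled as a scrambling of blocks of the germline
genome: a sequence $I_{\alpha(1)} I_{\alpha(2)} \dots I_{\alpha(M)}$ of
signed reference intervals. Paired-end sequencing of the tumor yields three
summaries of that hidden sequence:

* a partition $\mathbf{I} = (I_1, \dots, I_n)$ of the reference into
  intervals, cut at the breakpoints of clustered discordant read pairs;
* a set $A$ of novel adjacencies, each joining two oriented interval ends
  (the junctions the rearrangements created);
* a read-depth vector $\mathbf{r}$, the number of concordant pairs aligned
  entirely within each interval.

These are combined on the *interval-adjacency graph*: each interval
contributes two vertices $s_j, t_j$ joined by an **interval edge**;
**reference edges** join $t_j$ to $s_{j+1}$ for consecutive intervals on a
chromosome; each novel adjacency becomes a **variant edge** between the
oriented ends it joins (self-junctions — inverted repeats — are loops).
Chromosome-terminal vertices form the telomeric set $T$.

A reconstruction corresponds to a non-negative integer multiplicity
$\mu(e)$ on every edge. Walking a genome through the graph alternates
interval and non-interval edges, so any realizable $\mu$ satisfies the
*copy-number balance condition* at every non-telomeric vertex $v$:

$$\mu(e_I(v)) = \mu(e_R(v)) + \sum_{a \in E_A(v)} \mu(a),$$

with a loop at $v$ counted twice. Conversely (by Kotzig's theorem on
alternating Eulerian trails), any balanced $\mu$ decomposes into
edge-disjoint alternating tours that begin and end in $T$ — each tour
spells a block sequence of a genome consistent with the data.

Read depth selects among the balanced assignments. Under a Lander–Waterman
model the counts are Poisson, $r_j \sim \mathrm{Pois}(\lambda_j \mu_j /
\tau)$ with $\lambda_j = N L_j / L_R$, where $N$ is the total concordant
count, $L_j$ the interval length, $L_R$ the reference length and $\tau$
the copy number of an unrearranged interval (2 for a diploid sample).
Dropping constants, the fit minimizes

$$\mathcal{L}_r(\mu) = \sum_j \left[ \frac{\lambda_j \mu_j}{\tau} -
r_j \log \frac{\lambda_j \mu_j}{\tau} \right]$$

over balanced integer assignments. The minimizing interval multiplicities
$\hat c_j = \mu(e_I(j))$ are the inferred copy numbers. Over-dispersed or
negative-binomial depth models are out of scope here; the Poisson
assumption is the standard idealization for this purpose.

## Exact optimization by dynamic programming

The objective is separable over interval edges and the constraints couple
edges only at shared vertices. `solve_multiplicities()` exploits this: it
tabulates each interval edge's objective term at every integer
multiplicity up to its bound and sweeps the vertices in genome order,
keeping for every combination of multiplicities of the edges that cross
the current cut the cheapest completion (a cut dynamic program,
implemented in C++). Because the tabulation is exact at the integers, the
result is the true discrete optimum of $\mathcal{L}_r$ — there is no
piecewise-linear approximation gap, and the optimum provably agrees with
brute-force enumeration (`brute_force_oracle()`), which the test suite
checks on hundreds of random graphs.

The cost of a sweep step is the product of the domain sizes of the open
edges, so the method is exponential only in the *cut width* of the vertex
order. Deletions, tandem duplications, inversions and the simulator's
genomes give widths of 2–3; a guard (`max_states`, default $5 \times
10^6$) aborts with a clear error on graphs whose variant edges straddle
the genome order too heavily (e.g. hundreds of interleaved
translocations), rather than silently approximating.

Numerical choices:

* **$\mu = 0$ and the log term.** $\log 0$ is $-\infty$, which would
  forbid homozygous deletions outright. The log term at $\mu_j = 0$ is
  evaluated at a surrogate of `epsilon_copies` (default 0.05) copies, so a
  zero assignment costs $-r_j \log(0.05\,\lambda_j/\tau)$: free when no
  reads are observed, increasingly prohibitive as $r_j$ grows. The default
  keeps heterozygous intervals ($r_j \approx \lambda_j/2$) firmly at
  $\mu = 1$; see the robustness discussion below for its interaction with
  contamination.
* **Multiplicity bounds.** Per interval, $\mu \le \min(\texttt{mu\_max},
  \max(10, \lceil 4 \tau r_j / \lambda_j \rceil))$ — four times the
  depth-implied copy number, never less than 10; reference and variant
  edges inherit the smaller bound of their endpoints (halved for loops,
  which consume two junction slots). The global cap defaults to 50.
* **Ties.** Co-optimal assignments are common (a reciprocal pair can
  route through variant or reference edges at identical cost). The solver
  is deterministic (fixed sweep and enumeration order); `prefer_sparse =
  TRUE` adds a secondary objective — total variant-edge multiplicity — with
  weight far below any real objective gap, so unused junctions are zeroed
  among co-optima.
* **Degenerate inputs.** Zero-length intervals are rejected at
  construction, so $\lambda_j > 0$ whenever $N > 0$; all-zero depth
  vectors are legal and make every balanced assignment co-optimal at 0.
  Infeasibility (possible only when interval counts are pinned with
  `fixed_interval_counts`) is reported as such, never relaxed.

## Telomere loss

Telomere loss produces no novel adjacency, only a drop in concordant
coverage running to a chromosome end. `detect_telomere_loss()` flags an
interval boundary when the length-normalized depth ratio of its flanks
falls below `drop_ratio_threshold` (default 0.5 — a conservative
"half the copies vanished" rule) *and* the lower-depth side runs to its
chromosome end with no variant edge attached anywhere on that arm (a
variant edge there already explains the drop). Each detected loss adds a
telomeric $\sigma$ vertex with a variant edge to the boundary vertex of
the retained flank, and removes the displaced chromosome-end vertex from
$T$ — so the balance constraints force the lost arm to copy number 0,
tours terminate at $\sigma$, and $|T|$ stays at twice the chromosome
count. When both flanks of a drop could qualify, the edge attaches to the
higher-depth flank; when several nested boundaries qualify at one end,
the one closest to the end (zeroing the smallest arm) is chosen — the
least-committal reading of an under-determined signal.

## Tours and variant classes

`extract_tours()` builds the decomposition Hierholzer-style: arrivals via
non-interval edges depart via the vertex's interval edge and vice versa;
open tours are seeded at telomeric vertices while any has an excess of one
edge type, with lowest-edge-id-first branch choices (or seeded-random via
`seed` — many decompositions are usually consistent with one $\mu$, and no
uniqueness is promised). Balanced components that touch no telomere (e.g.
amplified circular structures) cannot host an open tour; they are emitted
as `leftover_cycles` with a warning rather than an error.

Variant edges are classified by endpoint geometry
(`classify_geometry()`): intra-chromosomal forward ($t_p$–$s_q$) edges are
deletion-type, back edges tandem-duplication-type, same-side edges
inversion-type, loops inverted-repeat (the breakage/fusion/bridge
signature); inter-chromosomal edges are classical or Robertsonian
translocations according to whether orientation is preserved. Two edges
are *reciprocal partners* when they cover the four free ends of the same
two breakpoints (`find_reciprocal_pairs()`; when several pairings are
possible the lexicographically smallest edge-id pair is taken). A
partnership is *trivial* when both variant edges and both flanking
interval pairs carry equal multiplicities — zeroing such a pair and
rerouting through the reference edges changes neither feasibility nor the
objective, so trivial usage carries no depth evidence.
`usage_association_test()` therefore tabulates *non-trivial* reciprocal
against non-reciprocal edges by used/unused and applies the two-sided
Fisher exact test (sum of hypergeometric probabilities not exceeding the
observed table's), per geometry class. Deletion-type and
tandem-duplication-type edges are reported as their own classes rather
than folded into the translocation/inversion tables.

## The simulator and what it does (not) show

`simulate_genome()` reproduces the reference robustness experiment: a
diploid genome over 22 autosome-proportioned chromosomes with 100
homozygous and 100 heterozygous deletions (lengths
$\mathcal{N}(10^4, 10^3)$ bases, placed disjointly with at least one
fragment length of separation), plus 50 *false* adjacencies, each
splitting an interval into three subintervals with a spurious
deletion-type junction (middle-segment lengths drawn from the same
distribution as true deletions, which the source experiment leaves
unspecified). `simulate_depth()` places fragments (mean 200 bp, sd 10) at
30× physical coverage: with probability $\rho$ on the unrearranged
diploid reference (contamination), otherwise on the rearranged genome; a
fragment counts toward $r_j$ only if it falls entirely within one copy of
interval $j$. Per-interval Gaussian noise with variance $\phi r_j$ is
then added, rounded, and clamped at zero (counts cannot be negative). The
default fast mode draws the counts directly from the equivalent Poisson
laws — uniform placement makes the two routes agree in mean within the
Monte-Carlo error, which the suite verifies on a 10 Mb genome. The
default genome totals 300 Mb (autosome proportions preserved) so that a
full 16-cell, 10-trial grid with ~1,270-edge graphs solves in seconds;
the proportions, deletion counts and coverage — not the absolute size —
drive the difficulty, and `sim_chrom_lengths(2.881e9)` restores
full-genome scale.

`run_grid()` scores, per $(\rho, \phi)$ cell, the mean percentage of
edges assigned their true multiplicity (overall, interval edges, and
reference + variant edges; trial genomes are shared across cells, depths
redrawn). Two regimes dominate the errors:

* **Depth noise** ($\phi$): short (10 kb) intervals have $r_j$ in the
  hundreds, so variance $\phi r_j$ at $\phi = 400$ perturbs their implied
  copy number by order one; heterozygous-deletion edges migrate from
  $\mu = 1$ to 0 or 2, while long intervals are essentially immune.
* **Contamination** ($\rho$): a homozygously deleted interval receives
  $\rho \tau$ expected copies of reference reads. Once
  $\rho > \varepsilon$-dependent threshold $\approx 1/(\tau
  \log(1/\texttt{epsilon\_copies})) \approx 0.17$, the objective prefers
  $\mu = 1$ over 0 there, and each of the ~100 homozygous deletions drags
  its junction and two flanking reference edges along — a structural,
  not stochastic, failure mode. On the default grid this makes the
  $\rho = 0.4$ column the accuracy floor (overall drop ≈ 47 points from
  the noise-free cell, vs ≈ 36 when $\rho \le 0.2$); interval-edge
  accuracy alone stays within a 40-point drop everywhere. There is an
  inherent trade-off in `epsilon_copies`: values near $1/3$ would tolerate
  40% contamination but leave almost no margin for heterozygous calls;
  0.05 favors clean heterozygous calling, the regime the method is
  designed for.

The simulation is deletion-only (no amplifications, inversions or
translocations are generated), uses positional read-intervals rather than
sequences, and has perfectly known breakpoints. Passing its recovery tests
therefore demonstrates the correctness of the graph/likelihood machinery
and its robustness to depth error and contamination — not performance
under breakpoint uncertainty, repeat-driven mis-clustering, or tumor
heterogeneity, none of which the generator emulates.

## Problem sizes used by the test suite

Property tests run the solver against exhaustive enumeration on hundreds
of random graphs with up to 6 edges and multiplicities up to 4, recover
generating copy numbers on 50 small deletion genomes (two chromosomes,
~7 Mb, 6 deletions + 2 false junctions), and verify tour conservation on
100 random instances; the grid experiment uses the full default
conditions above. These sizes keep the whole suite under a minute while
exercising every code path; all constants are the package's own choices.

## Known limitations

* General graphs with many order-straddling variant edges (dense
  inter-chromosomal rearrangement) exceed the cut-width guard; the exact
  solver refuses rather than approximate. A branch-and-bound or flow
  relaxation would be needed for such inputs.
* One genome per sample: no tumor heterogeneity, no allele-specific copy
  number.
* Co-optimal assignments and tours are reported, not ranked; choosing
  among them requires information (e.g. long-range linkage) outside the
  model.
* The Poisson depth model ignores over-dispersion and mappability
  structure; `phi` in the simulator exists precisely to probe that
  mismatch.
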