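---
title: "Congener-level dechlorination analytics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Congener-level dechlorination analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcbdechlor)
```

## The problem

Anaerobic microbial consortia — typically carrying organohalide-respiring
bacteria such as *Dehalococcoides* — dechlorinate polychlorinated biphenyl
(PCB) mixtures by stepwise reductive removal of single chlorines. A study of
such cultures measures, by GC–MS against a 209-congener standard, the mole
percent of each congener over time, and asks: how fast is chloride released,
from which ring positions (*ortho* 2/6, *meta* 3/5, *para* 4), along which
parent-to-product routes, and which named dechlorination specificities
(process N, process H/H′) are consistent with the observed shifts? A
companion 16S-derived genus table supports a co-occurrence network over taxa.
`pcbdechlor` implements that computational layer as reusable, tested code,
together with synthetic generators standing in for the instrument and
sequencing data.

## Congener model

A congener is a substitution pattern on two phenyl rings, each with
positions 2–6 available; the rings may be swapped and each mirrored through
its 1–4 axis, giving an 8-element symmetry group. `canonicalize()` stores
the lexicographically minimal image (positions ascending, ring A the smaller
ring string), so every symmetry image maps to one identity. Enumerating
orbits of the $2^{10}$ patterns gives exactly 209 chlorinated congeners with
homolog counts 3, 12, 24, 42, 46, 42, 24, 12, 3, 1 (mono through deca) —
`congener_table()` verifies this against a brute-force orbit oracle in the
test suite.

Ballschmiter–Zell numbers are assigned by the standard ordering rule
(ascending chlorine count, then ascending locant sequence, unprimed before
primed at equal position, the more substituted ring unprimed). A small
pinned override table is the source of truth where published lists are
historically irregular: the accepted numbers for 107–109 are a permutation
of the strict order, and 199–201 are pinned explicitly because lists have
disagreed there (the pinned values coincide with the post-1993 revision,
which the strict rule also yields). Anchor congeners — every number used in
the worked examples plus common reference congeners — are frozen in the
tests.

Molecular mass is $154.21 + 34.44\,n_{Cl}$ g/mol (chlorine replacing
hydrogen; H = 1.008, Cl = 35.45). These are documented constants, not
options.

## Dechlorination metrics

All metrics operate on mole-percent profiles. Entries must be non-negative
and sum to $100 \pm 0.5$ — GC–MS mole-percent tables routinely carry
rounding drift, so profiles inside the band are renormalized to exactly 100
and anything outside is an error, never silently rescaled. Congeners not
reported are exact zeros ("not detected"), not missing values.

* **Average chlorines per biphenyl**:
  $\bar{n}(t) = \sum_c x_c(t)\, n_{Cl}(c)$ with $x_c$ the mole fraction.
* **Molar concentration**: the nominal mass concentration (25 mg/L for the
  standard Aroclor 1260 dose) divided by the mole-fraction-weighted mean
  molecular weight of a reference profile, times 1000, in µM. The reference
  is the profile at the rate-window start. Published reports rarely state
  this basis; printed rates are generally not recoverable from printed,
  rounded averages, so the package fixes one reproducible convention and
  reports it. Ratios of rates (fold changes) are insensitive to the basis,
  which is why treatment comparisons are stated as fold changes.
* **Dechlorination rate**:
  $(\bar{n}(t_0) - \bar{n}(t_1)) \cdot C_{\mu M}(t_0) / (t_1 - t_0)$ in
  µM Cl⁻ d⁻¹.
* **Positional removal**: per class,
  $N_{pos}(t) = \sum_c x_c(t)\, n_{pos}(c)$ and removal fraction
  $1 - N_{pos}(t_1)/N_{pos}(t_0)$; a class absent at $t_0$ is flagged
  not-applicable rather than divided. The class deltas recombine exactly:
  $\Delta\bar{n} = \sum_{pos} \Delta N_{pos}$.

```{r}
p0 <- congener_profile(c("PCB153", "PCB180"), c(66, 34), time = 0)
p1 <- congener_profile(c("PCB101", "PCB153", "PCB180"), c(35, 31, 34), time = 15)
tc <- dechlor_timecourse(list(p0, p1), mass_conc_mg_l = 25)
dechlorination_rate(tc, 0, 15)
```

## Reaction network and process rules

`single_dechlor_products()` removes each chlorine in turn, canonicalizes the
product, and aggregates symmetry-equivalent removals into one reaction with
a multiplicity. Each reaction carries the removed position class, its
flanking context (chlorines at ring-adjacent positions along the 2–3–4–5–6
path; the ring bond never flanks), and the attacked ring's chlorophenyl
group rendered as ascending digits in the orientation with the smaller digit
string. `build_network()` assembles the directed acyclic graph over all 209
congeners restricted to allowed position classes; `reachable()` answers
shortest-path queries by breadth-first search, checked in the tests against
exhaustive path enumeration.

Process classification is configuration, not code: a rule is a
(chlorophenyl group, attacked position) pair, and the default table encodes
process N as flanked-*meta* removal from groups 236, 245, 2345 and 2356,
and process H/H′ as *para* removal from 234, 245 and 2345 — the example
groups the dechlorination literature attaches to those specificities.
Published group lists mark the removed chlorine typographically and often
ambiguously, so the default table is deliberately overridable
(`read_process_rules()`) rather than hard-coded as fact.

One attribution caveat surfaced by the network itself: among the commonly
named hexa/hepta parents of the tetra end products PCB 47/49/51/53, two
(PCB 110 and PCB 158) cannot reach any of those products by *meta*/*para*
removals alone — their per-ring ortho-chlorine multiset cannot match any
target. The package reports per-parent reachability facts instead of
asserting a parent list wholesale.

## Kinetic simulator

The generator evolves mole fractions by first-order kinetics
$\dot{x} = Kx$ for $t > \text{lag}$, with the per-edge rate equal to
`base_rates[position]` × the product of matching process multipliers × the
reaction multiplicity. Propagation uses matrix exponentials between
sampling times (`Matrix::expm`), which is exact for a linear system, so
closed-form checks hold to numerical precision — e.g. pure PCB153 under
*meta*-only rate $k$ decays as $e^{-2kt}$ (two equivalent *meta*
chlorines). An augmented linear system integrates the per-reaction flux, so
the chloride-release ledger equals $\Delta\bar{n}$ identically in the
noise-free system (machine-precision agreement, asserted at 1e-6 relative
in the tests; conservation of moles is asserted at 1e-9).

Design choices, in the package's own terms:

* **Lag as a hard delay** ($K = 0$ before the lag) rather than a growth
  model: the phenomenon emulated is a lag phase, not a growth law.
* **Noise after dynamics**: multiplicative log-normal perturbation at
  observation times only — measurement scatter, not process noise — then a
  detection limit (default 0.05 mole %) zeroes trace congeners before
  renormalization, mirroring "not detected" handling. A seed is mandatory
  whenever noise is drawn; all stochastic output is bit-reproducible.
* **Defaults**: lag 15 d, base rates *meta* 0.01 d⁻¹, *para* 0.002 d⁻¹,
  *ortho* 0. No kinetic constants are published for these cultures; the
  defaults were chosen once so that a 25 mg/L pseudo-Aroclor run shows no
  activity through day 15, loses roughly 1.5–2 chlorines per biphenyl by
  day 112, accumulates tetra/penta products, and *meta* dominates *para* —
  the qualitative shape of the observed time courses. They are generator
  conditions, not fitted estimates.

The pseudo-Aroclor start (`pseudo_aroclor()`) is supported on tetra–octa
congeners from the named Aroclor 1260 constituents, with seeded log-normal
jitter within homologs and a deterministic blend toward a pure-tetra or
pure-octa pool that lands the average chlorine number exactly on target
(6.34 or 6.4 per biphenyl in the emulated cultures).

```{r}
tc <- simulate_dechlor(simulation_spec(times = c(0, 15, 21, 45, 112), seed = 1))
vapply(attr(tc, "noise_free")$profiles, average_chlorine, numeric(1))
```

## Abundance generator and the closure artifact

`simulate_abundances()` draws independent log-normal abundances per taxon,
imposes planted blocks through a Gaussian copula factor (loading chosen so
the population Spearman correlation equals the block strength,
$a = 2\sin(\pi\rho/6)$), applies optional multiplicative group effects, and
closes rows to sum 1. Because the log-normal transform is monotone, planted
rank correlations survive the marginal transform exactly; closure, however,
does not preserve independence. With few taxa or a very uneven abundance
spread, the shared denominator induces substantial spurious rank
correlation between otherwise independent taxa — the classic compositional
artifact of relative-abundance data. The defaults (50 taxa, log-mean sd 1)
match the scale of a filtered genus table and keep the closure perturbation
negligible, so the zero-block generator behaves as an independence null
(false-positive share at $p<0.05$ close to nominal) and planted blocks at
strength 0.95 are recovered in full at 24 samples. Users planting blocks
into tables with, say, a dozen taxa dominated by one genus should expect
closure-driven edges; that is a property of compositional data, not of the
correlation machinery.

What the generator does **not** emulate: sequencing count noise and
zero-inflation, phylogenetic correlation structure, and genuine ecological
interaction dynamics. Passing tests therefore demonstrate the correctness
of the network stage's statistics on rank-correlated compositions, not
robustness to the full messiness of amplicon data.

## Co-occurrence networks

`spearman_edges()` computes midrank Spearman correlations for all taxon
pairs after an abundance filter (default: mean relative abundance strictly
above 0.01 %; the filter statistic is configurable because published
methods rarely state it). P-values use exhaustive permutation enumeration
for $n \le 10$ samples (tie-safe, implemented in C++ and checked against an
R enumeration oracle) and the t approximation otherwise; constant taxa are
skipped with a warning. No multiple-testing correction is applied by
default — matching the common "$p < 0.05$" practice this stage mirrors —
with Benjamini–Hochberg available by flag. Edges require
$|r| > 0.7$ and $p < 0.05$ (both configurable); nodes are the taxa incident
to at least one edge, the convention of edge-list network tools.

Topology metrics follow the usual co-occurrence reporting set. Two
conventions are fixed and documented because graph tools disagree silently:
modularity comes from deterministic greedy optimization (community *labels*
are not part of the contract, only the modularity value — seed-dependent
Louvain implementations cannot be reproduced at label level across tools),
and diameter / average path length are computed on the largest connected
component.

## Numerical choices and degenerate inputs

* Canonical-form and group-string tie-breaks are byte-order (`radix`)
  string comparisons — locale-independent.
* Profile normalization band $100 \pm 0.5$; outside it, hard error.
* Matrix exponentials on the reachable-support submatrix only; the
  augmented (states + reactions) system stays a few hundred rows for
  Aroclor-scale supports.
* Empty networks report zeroed metrics with an `empty` flag; an all-filtered
  abundance table warns and returns zero columns; `fold_change()` refuses
  non-positive references; reachability from a congener to anything with
  more chlorines is definitionally false.
* Exact permutation p-values enumerate distinct multiset arrangements
  (`std::next_permutation`), which weights tied ranks correctly.

## Problem sizes in the test and acceptance runs

The suites run at deliberately desk-scale sizes: the full 209-congener
enumeration against the $2^{10}$ orbit oracle; reachability oracles over
the nine named hepta/hexa parents; kinetic runs on Aroclor-scale supports
(~120 states, ~270 reactions); a 6-sample fixture for the permutation
oracle; 200 seeded replicates of 24 samples × 50 taxa for the
false-positive calibration; and planted-block recovery at 24 samples.
These sizes were chosen as the smallest that exercise every contract
meaningfully.

## Known limitations

* BZ numbering rests on the strict ordering rule plus a small override
  table; the 199–201 region is pinned to one published convention and
  documented as such.
* Published dechlorination rates are generally not exactly recoverable from
  published rounded chlorine averages (the concentration basis and unrounded
  inputs are rarely stated); the package therefore treats rate *ratios* as
  the comparable quantities and documents its own molar basis.
* The kinetic model is linear first-order with a hard lag: no biomass
  growth, no substrate saturation, no congener-specific enzyme affinities
  beyond the position/process rate structure.
* Process N / H / H′ group tables are configuration with literature-derived
  defaults, not asserted fact.
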