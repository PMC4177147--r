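---
title: "Fitting single-expansion demographies to Y-chromosome phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting single-expansion demographies to Y-chromosome phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(coalexp)
```

## The problem

The male-specific part of the Y chromosome does not recombine, so fully
sequenced Y chromosomes yield an unusually clean phylogeny whose shape
records male demographic history. The two major haplogroups associated with
the Neolithic transitions — R1b in Western Europe and E1b1a in sub-Saharan
Africa — show strikingly different tree shapes: R1b is almost a perfect
star (an expansion so fast that almost no mutations accumulated during it),
while E1b1a bifurcates regularly with greater time depth.

`coalexp` asks which demographic histories produce such shapes. It fits a
deliberately simple model: a single exponential change in male effective
population size, described by four parameters —

* `start_n` — ancestral male effective size (men),
* `end_n` — final male effective size (men),
* `duration_years` — length of the expansion,
* `t_end_years` — when the expansion ended (years before present).

Backwards in time the size function is constant at `end_n`, shrinks
exponentially to `start_n` through the expansion epoch, and stays at
`start_n` beyond it. The Y chromosome is haploid and paternally inherited,
so a pair of lineages coalesces at rate \(1/N(t)\) per generation and
population sizes are counts of men.

## Simulation

Genealogies are drawn from the variable-size Kingman coalescent by
inverse-CDF sampling: with \(k\) lineages the waiting time to the next
coalescence solves \(\int_{t_0}^{t_0+s} \binom{k}{2}/N(t)\,dt = -\log u\),
inverted in closed form within each epoch of the piecewise size function
(`coalescent_waiting_time()`). There is no recombination, migration or
selection; the whole 8.8 Mb callable region behaves as one locus. Mutations
are Poisson-sprinkled onto branches at
\(\mu L = 3\times10^{-8} \times 8.8\times10^6 = 0.264\) expected variants
per generation of branch, the infinite-sites convention. The simulator is
validated in the test suite against Kingman closed forms
(\(E[T_{\mathrm{MRCA}}] = 2N(1-1/n)\), \(E[L_{\mathrm{tot}}] = 2N\sum 1/k\)),
against a numeric-integration inversion oracle on the exponential epoch,
and against a plain-R reference implementation on matched seeds.

The mutation rate and the 30-year generation time only scale results
between generations and calendar years: halving the mutation rate would
double every inferred time.

## Tree statistics

Observed and simulated trees are reduced, after normalising total branch
length to 1, to three numbers (`tree_stats()`):

* the singleton/shared ratio
  \(r = \sum_{\mathrm{TER}} l_b \big/ \sum_{\mathrm{INT}} l_b
  (1 + \sum_{\mathrm{BEN}(b)} l_{b_i})\), which grows as the tree becomes
  star-like (a perfect star has no internal branches and \(r = \infty\));
* the mean of the \(\binom{n}{2}\) pairwise coalescence depths
  (time depth);
* their population standard deviation (star-likeness again: 0 for a star).

Two readings of "branches beneath" the weighting term are possible; the
package counts internal branches only, with
`include_terminal_beneath = TRUE` exposed as an option. The standard
deviation divides by the number of pairs, not pairs − 1; at \(n = 6\)–8 the
difference is under 3%. On SNP trees, which are not exactly ultrametric, a
pair's depth is the mean of the two MRCA-to-tip path lengths, which reduces
to the ordinary node depth on ultrametric genealogies.

## The AND fit statistic and the search

A scenario is scored by simulating `reps` genealogies (1,000 by default),
averaging each statistic, and taking the average normalised delta against
the observed triple:
\[\mathrm{AND} = \tfrac13\left(\frac{|r_s-r_o|}{r_o} +
\frac{|m_s-m_o|}{m_o} + \frac{|d_s-d_o|}{d_o}\right).\]
Scenarios with AND below 0.05 are called accepted. The four-dimensional
parameter space is explored by a sequential grid search
(`sequential_search()`): evaluate a 5×5×5×5 grid, keep the best-fitting
cells, narrow each axis around them, and repeat. Accepted cells, pooled
over rounds, are summarised per parameter by a frequency histogram, the
median and a 2.5–97.5 percentile interval.

Scenarios whose expansion begins (`t_end_years + duration_years`) before
the haplogroup's own TMRCA — estimated from the observed tree by the
mutation clock, mean root-to-tip SNPs / 0.264 generations — are excluded
before simulation.

### Genealogy scoring, scale invariance, and the `mutate` option

By default simulated statistics are computed on the genealogy branch
lengths themselves. Because all three statistics are taken on normalised
trees, they are then *exactly* invariant to rescaling: multiplying all
four parameters by a common factor \(c\) rescales every genealogy by
\(c\) and leaves the statistic distribution unchanged. The fit therefore
constrains the *shape* of the expansion sharply but its absolute scale
only through the TMRCA filter (which truncates the scale ridge from
above) and the grid bounds — accepted sets spread along the ridge, which
is why reported intervals for sizes and times are wide and why medians
must be read with their intervals.

`mutate = TRUE` instead scores scenarios on Poisson-mutated SNP trees,
whose integer variant counts carry scale through the mutation clock
(relative Poisson noise grows as the scale shrinks). That sounds
preferable, but it breaks on star-like observations: a mutated star tree
often has *no* internal variants, so its replicate \(r\) is infinite;
such replicates are dropped from the \(r\) average (their fraction is
recorded, and a scenario with more than half infinite replicates scores
AND = ∞), which caps the achievable finite mean \(r\) below the observed
\(r\) of strongly star-like trees and can leave no acceptable scenario
at all. Genealogy scoring, whose mean \(r\) is continuous and unbounded,
always admits a fit; the mutated mode is kept as a sensitivity option.

### Numerical and procedural choices

* Grids use 5 values per axis (625 scenarios per round) by default; the
  packaged haplogroup analyses use 6.
* Default first-round ranges are deliberately wide: `start_n` 1–5,000,
  `end_n` 100–100,000, `t_end_years` 0–TMRCA, `duration_years` one
  generation–TMRCA. The time axes deliberately reach the empirical TMRCA,
  the oldest possible start of the expansion.
* Default first-round time axes are linear and size axes geometric. With
  the fit surface nearly flat along the model's degenerate directions, the
  accepted-set marginals inherit the axis measure; a geometric duration
  axis piles accepted cells onto very short durations, which recovery
  experiments against the packaged regimes showed to be a pure
  discretisation artifact.
* Refinement keeps the lowest-scoring 20% of evaluated cells (quantile
  rule; a `max(0.05, 1.5 × round minimum)` threshold rule is also
  provided), then spans each axis by the 10–90% quantiles of the kept
  cells' *distinct* axis values, extended by one grid step, clipped to the
  global bounds, and never wider than the previous range. The robust span
  keeps single noisy stragglers from pinning the ranges open; distinct
  values (rather than cells) stop axis regions thinned by the TMRCA
  exclusion from being under-weighted; the monotone cap makes narrowing
  irreversible except through the one-step boundary extension.
* The search stops when at least half the evaluated cells score below
  0.05, or after `max_rounds` (15) rounds. Accepted (sub-0.05) cells are
  pooled over all rounds and deduplicated; pooling was adopted after
  recovery experiments showed final-round-only accepted sets of a handful
  of cells whose intervals grossly understate the uncertainty.
* Per-cell RNG seeds derive from (seed, round, cell index), so a search is
  reproducible end-to-end from one integer seed and insensitive to
  evaluation order. (Seeds are derived per scenario rather than per
  replicate; replicates within a scenario consume one ordinary RNG
  stream.)
* `duration_years = 0` is an instantaneous size change; `start_n = end_n`
  falls back to the constant-size closed form (the \(\beta = 0\) limit is
  handled analytically).

## Synthetic data and what the tests show

`europe_regime_spec()` and `africa_regime_spec()` package the two fitted
continental regimes — Europe: 2 → 9,500 men over 325 years ending 12,000
years ago with 6 sampled chromosomes; Africa: 40 → 2,000 men over 12,000
years ending 2,000 years ago with 8 — as generating models for end-to-end
parameter-recovery experiments (`generate_experiment()` +
`fit_expansion()`). Draws are redrawn deterministically until the observed
tree has at least one shared variant (finite \(r\)) and a mutation-clock
TMRCA no younger than the generating expansion's start, so that the
experiment is well-posed under the package's own TMRCA bound.

The generator emulates idealised observations: one non-recombining locus,
complete variant ascertainment, Poisson mutation, and exact SNP counts.
Real sequencing data add coverage-dependent false negatives, filtering
artifacts and pedigree structure (handled separately by
`collapse_pedigree()`), none of which the generator reproduces — so
passing recovery tests demonstrates the statistical machinery, not
robustness to data-quality issues.

The packaged example trees (`haplogroup_fixture()`) are *synthetic
stand-ins* for the two published haplogroup phylogenies, whose per-branch
SNP counts are only available as a figure: each is a seeded draw from the
corresponding regime model, zero-variant internal branches collapsed,
screened to match the described topology (R1b: a 6-tip star with exactly
one internal branch of one SNP uniting three chromosomes; E1b1a: an 8-tip
bifurcating tree with exactly one trifurcation and at least the regime's
time depth), and, among matching draws, selected for the lowest best-achievable AND
against a reference library of simulated scenario means (with closeness
to the generating scenario's means as tie-break), so that the packaged
observations are fittable by the model family the way the empirical trees
evidently were. They exercise the full pipeline realistically but are not
the empirical data.

## A worked example

A desk-scale fit of the packaged R1b-like tree (200 replicates per
scenario rather than the default 1,000):

```{r, eval = FALSE}
tree <- haplogroup_fixture("R1b")
tree_stats_report(tree)
fit <- fit_expansion(tree, reps = 200, seed = 1)
summary(fit)
plot(fit)                    # per-parameter histograms of accepted cells
write_fit_surface(fit, "r1b_surface.tsv")
```

`coef(fit)` returns the per-parameter medians over accepted scenarios;
`residuals(fit)` the relative deviation of each averaged statistic at the
best cell; `simulate(fit, 10)` draws genealogies from the median model.

## Problem sizes

The compiled simulator draws roughly a million 6–8 tip genealogies per
second. The package's default search is 15 rounds of 625 scenarios at
1,000 replicates each; the haplogroup analyses in the reproduction script
and test suite use a denser, longer search (6 points per axis, up to 25
rounds, 1,000 replicates), which completes in one to two minutes per
haplogroup, and the recovery experiments use 10 seeded desk-scale
searches per regime at 200 replicates.

## Known limitations

* The demographic model is a single exponential episode; multiple
  expansions, structure, migration and selection are out of scope.
* Three summary statistics cannot fully identify four parameters: the fit
  constrains the expansion's shape well and its absolute scale weakly, so
  medians should always be read together with their intervals.
* The AND statistic compares a *single* observed draw with scenario
  *means*; for statistics with skewed sampling distributions (notably
  \(r\) on near-star trees) the best-fitting scenario mean need not sit
  at the generating parameters.
* TMRCA estimation assumes the mutation clock's rate and generation time;
  both rescale, rather than reshape, the inference.
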