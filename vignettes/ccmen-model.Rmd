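---
title: "The CCMEN directional-preference model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CCMEN directional-preference model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmen)
```

## The problem

Nanoparticles coated with extruded cancer-cell membrane (CCMEN) display the
surface proteins of the source tumour cell and bind tumour cells
preferentially through homotypic protein--protein adhesion. In a real
culture, however, three sinks compete for every particle: glioblastoma
cancer cells (GCC), normal healthy cells (NHC), and secreted soluble factors
(F) — ligands such as PDGF or VEGF that can occupy the particle's receptors
without delivering it anywhere useful. The question this package answers is
quantitative: *given per-receptor binding efficiencies towards the three
channels, what fraction of the exposed particle population ends up directed
towards each fate?*

## Model structure and assumptions

The model works on a panel of $n$ receptor types (the packaged glioblastoma
panel has $n = 11$). Its assumptions, in plain terms:

1. A particle engages, in one binding event, some subset of its receptor
   types; each engaged receptor binds either a cell-surface partner or a
   secreted factor.
2. GCC and NHC are mutually exclusive targets: one particle cannot bridge
   both cell types.
3. At least one receptor interacts (the all-idle state carries no mass).
4. A particle whose engaged receptors are *all* factor-bound interacts with
   no cell at all — it is an F-only event.
5. Factor--factor interactions are ignored.
6. Everything else contributes no directional preference (it simply carries
   no mass; there is no fourth channel).

A **configuration** is a pair: a receptor combination of degree $k$
($\binom{n}{k}$ of them per degree, all enumerated exhaustively) and a
factor degree $k_F \in \{0, \dots, k\}$ counting how many members are
factor-bound. For $k_F < k$ the configuration exists on two branches (GCC or
NHC); for $k_F = k$ it is a single F-only configuration. The total number of
branch-level configurations is $\sum_k \binom{n}{k}(2k + 1)$ — 24,575 for
$n = 11$, enumerable in well under a second.

### Conditional binding efficiency

The per-receptor input is the conditional binding efficiency
$$\mathrm{CBE} = \mathrm{BS} \times \min(\mathrm{NEX}_{\mathrm{CCMEN}},
\mathrm{NEX}_{\mathrm{target}}) \times \min(\mathrm{FC}_{\mathrm{CCMEN}},
\mathrm{FC}_{\mathrm{target}}),$$
where BS is an intrinsic (docking-derived) binding score, NEX a native
expression level and FC the tumour-vs-normal fold change. The min()
structure means an interaction is rate-limited by its scarcer partner.
Three channels are built per receptor (`build_cbe_tables()`):

* **GCC**: homotypic receptor score with tumour-side expression and fold
  change on both sides (the particle carries the tumour membrane, so by
  default both sides share one expression table).
* **NHC**: the same homotypic score, but the normal cell is the fold-change
  *reference*, so its fold change is fixed at 1 by construction.
* **F**: the receptor against a factor — its cognate partner by default
  (row-aligned pairing, e.g. PDGFRA with PDGF), or the maximum over all
  factors with `pairing = "max_over_factors"` for score matrices that
  include cross pairs.

Precomputed per-channel CBE files (the `cmcc.csv`/`cmnc.csv`/`cmf.csv`
layout) are accepted directly and take precedence when both input styles are
given. The factor-channel file may be a vector or a square receptor-by-factor
matrix; a matrix is reduced by its diagonal (cognate) or row maximum.

### Binding strengths and the probability map

Which particular members of a combination are factor-bound is unobserved.
We treat all $\binom{k}{k_F}$ assignments as exchangeable and average over
them, which collapses to a closed form: the cell channels carry
$(k - k_F)/k$ of the combination's summed cell CBE, and the factor channel
$k_F / k$ of its summed factor CBE (`configuration_bst()`). The exhaustive
per-assignment average is retained in the test suite as an independent
oracle for this closed form.

The mapping from binding strengths to probabilities is the minimal
proportional-mass choice: every branch weight (GCC-branch BST, NHC-branch
BST, and the factor BST of any configuration with $k_F > 0$) is divided by
the global sum $Z$, so absolute probabilities sum to exactly one.
Conditional probabilities $CP_k$ renormalize within each degree.

One structural consequence is worth knowing: because the subclass weight
factors $(k-k_F)/k$ and $k_F/k$ both sum to $(k+1)/2$ over
$k_F = 0,\dots,k$, the *within-degree* channel shares $CP_{k,\cdot}$ are
identical at every $k$ under this map. The break-even point of a fitted
model is therefore always 1 or "none"; a $k$-varying $CP$ profile requires
a different (unpublished) probability map. The BEP machinery
(`break_even_point()`) is nonetheless fully general and accepts any
per-degree profile.

### Selective propensity geometry

Each configuration's binding-strength triple $(BST_{GCC}, BST_{NHC},
BST_F)$ is a vector in a 3-D channel space. For channel $T$,
$$S_{p,T} = 90^\circ - \arccos\!\left(\frac{BST_T}{\lVert BST \rVert}\right),$$
i.e. 90 degrees minus the angle to that channel's axis. Since the squared
direction cosines sum to one, at most one channel can exceed
$45^\circ$; the configuration is classified to that channel, and to NNDP
("no net directional preference") when none does. Two deliberate
conventions:

* The threshold comparison is **strict**: an exact $45^\circ$ propensity
  (e.g. equal GCC and NHC strengths with no factor component) falls to
  NNDP.
* A zero BST vector has no defined direction; it is classified NNDP rather
  than raising an error, so fully inert configurations never interrupt a
  pipeline run.

The "degrees of a ratio" in the source formulation is read as the arccos of
the direction cosine — the only reading that keeps every propensity in
$[0^\circ, 90^\circ]$ and makes the 45-degree threshold meaningful. The
test oracle independently computes the same angles as atan2 elevations.

### Fractions, NNDP redistribution, odds ratios, BEP

A configuration's entire probability mass (its cell-branch weights plus its
factor weight) follows its direction class; summing by class gives the
population fractions. For the headline prediction the NNDP mass is split
equally among the three fates (`redistribute_nndp()`); intermediate tables
keep the raw NNDP bookkeeping.

No published formula exists for the reported odds ratios, so the package
uses a documented, swappable definition (`odds_ratio()`): channel fraction
$f$ against the mean $g$ of the two competing channels' fractions,
$\mathrm{OR} = \frac{f/(1-f)}{g/(1-g)}$. Degenerate cases signal
(`Inf`/`NaN`) instead of failing.

The break-even point is the smallest $k$ at which
$CP_{k,GCC} < \max(CP_{k,NHC}, CP_{k,F})$ — the degree at which the
particle first loses its tumour preference; "none" (no crossing) is the
best possible outcome. The alternative "ranges from 0 to $n$" phrasing in
the source literature conflicts with this first-crossing definition; the
crossing definition is implemented, with the sentinel reserved for no
crossing.

### Culture modes

Test culture I (tumour cells + factors, no normal cells) is modelled by
zeroing the NHC channel before enumeration; culture II uses all three
channels. A property worth noting, confirmed against the brute-force
oracle: on a tumour-biased input, removing the NHC channel *slightly
decreases* the GCC fraction, because GCC-directed (cell-heavy)
configurations lose their NHC-branch mass while factor-directed mass is
untouched, shifting relative share towards F. Intuition that removing a
competitor must help the tumour channel does not survive the arithmetic.

## Synthetic inputs

`synth_cbe_tables()` generates per-receptor channel values as lognormal
draws with means `(gcc_bias, nhc_level, factor_level)` and coefficient of
variation `noise_cv`; lognormal noise keeps efficiencies nonnegative and
mimics the multiplicative score-times-expression structure of the CBE. The
defaults are neutral and noiseless (all levels 1, CV 0), i.e. a fully
predictable instance; demonstration runs in this package use a moderately
tumour-biased setting (GCC bias 3, other levels 1, CV 0.25 — a typical
biological between-receptor variability) with an explicit seed. The
generator emulates the *shape* of real channel inputs (nonnegative,
right-skewed, channel-biased); it does **not** emulate docking-score
distributions, receptor-receptor correlation, or the coupling between
channels induced by shared expression levels. Passing tests on synthetic
inputs therefore validate the combinatorial and geometric machinery, not
the biological accuracy of any particular channel table.

The packaged expression panel (`gbm_expression()`) ships the 11
receptor--factor pairs with normal-brain expression, IL-13-baseline relative
expression and glioblastoma fold change. Published relative-expression
columns are typically rounded at the last digit, so the loader always
recomputes them from the native levels and only warns when a supplied value
deviates by more than 1% — the packaged panel loads silently.

## Numerical choices

* Probability normalization is exact by construction; tests assert
  $\sum p = 1$ and per-degree sums at $10^{-9}$.
* All probabilities, conditional probabilities and angles are invariant to
  a global rescaling of the CBE tables (tested).
* Direction cosines are clamped to 1 before arccos to absorb floating-point
  overshoot.
* An all-zero CBE table is a degenerate model and errors; a zero *channel*
  is fine (that is culture I).
* CSV cells are written with 6 significant digits in a fixed iteration
  order (degree ascending, combination lexicographic, factor degree
  ascending), so identical inputs reproduce byte-identical files;
  `summary.json` keeps full precision.
* Expectations renormalize within each $(k, k_F)$ conditioning cell; empty
  cells are omitted rather than reported as 0/0.

## Problem sizes used by the tests

Oracle-equivalence tests run the naive full-materialization enumeration for
$n \le 6$; property suites loop over seeded random tables at $n \le 6$; the
full $n = 11$ model (24,575 configurations) is fitted in a fraction of a
second and asserted to finish within a minute. ELISA parameter recovery
uses 1000 seeded noisy calibrations of 6 points. These sizes were chosen so
the entire suite runs in seconds while still exercising every code path
exhaustively.

## Known limitations

* The probability map (BST-proportional mass) is a documented modelling
  choice, not a published formula; headline fractions depend on it.
* Real binding-score inputs for the glioblastoma panel are not
  redistributable here; shipped demonstrations use synthetic channels.
* The geometry is fixed at three channels; immune or inflammatory sinks
  would need an $N$-channel generalization.
* The odds-ratio definition is package-local (see above) and deliberately
  isolated so it can be swapped.
* ELISA support covers the logarithmic standard-curve family only — no
  4-parameter logistic fits, no plate-reader file parsing.
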