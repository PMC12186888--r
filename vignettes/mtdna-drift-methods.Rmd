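---
title: "Modelling biased inheritance of deletion-bearing mtDNA in yeast"
author: "rhodrift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling biased inheritance of deletion-bearing mtDNA in yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhodrift)
```

## The problem

When a *Saccharomyces cerevisiae* strain carrying a large-deletion
mitochondrial genome (rho^-^) is crossed with a wild-type (rho^+^)
strain, the diploid progeny are often dominated by the defective
mitotype — a phenomenon quantified as *suppressivity*, the percentage of
petite (respiration-deficient) colonies among the diploid progeny. Two
mechanisms can produce this bias: rho^-^ haploids may simply contribute
more mtDNA copies to the zygote, or rho^-^ molecules may out-replicate
rho^+^ molecules inside heteroplasmic cells (an *intracellular fitness*
advantage). `rhodrift` implements a stochastic model of the second
mechanism conditioned on the first, and the estimators needed to infer
the intracellular fitness of real strains from their measured
suppressivity and copy-number ratio.

## The stochastic model

A cell is a pair of molecule counts $(w, m)$ with fixed total
$w + m = n$ (default $n = 20$ segregating units), plus a division
clock. The mutant fraction sets the phenotype through a pathogenicity
threshold $\tau$ (default 0.5): a cell is petite iff $m/n > \tau$
(strictly; a cell at exactly $\tau$ is grande — the two conventions
differ only on this boundary and both are available via
`phenotype_ties`). Phenotype sets the doubling time: 140 min for grande,
210 min for petite by default. A 190-min petite doubling time, used in
some robustness analyses, can be set through `t_petite_min`.

Time advances in 1-minute scheduler ticks (`dt_min`); a cell divides on
the first tick at which its age reaches its phenotype's doubling time.
The starting population (default 1000 cells) is initialised with
identical composition $m = \mathrm{round}(h_0 n)$ — per-cell binomial
initialisation is available — and uniformly random ages, which
desynchronises the initial divisions. The run lasts 1440 simulated
minutes.

At division the parental pool is amplified — $2w$ wild-type and $2 f m$
mutant molecules, where $f$ is the intracellular fitness of the mutant
mtDNA — and each daughter receives exactly $n$ molecules sampled from
the amplified pool. The sampling scheme is not fully identified by the
verbal description "randomly sampled", so both natural readings are
implemented:

* `independent_binomial` (default): each daughter's mutant count is an
  independent $\mathrm{Binomial}(n, p)$ draw with
  $p = fm/(fm + w)$. This is well defined for any real $f \ge 0$,
  requires no rounding of $2fm$, and preserves the neutral martingale
  ($\mathbb{E}[m'] = m$ at $f = 1$).
* `partition_hypergeometric`: the amplified pool (with $2fm$ rounded
  stochastically) is partitioned without replacement; daughter two draws
  from the depleted pool, or from a fresh amplified pool if fewer than
  $n$ molecules remain. At $f = 1$ this also preserves the neutral
  martingale.

Degenerate cases are fixed by convention: $p = 0$ when $m = 0$ and
$p = 1$ when the amplified denominator vanishes with $m > 0$, so
homoplasmy is absorbing in both modes, as it must be without mutation
or recombination. There is no cell death, no mating dynamics and no
spatial structure; suppressivity is read out at the end of the run as
the fraction of cells devoid of wild-type mtDNA.

The simulator stores the population as parallel integer vectors and
schedules divisions into per-tick buckets, so the only per-tick work is
on the cells actually dividing; a run reaching $10^6$ cells completes
in about a second, and populations of several million cells are
well within memory.

## Fitness inference

Intracellular fitness is not directly observable. The estimator builds
a *suppressivity grid*: simulations over a lattice of initial
heteroplasmy $h_0$ and fitness $f$, several replicates each
(`build_suppressivity_grid`). An observed strain is a point
$(h_0, s)$ — its zygote heteroplasmy, computed from the parental copy
numbers as $h_0 = c_{mut}/(c_{mut} + c_{wt})$, and its measured
suppressivity as a fraction. `knn_fitness` takes the $k = 6$ nearest
grid points by plain Euclidean distance in this plane (both coordinates
already live on $[0,1]$, so no standardisation is applied) and averages
their fitness values. Inference is restricted to grid fitness values in
$[0, 2]$: above 2 suppressivity saturates and no longer discriminates
between fitness values. Distance ties are broken towards lower fitness,
then lower $h_0$, making the estimator conservative and deterministic.

By default the search runs over individual replicate points rather than
per-point means (a richer neighbour set; `use_replicates = FALSE`
switches to means). `estimate_panel` applies the estimator per strain
and summarises a panel with its mean, median and a Wilcoxon signed-rank
test against 1, the neutral expectation.

Two grid-design choices matter in practice and are deliberate:

* **Fitness spacing 0.1.** kNN averages of $k = 6$ neighbour fitness
  values are quantised in steps of (spacing)/6. With a coarse spacing
  (0.2 or wider) this quantisation becomes a locality-specific bias
  that the signed-rank test mistakes for signal, making the null test
  anti-conservative. At spacing 0.1 the independent assay noise
  dominates and the test is calibrated (95% of null panels
  non-significant at $\alpha = 0.05$ in the acceptance checks).
* **Replicates.** Grid noise is shared by all strains estimated against
  the same grid, so replicate averaging reduces a *correlated* error
  component; the package default is 10 replicates per point, and the
  reduced test configuration uses 5.

## Copy number from read depth

The mtDNA/nDNA ratio is estimated from per-base depth profiles. The
nuclear baseline is a quantile-trimmed mean (default 2.5%-97.5%),
computed on per-position depths, which discards rRNA-repeat and
telomere-like extremes. Because the AT-rich majority of the yeast
mitochondrial genome maps poorly, depth is read from three short
regions (8002-8153, 31222-31305, 48195-48296) chosen so that every
deletion strain retains at least one, and the final ratio is the
maximum of the per-region ratios — regions lost to a deletion
contribute zero and are ignored by the maximum. The GC-rich window
(14,000-20,000) is available as an alternative region for strains that
retain it; with the dropout present, the three-region estimate is
expected to run roughly 2-3-fold below the GC-window estimate. A region
counts as "retained" when its ratio exceeds 0.5 copies per nuclear
genome (an exposed, admittedly arbitrary floor), and
`detect_retained_segments` reports maximal above-floor runs with gaps
under 100 bp bridged.

Coordinates are 1-based inclusive throughout, matching the reference
annotation style; BED output converts to 0-based half-open at the
boundary.

## Growth rate

`mu_max` ln-transforms the OD series and takes the maximum ordinary
least-squares slope over all 50-point sliding windows (step one point).
At 5-minute sampling a window spans 245 minutes. The estimate is exact
on a pure exponential for any window size, slightly conservative on a
logistic (the window straddles the inflection), and no correction is
applied for OD non-linearity at high density — the estimate is simply
reported as potentially biased there. Non-positive OD values are
rejected rather than clipped; blank subtraction is the caller's
responsibility.

## Synthetic data

The generators produce inputs with the statistical structure the
estimators assume, each emitting a truth record:

* `gen_depth_profiles`: negative-binomial depth (dispersion 0.2 by
  default; variance $\mu + d\mu^2$) — Poisson would understate the
  overdispersion of real coverage — with a single-step AT dropout
  factor (default 3, inside the observed 2.3-3.4 range) outside the
  GC window, and hard zeros inside deletions. The nuclear profile is
  20 kb by default: a representative sample of the depth distribution,
  not a genome-scale simulation.
* `gen_growth_curve`: logistic OD trajectories (default
  $od_0 = 0.05$, $K = 2$, 216 points at 5-minute spacing — an 18-hour
  plate run) with multiplicative log-normal noise.
* `gen_strain_panel`: strains with known true fitness; zygote
  heteroplasmy derives from mutant copy numbers (default 22 values
  spanning 25-150 against a wild-type parental copy number of 15.5, so
  every mutant exceeds the parent, as observed for deletion strains);
  true suppressivity comes from running the simulator, and the observed
  value adds binomial colony-sampling noise (default 100 colonies).

What the generators do **not** model — mating-efficiency variation,
concatemeric segregating units, per-base GC content, secondary
deletions arising during propagation — bounds what passing tests show:
they validate the estimators under the model's own assumptions, not the
full messiness of plate data.

## Numerical choices and edge cases

* Phenotype comparisons use a $10^{-9}$ tolerance around $\tau n$ so
  binary representation of thresholds like 0.4 cannot flip a boundary
  cell.
* Grid seeds are a deterministic hash of (master seed, $h_0$, $f$,
  replicate), making grids invariant to the ordering of the value
  lists.
* A suppressivity of exactly 0 or 1 at $h_0 = 0$ or 1 is structural
  (homoplasmy is absorbing), so those boundary results are exact, not
  approximate.
* `drift_comparison` reports $p = 1$ when every paired difference is
  exactly zero (the signed-rank statistic is undefined there) and marks
  the test unavailable with fewer than two non-zero differences.
* Results are insensitive to halving the scheduler tick to 0.5 min
  within Monte-Carlo error; the division-time grid rounds doubling
  times up to the next tick.

## Problem sizes used by the tests and the acceptance script

Simulation-heavy checks run at a reduced, fixed scale chosen once:
200 founding cells for grid and panel simulations (the full 1000-cell
default is exercised by the neutral-drift checks), an inference grid of
$h_0 \in \{0, 0.1, \ldots, 1\}$ and $f \in \{0, 0.1, \ldots, 2\}$ with
5 replicates, 20 replicate panels of 22 strains for null/power
calibration, and robustness sweeps over $\tau \in \{0.4, 0.5, 0.6\}$
and $n \in \{10, 20, 50\}$ varied one at a time. These sizes give
Monte-Carlo errors comfortably inside the asserted tolerances while
keeping the whole suite in the minutes range.

## Known limitations

* The model has no cell death and no upper population bound; it is a
  20-24 h mating-culture model, not a chemostat model.
* kNN inference inherits the grid's coverage: strains whose
  $(h_0, s)$ falls where suppressivity barely responds to fitness
  (low heteroplasmy, or fitness near 0 where suppressivity is pinned
  at 0) are estimated towards the local neighbourhood average, with
  wide effective uncertainty. The panel-level test against 1 is the
  robust readout, not individual strain values.
* The copy-number estimator deliberately does not correct for
  concatemeric mtDNA or for the AT dropout itself; estimates are
  therefore comparable within a sequencing design, and are
  underestimates in absolute terms when all quantification regions sit
  outside the GC window.
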