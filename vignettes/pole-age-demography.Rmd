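---
title: "Pole-age lineage analysis and the demographic cost of bacterial aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pole-age lineage analysis and the demographic cost of bacterial aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poleage)
```

## The model of individuality: pole age

Rod-shaped bacteria divide by binary fission, but the two products are not
equivalent: one inherits a pre-existing ("old") cell pole, the other is built
around the pole formed at that division. `poleage` adopts the convention that
the *older pole defines the individual*. A new individual emerges from
division holding a pole of age 1; at each of its divisions the old-pole
product keeps the identity and its pole age increases by one, while the
new-pole product starts a fresh individual at age 1. An individual's $k$-th
division therefore occurs while it holds pole age $k$, and an individual that
permanently ceases dividing after $k$ divisions is recorded as stopping at
pole age $k + 1$ — the age it holds from its final division onward.

Under this bookkeeping a fully dividing population has the exponential stable
age structure $\pi(n) = 2^{-n}$: half of all cells hold a pole of age one, a
quarter of age two, and only about one cell in a million a pole of age 20 or
more. This is the quantitative reason why mortality restricted to old poles
is nearly invisible to selection, and it anchors several of the package's
exact tests (`pole_age_census()` on an enumerated complete binary tree
reproduces it digit for digit).

## Lineage reconstruction

`build_lineage()` collapses a per-frame tracking table into one node per cell
cycle and connects each parent to its two post-division children; the
division time is the parent's last observed frame, and children appear on the
first frame at or after the division. Which child carries the old pole must
be *declared* (column `old_pole_child`): orientation comes from simulator
ground truth or, for real data, from whatever upstream analysis established
it. No geometric inference is attempted — a wrong silent guess would corrupt
every downstream statistic.

Roots have unknown initial pole age, so ages along a root's chain are
relative. Three explicit policies control which individuals enter statistics:

* `exclude_first_division` (default, agar colonies): the founder individual,
  whose first division cannot be oriented, is excluded;
* `discard_root_use_last_daughter` (mother machine, short-lived strains): the
  bottom cell is discarded and analysis starts from its last daughter;
* `keep_root_as_unknown` (mother machine, long-lived strains): bottom cells
  are retained; since an unknown-age pole can only be older, their ages are
  conservative lower bounds.

Policies never alter the age annotation itself, only the `included` flag —
so a census over an annotated tree is policy-independent.

## The stop-of-division criterion

Arrest must be distinguished from slow division and from truncated
observation. An individual is *stopped* when it divides no more before the
end of its observation **and** the terminal gap exceeds `interval_factor`
(default 2) times the mean interdivision interval; it is *censored* when the
gap is too short to tell; it is *excluded* when observed for less than
`min_observation` (default 850 min, i.e. 170 frames at 5 min). Both
inequalities are deliberate about their edges: a gap of exactly twice the
mean interval is **not** a stop (strict `>`), an observation of exactly
850 min **is** kept (`>=`). The mean interdivision interval is estimated per
experiment from all observed intervals of included individuals (birth to
first division counts as an interval), with a per-call override.

`stop_curve()` turns fates into per-pole-age statistics. An individual is at
risk at age $a$ if it was observed holding that age with a classifiable
outcome: stopped individuals up to their stop age, censored ones up to their
last observed division (afterwards they leave the risk set — this convention
avoids censoring bias inflating late hazards). The per-division probability
is events over at-risk, and the cumulative curve is
$F(a) = 1 - \prod_{i \le a}(1 - h(i))$, an identity the tests verify exactly.
`median_stop_age()` offers the integer reading (smallest age with
$F \ge 0.5$) and a linear interpolation of the 0.5 crossing; the interpolated
estimator is one reasonable convention among several, which is why the
discrete median is the headline statistic.

The age trend in the hazard is tested by logistic regression of the
per-division stop indicator on pole age, each division opportunity treated as
an independent observation. Complete separation is detected and flagged
rather than silently reported with a meaningless Wald p-value. All p-values
in the package are two-sided and uncorrected; related predictors (size,
concentration) are fitted separately, not jointly.

## The Euler–Lotka model

The population-level cost of pole-age-specific mortality is computed from a
discrete renewal equation. With a fixed interdivision time $T$ and
survivorship $l(n) = \prod_{i=1}^{n}(1 - h(i))$ (the probability of
completing the $n$-th division), the Malthusian rate $r$ solves

$$ 1 \;=\; \sum_{n \ge 1} l(n)\, e^{-r n T}, $$

one newborn per completed division, the mother retaining her identity — the
fecundity convention that matches the pole-age frame. The solver bisects on
$x = e^{-rT} \in (0,1)$ to $10^{-14}$ in $x$; terms are truncated below
$10^{-16}$ with a hard cap of 500. An all-zero hazard returns $\ln 2 / T$
exactly. The headline quantity is the *relative* reduction
$(r_0 - r)/r_0$ against the immortal reference $r_0 = \ln 2/T$; expressed per
division it is invariant under rescaling of $T$, which the tests check to
$10^{-10}$.

Two independent routes guard the solver. First, the same demography is a
Leslie matrix (class-$i$ cells survive to class $i+1$ and produce one
class-1 newborn, both with probability $1-h(i)$); its dominant eigenvalue
must satisfy $r = \ln\lambda / T$, and 100 random schedules agree to
$10^{-9}$. Second, the stable pole-age distribution
$\pi(n) \propto l(n-1)\,(x^{n-1} - x^{n})$ must be proportional to the
Leslie right eigenvector, and reduces to $2^{-n}$ exactly for zero hazard.

Two fixed points connect the model to the biology: a schedule that lets every
cell complete exactly 17 divisions costs the population only
$\approx 5.5 \times 10^{-6}$ of its growth rate — below the selection
threshold $1/N_e = 10^{-5}$ for an effective population size of $10^5$ — and
the cost decreases strictly with the onset age of mortality (asymptotically
$2 \cdot 2^{-(A+2)}/\ln 2$ after $A$ completed divisions). Mortality like the
measured mutant schedule (onset around age 3–4) costs several percent and
would be purged by selection; the same mortality shifted to onset near age
17–18 would be effectively neutral. Note the off-by-one lurking in "onset":
hazard first acting at pole age $a$ means $a-1$ completed divisions; the
sub-$10^{-5}$ statement is about 17–18 *completed divisions* (first nonzero
hazard at age 18–19).

The analytic model keeps $T$ fixed. Interval variance is left to the
simulator, where the recovered reductions stay within sampling error of the
fixed-$T$ prediction; a full integral-equation treatment with an interval
distribution is out of scope.

## What the synthetic data emulate — and what they do not

`simulate_lineage()` is an agent-based generator of tracking tables with the
statistical structure the analysis assumes:

* **Stopping**: at each pole age $a$ a Bernoulli draw with probability
  $h(a)$, or alternatively a mechanistic rule (arrest when the inherited
  aggregate exceeds a threshold). Both produce the same output schema.
* **Growth and division**: lognormal interdivision times (mean 40 min,
  CV 0.1 by default — the distribution is a stand-in, chosen for
  positivity; the source experiments do not report one), exponential length
  growth with division at twice the birth length, multiplicative noise on
  the division site, and an optional size penalty on the old-pole product of
  a terminal division (emulating the observation that cells emerge smaller
  from their last division).
* **Arrest phenotype**: a stopped cell elongates a residual 7.5% over a
  25-min linear ramp and then halts. Measured on the 5-min frame grid the
  read-out is slightly lower (≈6.7%), because the ramp is anchored at the
  true division and measured from the first frame after it.
* **Geometry**: agar colonies observe the complete binary tree;
  mother-machine channels observe the bottom cell's chain fully, then — after
  each arrest — the arrested cell's last daughter becomes the new bottom-most
  dividing cell (three fully observed generations per channel by default);
  all other daughters are pushed out after one cycle and their descendants
  are never seen.
* **Reporters**: the aggregate-like signal is produced at a constant rate;
  at division the polar stock stays with the mother and the daughter receives
  a fraction $1-\rho$ of the *current cycle's production* only (retention
  $\rho \in [0.5, 1]$, default 0.85). This is what makes mothers accumulate
  while daughters are born with an approximately constant amount — a
  fixed-fraction split of the whole pool cannot produce that pattern. The
  chromosome-like signal doubles over a normal cycle and splits 1:1; in a
  terminal cycle replication is suppressed and the daughter inherits ~98% of
  it. Both signals are conserved at every division to the last floating-point
  digit, and production halts in arrested (chromosome-less) cells.
* **Spatial profiles**: the cytoplasm holds up to 50 AU/µm of reporter
  diffusely; the excess packs against the old pole at 400 AU/µm, so the
  old-pole quarter's share rises first and the aggregate fills the cell only
  near the end of life. The packing constants are phenomenological, chosen so
  that a cell arrests roughly when filled.
* **Plates**: OD600 curves are flat during the lag, *exactly* exponential at
  the specified rate below half the carrying capacity, then logistic. A
  textbook logistic is already ~5–10% slower than its nominal rate inside the
  fitting window (0.0625–0.125 at $K = 1.2$), which would contradict a
  "specified exponential-phase rate"; the piecewise form keeps the window
  clean while still saturating. Per-read noise is multiplicative lognormal
  (CV 1% by default), with optional well-to-well rate variability.

Because stopping in the default (hazard) mode is drawn independently of the
cell's reporter content, passing tests on hazard-mode data say nothing about
mechanistic correlations — birth concentration does *not* predict replicative
potential there, by construction. The mechanistic threshold mode exists for
exactly those pattern-level checks. More generally, the generator reproduces
the bookkeeping structure of time-lapse data, not microscopy itself: no
segmentation error, no drift, no background fluorescence, no photobleaching,
no spatial crowding. Green tests demonstrate that the estimators recover
known generative truth, not that real images would be analyzed correctly.

## Doubling times from plate curves

`estimate_doubling_time()` regresses $\log \mathrm{OD}$ on time using only
readings with OD inside $[0.0625, 0.125]$ (bounds inclusive; the window is
one doubling wide) and converts the slope to $\ln 2/\mathrm{slope}$ — the
logarithm base cancels, so log2, ln and log10 fits are identical. A fit is
rejected when the windowed $R^2$ (squared Pearson correlation) is below 0.99
or the slope is non-positive. Selecting the window on *noisy* readings biases
the slope (points fluctuate asymmetrically across the window edges); the bias
grows roughly with the square of the read noise and reaches several percent
at CV 5% — but such curves essentially never pass the $R^2$ filter. For
curves that do pass at realistic read noise (CV ≈ 1%), the bias stays below
1% of the doubling time, which is what the test suite asserts.

## Fluorescence quantification

Integrated density is mean per-pixel intensity × pixel count; concentration
divides it by a cylinder volume of height = cell length and diameter =
channel width (1.2 µm). The source wording ("mean intensity … calculated a
concentration") is ambiguous between per-pixel and per-volume readings; the
cylinder definition is used for dimensional consistency and the per-pixel
mean is kept available separately. Quarter profiles split the long-axis
column profile (old pole first) into four equal parts, remainder columns
assigned by the largest-remainder rule with ties toward the old pole;
lifetime summaries interpolate quarter shares onto a 101-point normalized
lifetime grid (birth to last division — the arrested plateau is not part of
the dividing lifetime) and report per-gridpoint medians with quartile bands.
The mother/daughter division panel compares signals just after the first,
second-last and last division; its qualitative flags use fixed documented
thresholds (mothers at least 1.5-fold up and strictly increasing with
daughters within 25% of each other → aggregate-like; mother collapsing below
half its second-last value with mother ≈ daughter before → chromosome-like).

## Problem sizes and numerical choices

The shipped analyses and tests use 4096-leaf enumerations for the exact
$2^{-n}$ census, ~1000 fully observed individuals for the pipeline median,
10,000 direct draws for hazard-recovery bounds (3 binomial SDs), 100 random
schedules for the Leslie cross-check ($10^{-9}$), 100 replicates for the
type-I calibration of the trend test, and 48 wells per strain for the plate
analyses — sizes at which every stochastic acceptance bound holds with wide
margin while the whole suite runs in about a minute. Bisection tolerances
($10^{-14}$ in $x$), term truncation ($10^{-16}$, cap 500) and the
separation guards in the logistic fits are the only numerical knobs; none is
data-dependent.

## Known limitations

* The hazard schedule shipped as the default study condition is a plausible
  reconstruction of the mutant's measured mortality pattern, not a fit to
  raw data (which are not deposited); consequently the predicted growth-rate
  cost (~10%) matches the published "about 6%" only in order of magnitude.
* Old-pole orientation must be supplied; data lacking it cannot be analyzed.
* The Euler–Lotka model ignores interval variance and treats arrest as
  demographic death (arrested cells persist in images but not in the renewal
  accounting).
* No multiple-testing correction is applied anywhere, mirroring the source
  analyses; interpret families of p-values accordingly.
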