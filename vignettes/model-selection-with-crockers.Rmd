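---
title: "Selecting models of collective motion with crocker matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting models of collective motion with crocker matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crocker)
```

## The scientific setting

Pea aphids walking in a featureless circular arena move intermittently:
they alternate between a stationary state and bouts of movement, and their
behaviour appears to change when another aphid is nearby. Two stochastic
models formalize this. In the **interactive model**, the per-frame
probability that a moving aphid stops, the probability that a stationary
aphid starts, the step length while moving, and the concentration of the
turning-angle distribution all depend on the distance $d$ to the aphid's
nearest neighbour. The **control model** is the same walk with every one of
those quantities frozen at its $d \to \infty$ limit, so aphids ignore each
other. Given a reference set of trajectories, the package decides which
model is more faithful to it.

This package implements the full analysis chain: the simulator, a
synthetic-data generator standing in for the (non-public) experimental
tracking data, order-parameter and topological trajectory summaries, and
the ensemble statistics that turn summary distances into a verdict.

## The walk model and its assumptions

Each agent carries a position, a heading, and a binary motion state, updated
synchronously once per 0.5 s frame:

1. distances $d_i$ to the nearest *present* neighbour are computed from the
   positions at the start of the frame (an agent with no present neighbour
   uses $d = \infty$, i.e. behaves non-socially for that frame);
2. states flip with probabilities $P_{MS}(d)$ (moving to stopped) or
   $P_{SM}(d)$ (stopped to moving);
3. each agent moving after the flip advances by $\ell(d)$ along its current
   heading, is reflected at the arena boundary if it overshot, and then
   turns by a wrapped-Cauchy angle with spread $\rho(d)$. Stationary agents
   keep position and heading.

The functional forms and fitted constants (defaults of
`aphidModelParams()`) are:

| quantity | form | $d=0$ | $d\to\infty$ | length scale |
|---|---|---|---|---|
| $P_{MS}(d)$ | exponential decay | 0.5508 | 0.1280 | 0.0134 m |
| $P_{SM}(d)$ | decay + saturating rise | 0.1587 | 0.3552 | 0.0079 m, $\Delta$ 0.0739 m |
| $\ell(d)$ | exponential rise | 0.0003 m | 0.0013 m | 0.0074 m |
| $\rho(d)$ | exponential rise | 0.1387 | 0.9013 | 0.0044 m |

So an isolated aphid moves often, takes long, nearly straight steps
($\rho$ close to 1), while a crowded aphid stops more, steps less, and
turns erratically. These opposing pressures produce a preferred social
distance; the control model has none.

Several micro-choices are not pinned down by the model statement and are
explicit options here, with the defaults we consider the most natural
reading:

* **Initial states** are all-stationary by default
  (`initialStates = "steady"` draws each agent from the two-state Markov
  stationary distribution at its initial $d$). The transient decays within
  tens of frames either way.
* **Initial headings** are uniform on $(-\pi, \pi]$ — the walk is unbiased,
  so no direction is privileged.
* **Update order**: state transition first, then step, then turn
  (`transitionTiming`, `turnTiming` select the alternatives). At the fitted
  parameters the orderings are statistically indistinguishable, but they
  are distinct algorithms, so both are exposed.
* **Boundary reflection** is a radial mirror ($r \mapsto 2R - r$ along the
  centre ray), with a specular option. The longest possible step
  (0.0013 m) is three orders of magnitude below the arena radius (0.2 m),
  so the two rules differ by less than the step length itself; the radial
  rule is used because it is unconditionally contained for such steps.
* **Random stream**: one generator per simulation, consumed in a fixed
  order (per-agent transition uniforms, then per-agent turn uniforms).
  This makes control-model state sequences identical across spatial
  configurations under the same seed — a property the tests exploit.

Wrapped-Cauchy sampling uses the inverse-CDF tangent transform
$\theta = 2\arctan\!\big(\tfrac{1-\rho}{1+\rho}\tan(\pi(u - 1/2))\big)$ of
a single uniform variate; the tests verify it against numerical integration
of the density (the circular mean resultant length of the distribution
equals $\rho$ exactly).

## What the synthetic data emulates — and what it does not

The experimental recordings behind the fitted constants (nine trials of 7
to 33 aphids, several thousand frames each) are not publicly deposited, so
the package generates its own study material:

* `generateInitialConditions()` draws starting configurations: `clustered`
  (uniform in a sub-disk of radius $0.25 R$, mimicking the tight initial
  huddles of most trials), `dispersed` (uniform over the arena), `ring`.
  The 0.25 fraction is a visual match to the published initial
  configurations, not a fit; it is configurable. `aphidTrialSizes()`
  provides the nine historical group sizes.
* `generatePseudoExperiment()` runs one model realization and overlays
  motion-tracking dropouts: each agent independently begins an absence run
  at a per-frame rate, with geometrically distributed run lengths. Real
  tracking gaps are described only qualitatively (aphids "dropped and
  picked back up"), so the memoryless model is the simplest emulation; no
  attempt is made to match the real gap statistics. Dropout draws happen
  after the simulation, so a pseudo-experiment with `dropoutRate = 0` is
  bit-identical to the plain run under the same seed.

A pseudo-experiment generated by the interactive model gives the analysis
a known ground truth: a correct pipeline should prefer the interactive
model. That is exactly what the self-consistency tests check. What passing
them does **not** show is that the interactive model describes *real*
aphids — the synthetic reference has the model's own noise structure,
perfectly Markovian gaps, and no tracking jitter, mislabeling, or identity
swaps. Conclusions about real data require real data.

## Order parameters

Velocities are one-frame backward differences (m/frame); with tracked
data an agent is classified stationary when it moved at most $10^{-4}$ m
in a frame (boundary case stationary), while simulated trajectories carry
exact states. Per frame we compute polarization $P$, angular momentum
$M_{ang}$, absolute angular momentum $M_{abs}$ (positions relative to the
instantaneous centre of mass of present agents; 2-D scalar cross products),
mean nearest-neighbour distance $d_a$, and percent moving. Conventions for
degenerate frames: if every present agent is stationary, $P = M_{ang} =
M_{abs} = 0$ (their $|v_i| = 0$ terms vanish from numerator and denominator
alike, which also means stationary agents are effectively excluded from
those sums — the literal reading of the formulas); frames with fewer than
two present agents have $d_a$ missing; missing values propagate as `NA`
and are dropped pairwise, never silently, when series are compared.

## Crockers

For each sampled frame (every fourth, by default) the package builds the
Vietoris–Rips filtration on the frame's point cloud and records the Betti
numbers $b_0$ (components) or $b_1$ (loops) at 50 proximity values sampled
uniformly from 0 to a maximum filtration scale — 0.2 for raw 2-D position
clouds (the arena radius), 1.5 for 4-D position⊕velocity clouds normalized
by 0.2 m and 0.0013 m (the longest step), so both blocks are order one.
The resulting $\epsilon \times t$ matrix is the crocker.

Numerical conventions, chosen once and documented because they are easy to
get silently wrong:

* A $k$-simplex enters the filtration at the largest pairwise distance
  among its vertices: edges exist at $\epsilon \ge$ distance ("pairwise
  within $\epsilon$").
* Persistence intervals are half-open, $[\mathrm{birth},
  \mathrm{death})$: $b_k(\epsilon)$ counts intervals with $\mathrm{birth}
  \le \epsilon < \mathrm{death}$. Coincident points therefore merge at
  scale 0, and $b_0(0)$ equals the number of *distinct* present points.
* The $\epsilon$-grid includes 0 as the first of its 50 samples.
* Ties in the filtration order are broken by dimension (faces before
  cofaces), which is the only constraint homology cares about.
* The complex is truncated at scale `maxEps`; classes alive beyond it get
  $\mathrm{death} = \infty$, so Betti counts are exact on the whole grid.
* Homology is over the two-element field, dimensions 0 and 1 only.
* Empty clouds give zero columns; dropout frames are computed on the
  reduced cloud (columns are independent — there is no inclusion between
  time steps, so the crocker is not a bifiltration, just a grid of
  filtrations).

Two independent code paths compute the same quantity. The production path
derives intervals from union-find merge heights ($b_0$) and the standard
boundary-matrix column reduction ($b_1$); the test oracle re-derives each
$b_k(\epsilon)$ from GF(2) ranks of dense boundary matrices at a single
scale, with a 25-point guard against combinatorial blow-up. The suite
checks them against each other on hundreds of random clouds in 2 and 4
dimensions.

The $b_1$ reduction is the expensive step — cost grows with the number of
triangles, roughly $n^3$ per frame — which is the known price of the
topological summaries; $b_0$ crockers on 25-agent, 500-frame trajectories
take well under a second each.

`mergeScale()` condenses a $b_0$ crocker column into the smallest grid
scale at which the group is a single component (the top of the grid if it
never is, since the grid's 0.2 m ceiling is below the 0.4 m arena
diameter). Its time trend measures dispersal: clustered groups drifting
apart push the merge scale up, which is the contour-rise phenomenon the
averaged crockers display and the qualitative trend test asserts.

## Comparison statistics

For a measure $\phi$ and ensembles of $n$ runs per model,
$D_{int}$ and $D_{con}$ are the mean Euclidean (series) or Frobenius
(crocker) distances from the reference to the runs of each model, and
$D = D_{con} - D_{int}$. The interval radius $R_{95}$ uses a Welch
unpooled-variance two-sample interval for a difference of means at level
$\alpha / n_{comp}$; the Bonferroni divisor defaults to 81, the
nine-measures-by-nine-experiments design of the original study, and is
configurable because synthetic studies run other layouts. The verdict is
`interactive` if $D - R_{95} > 0$, `control` if $D + R_{95} < 0`, else
`inconclusive`.

The interval construction is a deliberate design choice: the reference is
shared by both ensembles, which induces a positive correlation between the
two distance samples that the unpooled interval ignores. Treating the
ensembles as independent follows the independent-ensembles formulation of
the distances themselves; a paired interval would be narrower, so the
default errs conservative. Ensembles with zero variance (identical runs)
get $R_{95} = 0$ rather than an undefined $t$ quantile.

## Problem sizes used by the checks

The packaged checks run a deliberately scaled-down version of the full
study (which used 100 runs per model on trials of up to 5883 frames): the
self-consistency check uses a 25-agent clustered pseudo-experiment of 500
frames, 20 runs per model, repeated 10 times with distinct seeds, asserting
that $d_a$, percent moving, and the $b_0$ position crocker each recover the
generating model in at least 9 of 10 repetitions; the dispersal-trend check
averages 20 control-model $b_0$ crockers; sampler and transition-rate
calibrations use $10^6$ draws and $10^5$ frames. These sizes were chosen as
the smallest at which the ensemble statistics are comfortably away from
their decision boundaries.

## Known limitations

* The $b_1$ reduction in pure R is practical for the tens-of-agents clouds
  this study needs, not for hundreds of points per frame.
* The Frobenius/Euclidean metric weighs every grid cell equally; transport
  metrics (Wasserstein) on crockers are out of scope here.
* Parameter fitting from raw tracking data is out of scope; the constants
  are taken as given.
* The dropout generator is memoryless by construction and should not be
  used to study tracking-gap statistics themselves.
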