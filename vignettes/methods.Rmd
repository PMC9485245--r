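---
title: "Models and methods behind spiralflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spiralflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralflow)
```

# Scope

spiralflow models a combined roll / heading discrimination experiment:
optic-flow stimuli drawn from a 3D spiral space, multiunit (MU) tuning in
its two planes, a four-alternative forced-choice (4-AFC) report of flow
pattern and direction, and electrical microstimulation that injects an
artificial labelled-line signal into the decision. Because raw recordings
are not required, the package ships a first-class synthetic-data layer
(dot-cloud stimuli, tuned MU sites, behavioral sessions) whose ground
truth is known, so every statistic in the analysis layer can be validated
by recovery.

# The stimulus model

The stimulus is the projection of a camera moving through a dot cloud
that uniformly fills a 100 × 100 × 40 cm volume at 0.01 dots/cm³
(4,000 dots), viewed from ~32 cm so the display spans about 90° × 90°.
A flow pattern is a point in spiral space: a plane (roll or translation)
and an angle θ from straight forward within that plane. Coherence is
implemented per frame by an independent Bernoulli draw per dot — a
`coherence` fraction moves according to the camera-motion rule, the rest
are re-drawn uniformly in the volume. Two consequences worth knowing:

- the coherent set is not a fixed subset of dots, so a dot's lifetime in
  the signal stream is geometric, and
- dots leaving the volume under coherent motion are wrapped to the
  opposite face (the entry face), which keeps density exactly stationary.

The analysis layer never consumes rendered frames. What it uses are the
idealized first-order screen velocity templates,

$$v(\theta) = \cos\theta \cdot \text{radial} + \sin\theta \cdot \text{secondary},$$

with the radial basis pointing away from the fovea with magnitude
proportional to eccentricity, and the secondary basis either tangential
(clockwise for positive θ; roll plane) or uniform horizontal (leftward
for positive θ; translation plane). The templates are exactly linear in
$(\cos\theta, \sin\theta)$, which the tests assert. Sign conventions
throughout: positive roll = CW from the observer's view, positive
translation = leftward; screen axes +x right, +y up, fovea at origin.

The self-motion speed magnitude is never pinned down by the behavioral
design (only angles and coherences are), so `speed_scale` is a free
parameter: deg/s at 10° eccentricity for the templates, and reused as
cm/s (radial) / deg/s (rotation) when advancing the cloud. Similarity
statistics below depend only on vector *directions* and are invariant to
it.

# Tuning and its statistics

A synthetic MU site (`synth_mu()`) has a circular-Gaussian tuning bump
per plane, `baseline + amp * exp(kappa * (cos(dir - pref) - 1))`, sampled
at 8 directions per plane in 45° steps (the measurement granularity is a
package choice; it is configurable) with Poisson trial noise by default
(Gaussian with a Fano factor as an alternative). Defaults — baseline
10 spikes/s, amplitude 30, κ = 1.5, 5 repetitions — give realistic
MSTd-like rates and ANOVA power.

Statistics implemented:

- **Classification**: one-way ANOVA of trial rate on direction per plane
  with the two radial poles (0°/180°, shared between planes) excluded;
  spiral / roll-only / translation-only / untuned at the strict
  p < 0.001 rule. The looser p < 0.05 eligibility rule used for
  population spiral-index summaries is a separate, caller-side choice;
  both levels are plain function arguments.
- **Resultant vector**: the rate-weighted vector sum with roll-plane
  directions embedded in the (forward, roll) plane and translation-plane
  directions in the (forward, translation) plane. The radial poles are
  measured twice (once per plane) but embedded once, using the mean of
  the two measurements — summing them twice would double-weight the
  forward axis for purely geometric reasons. Raw mean rates are used
  (no spontaneous subtraction); `subtract_spontaneous = TRUE` switches
  this, since either convention is defensible and the choice matters
  only for weakly modulated sites.
- **Spiral index** `(cos α − cos β)/(cos α + cos β)` with α the angle of
  the resultant to the translation plane and β to the roll plane. A pure
  forward resultant lies in both planes (α = β = 0), giving index 0 —
  equal preference — rather than an undefined value; the denominator can
  only vanish for the zero vector, which is rejected earlier.
- **d′ and ROC**: d′ from the ±90° conditions with the pooled-SD
  denominator; ROC as the normalized Mann-Whitney statistic with ties
  credited 1/2, verified in the tests against an all-pairs enumeration.
- **Clustering index**: Pearson correlation of two sites' mean-rate
  curves in one plane; callers pair sites at Δdepth of 100–300 μm.
  Constant curves return `NA` rather than a fabricated correlation.
- **Similarity index**: the two preferred-flow templates sampled on a
  1°-step grid inside the rectangular RF; the index is the fraction of
  grid points with inter-vector angle < 45°. Points within 0.5° of the
  fovea are excluded (both basis fields vanish there and direction is
  undefined), as are near-zero vectors. The analytic check: pure
  rotation vs pure laminar flow over a fovea-centred RF gives 0.25,
  because the tangential direction is uniform in polar angle and the
  wedge within 45° of a fixed direction covers 90°/360°.

# The decision model

The three qualitative microstimulation outcomes — bias within one
pattern, bias within both, bias within and *between* patterns — are
outcome descriptions, not mechanisms. The package realizes them with the
simplest generator that reproduces all three: independent Gaussian
decision variables per axis,

$$d_R = x_R + \delta_R s + \varepsilon_R, \qquad
  d_T = x_T + \delta_T s + \varepsilon_T,$$

a two-stage readout (choose the roll pattern iff
$|d_R| - |d_T| > \text{bias}$, then report the sign of the chosen axis),
and a per-variant stimulation mapping: variant 1 injects δ into one axis
only, variant 2 into both, variant 3 additionally shifts the arbitration
criterion on stimulated trials (positive `pattern_shift` = toward
translation choices). A `lapse` fraction guesses uniformly over the
available targets. Ties $|d_R| = |d_T|$ are measure-zero under Gaussian
noise and broken by the strict inequality. In the coarse task version the
decision-variable mean is linear in signed coherence, with the slope
absorbed into σ, so both versions share one parameterization.

`choice_probabilities()` integrates the rule in closed form (1D adaptive
quadrature over each axis's half-line, rel.tol 1e-11, with explicit
splits at the integrand's kink and at the density peak); the four
probabilities sum to 1 within 1e-9 and are the oracle against which the
Monte-Carlo session simulator is tested (χ² goodness-of-fit at 10⁵
trials).

**Default noise levels.** The behavioral reports give psychometric
thresholds (roughly 2–8° fine) but no generative parameters, and in this
two-stage model the same σ that sets the direction threshold also sets
pattern-identification accuracy — a coupling real observers do not seem
to share, as they identify patterns better than the |d| comparison
predicts at matched σ. The defaults σ_roll = 3, σ_trans = 1.5 axis units
were chosen once so that the simulated observer both has within-pattern
thresholds in the reported range and passes the standard 65%
flow-pattern correct-rate inclusion gate (~69% expected), i.e. behaves
like a session that would actually enter the analyses.

**Reward.** Non-ambiguous trials are rewarded iff the choice matches
plane and direction. The ambiguous reference carries no information and
is rewarded at random; the probability is set to 0.5 (the natural
uninformative value — the experimental description says only "random").

# The psychometric layer

Three constructions from the 4-AFC counts: within-pattern
(CW/(CW+CCW) or Left/(Left+Right)), general error (same numerator over
all four choices), and flow-pattern ((Left+Right)/all four against a
signed axis in [−1, 1]; each axis's levels are scaled by its largest
absolute level so the ambiguous reference sits at 0 and the extreme
levels at ±1). Zero denominators yield missing values, never zeros.

`fit_cumgauss()` is a two-parameter binomial maximum-likelihood fit of
Φ((x−μ)/σ): initialization by probit-transformed weighted linear
regression, Nelder-Mead, then BFGS polishing with the analytic gradient
on (μ, log σ); σ is bounded below at 1e-6 axis units and standard errors
come from the inverse Hessian (delta method for σ). On data lying
exactly on a cumulative Gaussian the fit recovers μ and σ to 1e-6. No
lapse parameter is fitted (the construction is deliberately the
two-free-parameter one); with lapsing observers this inflates σ, a
documented limitation. Fits are naturally weighted by trials per level
through the binomial likelihood. All-0/all-1 data returns boundary
estimates flagged `converged = FALSE`, and downstream code uses
converged fits only.

Stimulation significance uses the probit regression
$\Phi(b_0 + b_1 x + b_2 s + b_3 x s)$ — the interaction model nests both
the "separate curves" and "shift only" readings; $b_2$ tests the PSE
shift and $b_3$ the slope/threshold change, two-sided Wald at α = 0.05.
With s constant the model collapses to the cumulative-Gaussian
parameters ($-b_0/b_1 \approx \hat\mu$, $1/b_1 \approx \hat\sigma$),
which the tests verify. No multiple-testing correction is applied across
sites; per-site significance is reported as-is, matching standard
practice for this analysis, and population summaries (medians, sign
tests) call the stock R routines.

Sign conventions are centralized: ΔPSE is `preferred_sign × (μ_ctrl −
μ_stim)`, positive when stimulation produces more choices of the
stimulated site's preferred direction; the normalized version divides by
the control threshold so roll (deg), translation (deg) and coarse (%)
effects are comparable. The choice-change index uses the ambiguous
reference plus, by default, the smallest nonzero level on each axis
(near-threshold conditions where pattern confusions concentrate; fully
configurable), and applies the 65% control correct-rate gate before
anything is computed.

# Pipeline, seeding and problem sizes

`run_simulate()` derives session *i*'s seed as `seed + i` and records
the scheme plus MD5 hashes in a manifest; identical configs give
byte-identical CSVs. `run_analyze()` writes the per-session effects
table and a JSON report whose every number is recomputable from the
stored trial tables. `run_recover()` sweeps a (δ, σ, variant) grid and
reports bias and CI coverage against the generative truth.

The shipped tests run at deliberately desk-sized problem sizes chosen to
make their statistical assertions well-powered while staying quick:
500 replicate fits for CI coverage (9 levels × 200 trials), 1,000 null
sessions for probit type-I calibration, 100–200 sessions per model
variant for the CCI discrimination checks (the variant-2 check uses the
coarse design with equal σ and δ on both axes, the symmetric
configuration in which the no-interaction model provably leaves expected
pattern frequencies at 1/2), and 10⁵ trials for the χ² match between the
simulator and the closed form.

# What the generator does and does not emulate

Emulated: the fine (±11.54°, ±5.74°, ±2.87°, ±1.15°, 0°) and coarse
(±8%, ±4%, ±2%, ±1%, 0%) level grids with the shared ambiguous
reference; 1:1 interleaving of stimulated and control trials; 4-AFC and
blocked 2-AFC paradigms; Poisson-like MU tuning noise; labelled-line
stimulation under the three readout variants.

Not emulated: reaction times, fixation breaks and training dynamics;
serial dependencies across trials (trials are exchangeable given the
design); correlated noise between the two axes (the decision model assumes
independence, which keeps the choice probabilities a pair of 1D
integrals); depth-dependent dot speeds in the similarity
analysis (it uses the first-order templates, as the quiver-plot analyses
do); and any non-stationarity of tuning within a session. Consequently,
passing tests demonstrate the correctness and calibration of the
*statistics* under the stated generative model — not that real MSTd
sessions satisfy that model.

# Known limitations

- The two-stage arbitration couples direction and pattern sensitivity
  through one σ per axis; matching both aspects of real behavior exactly
  would need a separate pattern-noise parameter.
- The cumulative-Gaussian fit has no lapse term, so extreme-level lapses
  bias σ upward.
- The CCI is a ratio of frequencies and is undefined when the control
  translation-choice frequency is 0; such sessions are reported missing
  rather than imputed.
- Receptive fields are axis-aligned rectangles; elliptical RFs would
  change only the similarity-index integration region.
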