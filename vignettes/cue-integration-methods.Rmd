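---
title: "Methods: categorical audio-visual cue integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: categorical audio-visual cue integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuecat)
```

# The model

## Cue combination for continuous estimates

Given independent Gaussian internal estimates of an auditory and a visual
cue with variances $\sigma^2_A$ and $\sigma^2_V$ (in continuum step
units squared), the minimum-variance linear combination weights each cue by
its inverse variance,

$$ w_A = \frac{1/\sigma^2_A}{1/\sigma^2_A + 1/\sigma^2_V}, \qquad
   w_V = 1 - w_A, $$

and the combined estimate has variance

$$ \sigma^2_{AV} = \frac{\sigma^2_A\,\sigma^2_V}{\sigma^2_A +
   \sigma^2_V} < \min(\sigma^2_A, \sigma^2_V). $$

`predict_weights_sensory()` and `combined_variance()` implement these.
They form the *sensory-only* normative predictor: the weights an optimal
observer would use if trial-to-trial sensory noise were the only source of
uncertainty.

## Cue combination for categorical decisions

A 2AFC phoneme-labeling task is a categorization, not an estimation: the
observer must map a noisy bivariate signal $(a, v)$ onto one of two
categories (/ba/ or /da/), each of which is itself a *distribution* of
exemplars in the world. We model the two categories as Gaussians in the
joint audio-visual feature space with equal diagonal covariance. The
optimal categorizer projects the signal onto the Fisher linear
discriminant and compares the decision variable

$$ D = w_A a + w_V v $$

to a criterion $k$. With uncorrelated noise the discriminant weights are

$$ w_A \propto \frac{\Delta_A}{\sigma^2_{A,\mathrm{sens}} +
   \sigma^2_{A,\mathrm{env}}}, \qquad
   w_V \propto \frac{\Delta_V}{\sigma^2_{V,\mathrm{sens}} +
   \sigma^2_{V,\mathrm{env}}}, $$

normalized to sum to one (`predict_weights_categorical()`). Here
$\Delta$ is the separation between the category means along each cue
dimension and $\sigma^2_\mathrm{env}$ is the *environmental* (production)
variance of exemplars within a category — variability that exists in the
world and is therefore untouched by degrading the stimulus. With equal
separations and zero environmental variance the rule collapses exactly to
inverse-variance weighting, which the tests verify.

The central qualitative signature follows directly: as visual blur raises
$\sigma^2_{V,\mathrm{sens}}$, the categorical weights change *less* than
the sensory-only weights, because the constant environmental term dilutes
the manipulation. `fit_environmental_variance()` inverts this signature,
finding the nonnegative $(\sigma^2_{A,\mathrm{env}},
\sigma^2_{V,\mathrm{env}})$ that minimize the mean squared difference
between predicted and observed visual weights across blur levels.

## The bimodal variance identity

For *any* linear integrator with normalized weights — optimal or not —
the variance of the combined estimate is

$$ \sigma^2_{AV} = w_A^2 \sigma^2_A + w_V^2 \sigma^2_V. $$

Solving for $\sigma^2_V$ given the fitted bimodal variance, the unimodal
auditory variance, and the observed weights
(`infer_bimodal_visual_variance()`) yields an estimate of the visual
noise operating *during cue combination*, with no optimality assumption.
This matters because the perceptual strategy used in a video-only block
(e.g. judging lip aperture) need not match the strategy used on bimodal
trials; when the two variances disagree grossly, the single-cue estimate
is the wrong input to the normative predictor. The pipeline therefore
produces both an *uncorrected* prediction (unimodal visual variances) and
a *corrected* one (bimodal-inferred variances), and flags participants
whose mean inferred bimodal visual variance exceeds a ratio threshold
(default 4) times their mean unimodal visual variance
(`flag_outliers()`). A ratio — not an absolute difference — is used
because the continuum step scale is arbitrary. The threshold sits well
above the sampling scatter of consistent observers (ratio near 1, roughly
lognormal with spread well under twofold at 26 repetitions) and well
below the ninefold variance inflation of the planted inconsistent
observers used in validation; sensitivity is not delicate to its exact
value.

# The psychometric model

Responses are modeled as a mixture of a Gaussian discrimination process
and stimulus-independent guessing ("lapses"):

$$ P(\text{respond /da/} \mid x) = \frac{\lambda}{2} +
   (1 - \lambda)\,\Phi\!\left(\frac{x - \mu}{\sigma}\right), $$

where $\mu$ is the PSE (category boundary), $\sigma$ the SD of the
underlying discrimination process (inverse slope, the quantity entering
all variance computations), and $\lambda$ the lapse rate. Guesses respond
/da/ with probability exactly one half — the minimal symmetric reading of
a "random guessing" process — and a single $\lambda$ is shared across the
stimuli of one fit: with 26 repetitions per condition, per-condition
lapse rates would be badly over-parameterized. Ignoring lapses is known to
bias slope estimates, which is why the mixture is fitted rather than the
bare cumulative Gaussian.

Bimodal trials at one blur level are fitted with the two-dimensional
surface

$$ P(\text{/da/} \mid a, v) = \frac{\lambda}{2} + (1 - \lambda)\,
   \Phi\!\left(\frac{w_A a + (1 - w_A) v - c}{\sigma_{AV}}\right), $$

jointly estimating $(w_A, c, \sigma_{AV}, \lambda)$. The weights are
constrained to sum to one: the linear rule is invariant to a common
rescaling of weights, criterion and SD, so the constraint fixes the gauge
without loss of generality. On the no-conflict diagonal ($a = v$) the
weights enter only through their sum, so the fit refuses data spanning
fewer than two distinct conflict offsets rather than returning an
arbitrary point on the ridge.

## Numerical choices

* Likelihoods are binomial over aggregated stimulus cells; analytic
  gradients are supplied to the optimizer.
* Optimization is bounded quasi-Newton (`optim`, L-BFGS-B) from 8
  multi-starts — a coarse grid over $(\mu, \sigma)$ (or $(w_A,
  \sigma_{AV})$) plus two data-driven moment starts — because the
  likelihood can be multimodal in $(\sigma, \lambda)$. The returned
  optimum is verified (and unit-tested) to dominate every start; among
  ties within the $10^{-8}$ objective tolerance a cleanly converged run
  is preferred.
* Bounds: $\sigma \in [0.05, 20]$ step units, $\lambda \in [0, 0.35]$,
  $\mu, c \in [-5, 16]$. They contain degenerate fits while covering
  anything the 1–10 design can produce. A fit whose $\sigma$ lands on the
  lower bound (perfectly separated step-function data) is flagged
  `degenerate` rather than silently accepted.
* Bootstrap CIs are nonparametric percentile intervals: trials are
  resampled with replacement within each stimulus condition (equivalent
  to redrawing each cell count from its empirical binomial), each
  replicate is refitted from a warm start at the point estimate, and
  degenerate replicates are dropped and counted, with a warning above
  20% drops. Intervals are deterministic given the seed.
* The environmental-variance objective is optimized on a square-root
  parameter scale (enforcing nonnegativity smoothly) by Nelder–Mead with
  a BFGS polish from a $5 \times 5$ log-spaced grid of starts plus the
  zero corner; in the noiseless inverse-crime setting it recovers
  generating parameters to machine precision.

# The experimental design

`build_design()` enumerates 10 audio-only conditions, 10 video-only
conditions at each of 4 blur levels, and 32 bimodal pairs at each blur
level — 178 conditions, 4628 trials per participant at 26 repetitions,
1157 per session over 4 sessions. Audio is never blurred; blur applies to
the visual stream including the visual component of bimodal stimuli.
Sessions hold one unimodal and one bimodal block with order
counterbalanced across sessions, and trial order is randomized within
blocks; this structure has no effect on fitting and exists so simulated
tables mirror the real protocol. Repetitions are spread round-robin over
sessions with a global cyclic counter so session totals stay balanced; a
warning is issued if the total cannot divide evenly.

The 22 cue-conflict pairs are only constrained by their published
composition (32 pairs total, 10 no-conflict, conflicts within ±3 steps).
The generator picks them deterministically: candidate off-diagonal pairs
are ordered by distance of their midpoint from the continuum center, then
by conflict size, and the first 11 above-diagonal pairs plus their
mirror images are taken. This yields a sign-balanced set concentrated on
central steps 3–8, where the psychometric surface is steep and therefore
most informative about the weights. The set is overridable
(`build_bimodal_pairs(pairs = ...)`) for users who wish to impose a
specific layout.

# The observer simulator

`observer_params()` defines a mechanistic generative observer: on each
trial, with probability $\lambda$ it guesses (fair coin); otherwise it
draws Gaussian internal estimates around the presented step(s), combines
them with its weighting rule, and compares the decision variable to a
fixed criterion. Three weighting rules are supported — inverse-variance
(`sensory_optimal`), Fisher-discriminant with environmental variance
(`categorical_optimal`), and arbitrary `fixed` weights, the last so that
the weight estimator can be shown not to presuppose optimality. A
closed-form response probability (`response_prob()`) serves as the
independent oracle against which the Monte-Carlo simulator is tested.

Defaults define the emulated study conditions and were chosen once, on
field-typical grounds:

* `sigma_a = 2.0` steps; `sigma_v = (0.8, 1.2, 1.6, 2.0)` steps across
  blur levels. The unblurred visual cue is substantially more reliable
  than the auditory cue, and at maximum blur the two are matched — the
  qualitative pattern reported for unimodal slopes in this task. The
  implied generating visual weights (0.86, 0.74, 0.61, 0.50) span the
  informative range without saturating.
* `lapse = 0.04`: a few percent of stimulus-independent errors, typical
  of naïve participants.
* `criterion = 5.5`, the continuum midpoint, mirroring the approximately
  matched PSEs of the two continua; configurable.
* `delta_a = delta_v = 9` steps (endpoints as category prototypes). The
  weight predictions depend on the separations only through their ratio,
  and conclusions do not hinge on the separations being equal because the
  step scale within each modality is arbitrary.
* For `categorical_optimal` observers used in validation, environmental
  variances follow the proportional recipe: auditory environmental
  variance 18% above auditory sensory variance
  ($\sigma^2_{A,\mathrm{env}} = 1.18 \times 4 = 4.72$) and visual
  environmental variance 42% of the auditory environmental variance
  ($1.9824$).
* `bimodal_v_sd_scale` multiplies the visual noise on bimodal trials
  only (default 1); setting it to 3 plants the unimodal/bimodal variance
  inconsistency that the outlier QC is designed to detect (a ninefold
  variance ratio against the fourfold threshold).

What the simulator deliberately does **not** emulate: sequential effects,
learning or adaptation across trials, response times, criterion drift or
criterion noise, asymmetric guessing, truncation of internal estimates at
the continuum ends, and the robust-integration nonlinearities expected for
large, noticeable cue conflicts (the design keeps conflicts within ±3
steps precisely to stay in the linear-integration regime). Passing
recovery tests therefore certify the analysis chain on data obeying the
stated generative model — they do not certify those modeled-away aspects
of real behavior.

# The pipeline

`run_cue_analysis()` executes the full sequence per participant: unimodal
fits → sensory-only predicted weights → bimodal surface fits (with
bootstrap CIs) → variance-identity inversion → variance-ratio QC →
corrected predictions excluding flagged participants → optional
environmental fit. `compare_weights()` summarizes cohort agreement as
per-blur mean differences with participant-resampling bootstrap CIs plus
a monotonicity check — an intentionally assumption-light replacement for
repeated-measures ANOVA on data we simulate ourselves. Every random draw
descends from the master seed via per-participant and per-stage
substreams, so reports are bit-reproducible and participants'
fits are independent of who else is in the cohort.

The environmental fit defaults to the *pooled* scope (one fit to the
cohort-mean weights, using the corrected, bimodal-inferred visual
variances); a per-participant scope and the uncorrected variance source
are available as options. Pooling is the default because two free
parameters against four per-participant weights is fragile at realistic
noise levels, while cohort means are considerably more stable.

# Validation problem sizes

The test suite and the acceptance script validate the chain at these
scales, chosen to make the checks statistically decisive while remaining
desk-scale: generate-and-refit recovery over 200 simulated participants
(10-step continuum, 260 repetitions — tenfold the protocol — for the
within-5% bias checks, with the 26-repetition bias additionally checked
to shrink at the larger size); bootstrap coverage of the visual-weight
CI over 500 replicate datasets at 26 repetitions (nominal 95%, accepted
at 90–98%); cohort-level recovery with 6 reliability-weighting observers
on the full 4628-trial design; flattening and environmental-recovery
checks with 4 categorical observers; and QC operating characteristics on
8 observers with 2 planted inconsistents.

# Known limitations

* The Fisher-discriminant weight rule assumes equal diagonal category
  covariances and uncorrelated cue noise; correlated noise or unequal
  covariances would change the optimal rule. The rule is isolated in
  `predict_weights_categorical()` so an alternative can be swapped in.
* The environmental fit is a two-parameter least-squares fit to at most
  four weight values; it cannot, by construction, accommodate weights
  that change *faster* with blur than the sensory-only prediction, and
  its estimates should be read as descriptive rather than sharply
  identified.
* The lapse model is symmetric and shared within a fit; strongly
  asymmetric guessing or condition-dependent lapses would bias slope
  estimates.
* Weight identification relies on small cue conflicts; the package does
  not model the causal-inference regime where conflicts become large
  enough to be noticed and integration breaks down.
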