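---
title: "Distributed value coding in a small feedforward chooser: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed value coding in a small feedforward chooser}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choicenet)
```

## The scientific question

Models of economic choice are often modular: one circuit evaluates offers,
another compares them, a third binds the winner to an action. `choicenet`
implements the opposite intuition — a fully distributed chooser — as a small
feedforward network trained on a two-gamble task, together with the
population-statistics toolbox (tuning regressions, coefficient
correlations, choice probability correlations, fixed-value probes, lesions)
that electrophysiologists use on real neurons. The point of the package is
not the network itself but the *analysis pipeline*: every statistic is
computed exactly as it would be on recorded spike counts, so the simulated
population can be compared like-for-like with published neural results.

## The task generator

Each trial presents two gambles, right and left. Rewards sit on an 11-level
grid {0, 0.2, …, 2.0} (arbitrary units) and win probabilities on
{0, 0.1, …, 1.0}; all four quantities are drawn independently and uniformly,
so expected values EV = r·p range over the 121 grid products in [0, 2].
Outcomes are Bernoulli: the chosen gamble pays its reward with its
probability, else zero.

Grid values are represented by integer indices (reward = idx/5,
probability = idx/10), so grid membership and EV ties are decided by exact
integer arithmetic, never by floating-point comparison. The two gambles may
coincide on a trial (independent sampling allows it); EV-tie trials stay in
the logs and in all tuning analyses but are excluded from accuracy
denominators, where "choose the better offer" is undefined.

This generator *is* the study's synthetic data. It emulates the stated
discrete uniform design and the Bernoulli outcome model; it does not emulate
anything a real experiment would add — session structure, reward satiety,
stimulus confusability, temporal discounting — so passing tests demonstrate
properties of the model under its idealised task, not claims about
behaviour on real data.

## Network and learning rule

The default architecture is 4–20–20–20–2 with activation `tanh(3x)` and no
biases. Output unit 1 codes the right gamble, unit 2 the left; the larger
output wins and exact floating-point ties are broken by a fair coin. Ties
are detected by exact equality deliberately: an epsilon band would randomise
near-ties and artificially flatten the psychometric curve around
indifference.

Learning is trial-by-trial gradient descent on the squared prediction error
of the *chosen* output unit only (e = R − y_chosen). The unchosen unit's
delta is exactly zero, so its incoming weights are bitwise unchanged on that
trial; hidden layers receive error only through the chosen unit's paths.
This gating is the study's central learning-rule assumption: credit flows
only through the pathway whose prediction was tested by the outcome. The
implementation is verified against central finite differences of the gated
loss (to 1e−5 on randomised small architectures) in the test suite.

Two printed formulas in the source description are ambiguous, and both are
exposed as switches:

* **Activation derivative.** The analytic derivative of `tanh(3x)` is
  `3(1 − tanh²(3x))`; the source prints a form without the leading factor.
  Since a constant factor is absorbable into the learning rate, the package
  defaults to the analytic derivative (`derivative = "analytic"`, verified
  by finite differences) and offers `"printed"` (`1 − tanh²(3x)`) for
  sensitivity analysis.
* **Weight normalisation.** The rule "divide each layer by its maximum
  weight after every update, to keep the weights between bounds" admits two
  readings. Read literally (`normalization = "absmax"`), every layer is
  rescaled to maximum absolute weight 1 on every trial — including trial 1,
  which inflates the ±0.01 initial weights a hundredfold, saturates the
  steep tanh units, and stalls learning near chance (~56% accuracy in our
  runs). Read as a bound (`normalization = "max_bound"`, the default), a
  layer is divided by its maximum absolute weight only when that maximum
  exceeds 1: weights stay in [−1, 1], the stated purpose ("keep the weights
  between bounds") is met, the slope-3 rationale ("good initial scaling" of
  the small initial weights) stays coherent, and training reaches the
  reported ~80–85% accuracy. The bounded reading also makes normalisation
  nearly equivalent to disabling it (`"none"`), matching the remark that
  results hold without normalisation. `"signed_max"` implements the literal
  signed-maximum division for completeness.

Defaults follow the stated study conditions throughout: η = 0.01, 3,000
trials, initial weights U[−0.01, 0.01], analysis on the final 1,000 trials
(learning stays on — no freeze is stated), ensembles of 300 networks with
seeds `base_seed + k`. Networks below the 80% performance criterion are
flagged (`glance()`) but not excluded; exclusion would be a post-hoc filter
the package leaves to the user.

## Population analyses

**Tuning.** A unit is tuned to a variable when the single-regressor OLS
slope of its final-window activity on that variable has two-sided p < 0.05
(uncorrected, as in the source analyses; `stats::p.adjust` can be applied
to the returned records by users who want FDR control). Variables: each
offer's reward and probability, each offer's EV, the chosen EV, the binary
choice (left = 1), and offer side. Degenerate fits (constant predictor or
activity) return β = 0, p = 1, flagged. The closed-form vectorised OLS is
cross-checked against `lm()` in the tests, and its null rejection rate is
calibrated (5% ± 1.5%) on noise.

**Side (position) coding.** For every reward × probability cell observed on
both sides, the unit's mean activity with that offer on the left
(position 1) and on the right (position 2) is computed, and the cell means
are regressed on the position code. A structural caveat the implementation
makes explicit: because the two sides have identical offer marginals, the
slope of this regression converges to zero for *any* unit whose response is
a fixed function of the two offers — the grand means across cells coincide.
Side coding in this strict matched-offer sense is therefore essentially a
finite-sample quantity, and the fraction of "position-tuned" units stays
near the false-positive rate. This is one of the published headline
fractions the pipeline does not reproduce, and we believe the original
statistic must have been computed differently (the printed description is
not specific enough to tell how).

**Coefficient correlations.** Per layer, the per-unit β vectors for two
variables are Pearson-correlated across units pooled over the ensemble
(signed, or on |β| for coding *strength*). Zero-variance vectors are
flagged rather than propagating NaN.

**Choice probability correlations.** Unit activity is residualised on the
four task inputs by multiple regression; the residuals are correlated with
the binary choice. Residual variance at rounding-noise level (an exactly
linear unit) is flagged degenerate instead of yielding spurious
correlations.

**Common-currency probe.** All grid combinations with r·p equal to the
probe EV (0.16 → exactly {(0.2, 0.8), (0.4, 0.4), (0.8, 0.2), (1.6, 0.1)})
are presented on one side against the same fixed, seeded sample of 50
opposing offers (paired across combinations), and each unit's responses are
compared across combinations by one-way ANOVA (Kruskal–Wallis available via
`layer_trend_test` for the rank-based variant). A unit with a true common
currency responds identically across equal-EV combinations and is not
rejected; the degenerate all-equal case returns p = 1 explicitly.

**Psychometrics and lesions.** Choices are binned by ΔEV = EV_L − EV_R
(bin width 0.25 over [−2, 2]; bins with fewer than 5 trials dropped — a
compromise between resolution and per-bin counts at 1,000 trials) and fit
by least squares to P = ½(1 + tanh(k(ΔEV − b))), initialised from the
linearised (atanh) regression with the linearised estimate as fallback for
step-like data; the crossing slope is k/2. Lesions zero the
*post-activation* activity of a random fraction of units in a layer
(weights untouched, so silenced units also transmit nothing downstream),
with masks fixed per network and nested across fractions; evaluation runs
1,000 fresh trials with learning fully disabled.

## What the pipeline reproduces, and what it does not

With the default (bounded-normalisation, analytic-derivative) conditions
the pipeline reproduces the behavioural headline: ensemble accuracy settles
near 81–82% (reference 85 ± 5), errors concentrate at small |ΔEV|, the
psychometric curve is a clean sigmoid through 50% at indifference, tuning
for rewards, probabilities and choice is ubiquitous (>99% of units), offer
values are coded in anti-correlated fashion in every layer with the
anti-correlation strongest in layer III, equal-EV offers evoke reliably
distinct responses (no common currency) in essentially all layer-III units,
and choice probability correlations rise monotonically across layers.

It does not reproduce the *graded magnitudes* of the published
coefficient correlations (e.g. value anti-correlation −0.58/−0.90/−0.93
across layers, within-offer integration ≈ 0.53, coding-strength
correlations 0.08–0.35). By trial 3,000 every hidden unit's linear tuning
has aligned onto a common value-difference axis, so pooled β correlations
saturate near ±1, matched-offer side coding vanishes, and — because the
surviving units carry a redundant sign code — lesions of up to 75% of a
layer barely move accuracy, flattening the published ordered lesion
deficits. We explored the plausible readings of the ambiguous printed rules
(literal per-trial normalisation, the printed derivative forms, an
early-stopping interpretation of the 80% criterion): each recovers *some*
of the graded structure, but none jointly attains the reported accuracy and
the graded correlations, so the package keeps the defaults that reproduce
the behavioural result and reports the population statistics as computed.
The divergent statistics are left visibly failing in the acceptance checks
rather than being tuned toward the reference values; `report()` prints the
side-by-side comparison with its tolerance bands.

## Problem sizes and reproducibility

The test suite exercises the full study conditions at a reduced ensemble
size — 50 networks for the ensemble-level checks (lesion and probe
sub-analyses on 20) — which we chose as the smallest ensembles at which the
pooled statistics are stable to well under the tolerance bands;
`scripts/acceptance.R` runs the full 300-network protocol. All randomness
(weights, trials, tie-breaks, outcomes, lesion masks, probe samples) flows
through R's RNG in a documented order, so every result in the package is a
deterministic function of a single seed; the compiled training loop
consumes only pre-drawn uniforms and is itself bitwise deterministic, and
its trajectory is checked against an independent pure-R reimplementation in
the tests.

## Known limitations

* Side/position coding as specified is structurally null (above); the
  corresponding published fractions and correlations are not recovered.
* The output nonlinearity bounds y_chosen in (−1, 1) while outcomes reach
  2.0, so the squared prediction error cannot vanish for large rewards; the
  network regresses toward a saturated estimate of the chosen value. This
  is faithful to the printed cost but worth keeping in mind when
  interpreting the per-trial errors.
* A single task, no biases, no recurrence, no noise in unit responses:
  trial-to-trial "variability" of a unit is entirely nonlinear task
  dependence, which makes choice probability correlations interpretable but
  not directly comparable to noisy spiking data.
* Fully converged networks become functionally homogeneous, which sharpens
  the distributed-coding message (everything everywhere) but erases the
  layer gradients a partially trained system shows.
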