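# choicenet

Distributed economic choice in a small feedforward network.

`choicenet` simulates binary risky choice — two gambles, each defined by a
reward magnitude *r* on the grid {0, 0.2, …, 2.0} and a win probability *p*
on {0, 0.1, …, 1.0} — with a layered tanh network (4 inputs, three hidden
layers of 20 units, 2 outputs) trained trial-by-trial by a chosen-unit-gated
variant of backpropagation. It then provides the population-level analyses
used to argue that value coding in such a system is *distributed*: every
unit carries graded information about both offers' values, their attributes,
and the forming choice, with no common-currency units, no labelled lines for
the two offers, and graceful degradation under simulated lesions.

The package is aimed at computational neuroscientists who want a tested,
reproducible implementation of this style of network-plus-electrophysiology
analysis: per-unit single-regressor tuning, correlations of tuning
coefficients across a population, choice probability correlations,
fixed-expected-value probes, psychometric (tanh) curve fits, and lesion
sweeps.

## Model

Inputs are the two offers in right-first order, **I** = (r_R, p_R, r_L, p_L).
Activities propagate as

    y_i^n = tanh(3 · Σ_j w_ij^n y_j^(n-1)),     y^0 = I,

with zero biases. Output unit 1 codes the right gamble, unit 2 the left;
the larger activity wins (exact ties are a fair coin). The chosen gamble's
Bernoulli outcome R_t is revealed, and only the chosen output unit receives
the prediction error e_t = R_t − y_chosen:

    δ_chosen^N = e_t · f'(net),   δ_unchosen^N = 0,
    δ_j^n = (Σ_i δ_i^(n+1) w_ij^(n+1)) · f'(net_j^n),
    Δw_ij^n = η δ_i^n y_j^(n-1),          η = 0.01,

followed by a per-layer renormalisation that keeps weights inside [−1, 1]
(see the methods vignette for the normalisation variants and why the
default divides by the layer's maximum absolute weight only when it
exceeds 1). Training runs 3,000 trials; analyses use the activities of the
final 1,000 trials, and ensembles of independently initialised networks
(study scale: 300) are averaged.

## Worked example

```r
library(choicenet)

fit <- train_network(seed = 1)
fit
#> <choicenet_fit> 4-20-20-20-2 network, 3000 trials (eta = 0.01)
#>   final-window accuracy (ties excluded): 0.792

psychometric_curve(fit)
#> <choicenet_psychfit> k = 1.477, b = 0.081, crossing slope = 0.738

ens <- run_ensemble(10, base_seed = 1)
glance(ens)
#>   mean_accuracy sd_accuracy trial_variance n_networks frac_met_criterion
#>       0.812        0.0334          0.153          10                0.7

tun <- compute_tuning(ens)
beta_correlation(tun, "EV_L", "EV_R")
#>   layer var_x var_y   mode    rho         p n_units
#>       1  EV_L  EV_R signed -0.994  1.4e-192     200
#>       2  EV_L  EV_R signed -0.994  3.9e-190     200
#>       3  EV_L  EV_R signed -0.994  3.7e-189     200
```

Reading the output: the network chooses the higher-expected-value gamble on
~79–81% of non-tie trials (errors concentrate where the two offers are close
in value — the psychometric gain `k` sets how sharply choice flips around
ΔEV = 0, and the crossing slope `k/2` is its steepness at indifference). The
strong negative correlation between the per-unit regression slopes for the
left- and right-offer expected values shows that units encode the two
offers' values in an anti-correlated, comparison-like format in every
hidden layer.

`run_study()` runs the full pipeline (tuning fractions, all correlation
pairs, choice probability correlations, the EV = 0.16 common-currency probe,
and the lesion sweep) and writes tidy CSVs plus a JSON summary;
`report()` compares the headline statistics against their published
reference values. `autoplot()` / `plot_*()` functions draw the psychometric
curve, tuning fractions, layer-wise correlations, and lesion curves.

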