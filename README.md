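# patchcross

Bayesian model selection for collective patch-crossing decisions in small
fish shoals.

Site-attached reef fish such as humbug damselfish (*Dascyllus aruanus*)
repeatedly cross back and forth between nearby habitat patches, and the
timing and direction of each crossing is shaped by social cues. Two families
of cue are hard to tell apart because they are strongly correlated over
time: **static** cues (how many conspecifics currently sit on each side) and
**dynamic** cues (who has just crossed, and in which direction). `patchcross`
implements the full analysis pipeline needed to separate them from event
logs of crossing experiments:

* competing social-response models expressed as per-fish crossing
  propensities,
* sequential binary-choice likelihoods and log₂ marginal likelihoods
  (Bayesian evidence) for ranking the models,
* an event-driven stochastic simulator for checking that a selected model
  also reproduces the large-scale patterns,
* descriptive statistics (occupancy distributions, crossing groups and
  pools, direction-vs-interval analysis, exact sign tests), and
* leadership and dominance-hierarchy statistics (initiation scores,
  circular triads, Kendall's linearity *K* with a Monte Carlo null,
  Fisher's omnibus combination).

A synthetic-data module generates complete experiments with known ground
truth, so the entire pipeline is testable without any field data.

## The models

Each crossing event is reduced to a *decision point*: the side occupancies
(n_L, n_R) immediately before the event, the direction of the most recent
crossing, and the tally of recent crossings within a memory window τ
(default 3.5 s). A model M assigns every fish a non-negative propensity
weight w; the side-level rate is Λ_side = n_side · w_side, and the
probability that the next crossing originates from the left is

    P(L) = Λ_L / (Λ_L + Λ_R).

With Δ = n_opposite − (n_same − 1) (the focal fish does not count itself),
the supported models are:

| model | class    | weight                                      | parameter |
|-------|----------|---------------------------------------------|-----------|
| M0    | null     | 1                                           | —         |
| S1    | static   | γ^sign(Δ) (binary attraction to the larger group) | γ   |
| S2    | static   | max(ε, 1 + βΔ) (linear response)            | β         |
| S3    | static   | g^Δ (geometric response)                    | g         |
| S4    | static   | 1 / (1 + a·s^−Δ) (Bayesian-decision logistic) | a, s    |
| D1    | dynamic  | α on the last mover's origin side, 1 elsewhere | α      |
| D2    | dynamic  | α^m, m = net recent crossings a move would continue | α  |
| C1    | combined | w_S1 · w_D1                                 | γ, α      |

The likelihood of a dataset multiplies P(outcome side) over all
*informative* decision points (both sides occupied; a move from a
configuration with an empty opposite side is forced and carries no
evidence). Model evidence integrates this likelihood over scale-free
parameter priors (log-uniform on multiplicative factors over [2⁻⁶, 2⁶],
uniform on β) by deterministic grid quadrature, with Monte Carlo prior
sampling as an independent cross-check. The simulator realises the same
weights as competing exponential hazards (per-fish rate λ₀·w, default
λ₀ = 0.08 s⁻¹), so the simulation and the likelihood share one definition
of every model.

## Worked example

Generate a synthetic experiment from the follow-the-last-mover model
(α = 4), then run model selection and the descriptive analyses:

```r
library(patchcross)

gen <- generate_dataset(synth_config(model = "D1", params = c(alpha = 4),
                                     trials_per_group = c("4" = 6, "5" = 6),
                                     duration_s = 300, seed = 42))
ds <- gen$dataset

compare_models(ds, settings = integration_settings(grid_points_per_dim = 257))
#> Model comparison (log2 marginal likelihoods)
#>  model   class n_params log2_evidence                 map rank
#>     D1 dynamic        1     -1491.681        alpha=4.1771    1
#>     D2 dynamic        1     -1851.052       alpha=1.25538    2
#>     S4  static        2     -1955.058 a=2.40431;s=1.25346    3
#>     S3  static        1     -1956.361            g=1.1764    4
#>     S2  static        1     -1956.366        beta=0.15625    5
#>     S1  static        1     -1956.557       gamma=1.42961    6
#>     M0    null        0     -2046.121                        7
#> Best model: D1
```

The generating model wins by ≈ 360 log₂ units over the next model, and its
posterior concentrates on the true follow strength:

```r
posterior_summary("D1", ds)
#>   param     mean     mode  ci95_lo  ci95_hi mean_log2
#> 1 alpha 4.216359 4.177095 3.789152 4.756828  2.073816
```

(`mean_log2` ≈ 2.07 against the true log₂ 4 = 2.) The direction-vs-interval
table shows the dynamic-cue signature: successive crossings within the 3.5 s
salience window are mostly same-direction, later ones are not:

```r
direction_interval_analysis(ds)$by_interval
#>         bin n_pairs    p_same
#> 1   [0,3.5]    2099 0.6574559
#> 2 (3.5,Inf]     258 0.3759690
```

Exact descriptive tests use closed forms, e.g. the one-sided binomial sign
test for coral association with 11 of 14 trials favouring the coral:

```r
coral_association_test(14, 11)
#> [1] 0.02868652
```

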