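# dispcomm

Experimental evolution of **displaced communication** between pairs of
neural-network agents.

A *sender* and a *receiver* forage on a one-dimensional circular world with
five foraging sites, one of which contains food, and a nest at position 0
where — and only where — the receiver can perceive the sender's signal.
Because the food is never visible from the nest, any information the signal
carries about food location is *displaced*: it refers to somewhere other
than where the communication happens (the property that makes the honeybee
waggle dance famous). Both agents are continuous-time recurrent neural
networks (CTRNNs) whose weights, biases and time constants evolve under a
genetic algorithm in which the pair's joint foraging performance is the
fitness. The package implements:

- the world, trial and pair-evaluation machinery (compiled core, with a
  pure-R reference simulator cross-checked to 1e-12),
- the generational loop (tournament selection, per-gene Gaussian mutation,
  random re-pairing, named RNG streams, checkpoint/resume),
- three evolutionary treatments: `communication`, `no_communication`
  (perceived signal clamped to 0; its performance ceiling is 0.2) and
  `constrained_sender` (fixed sender velocity, removing timing cues),
- counterfactual **probes** of evolved pairs (fixed amplitude,
  mean-amplitude replay, onset shift, duration lock) that diagnose which
  communication channel a population actually uses,
- the analysis layer: food-found classification, success histograms, the
  between-trial signal-variation statistic, onset-delay extraction,
  evolutionary milestones with a repeated-testing guard, and nonparametric
  treatment comparisons,
- experiment orchestration with manifests, plus `tidy()`/`glance()`/
  `autoplot()` methods.

See `vignette("dispcomm-methods")` for the model definition, numerical
choices, and an honest account of which of the original study's results
reproduce at desk scale and which do not.

## Worked example

```r
library(dispcomm)

# a hand-built pair: silent stationary sender, receiver that cruises so it
# sits on site 1 during every scored step of trial 1
sender <- make_fixture_genome("sender", "stationary")
receiver <- make_fixture_genome("receiver", "constant_speed",
                                speed = (3 * pi / 8 / 80 + 5 * pi / 8 / 99) / 2,
                                direction = 1)
pair <- evaluate_pair(sender, receiver, food_order = 1:5)
pair
#> <pair_performance> total = 0.2 
#> # A tibble: 5 × 4
#>   trial food_site p_trial onset
#>   <int>     <int>   <dbl> <int>
#> 1     1         1     0.2     1
#> 2     2         2     0       1
#> 3     3         3     0       1
#> 4     4         4     0       1
#> 5     5         5     0       1
```

Without communication a receiver can fully exploit at most one of the five
trials, so 0.2 is the no-communication performance ceiling. Evolving a
population under the full-communication treatment beats it quickly:

```r
# evolve a desk-scale population with full communication (~20 s)
history <- run_evolution(
  evolution_config(generations = 500, n_pairs = 100,
                   treatment = "communication"),
  seed = 1)
history
#> <evolution_history> communication: 100 pairs, 500 generations (seed 1)
#> final mean performance 0.310 (max 0.410)

first_exceeds_threshold_generation(history)
#> [1] 6
```

The milestone above is the first generation at which a one-sided Wilcoxon
test against 0.2 rejects *and keeps rejecting for 20 consecutive
generations* — the persistence guard against repeated-testing false
positives (see the vignette). `autoplot(history)` draws the trajectory.

Probes tell you what the evolved population communicates *with*. Fixing the
signal amplitude at each pair's own mean removes only the amplitude channel:

```r
probe <- probe_population(history$population, "fixed_amplitude", seed = 1)
probe_significance(probe)
#> # A tibble: 1 × 6
#>       n median_control median_probe statistic p_value decreased
#>   <int>          <dbl>        <dbl>     <dbl>   <dbl> <lgl>    
#> 1   100           0.38        0.365     4198.  0.0485 FALSE
```

Here the decrease is not significant at the 0.01 level, so this population
does not rely primarily on amplitude — try `"duration_lock"` on the same
population, and `"fixed_amplitude"` on a `constrained_sender` population,
where it collapses performance.

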