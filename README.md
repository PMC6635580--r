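# attnrl

Attention-controlled reinforcement learning for multi-attribute,
multi-option choice.

`attnrl` is for computational-neuroscience and behavioural researchers who
model trial-by-trial choice among options that differ on several attributes
at once — a foraging subject picking among four foods that differ in
calories, colour and location, a consumer weighing price against brand. It
provides (1) a choice model in which the *geometry of the choice set* gates
attention over attributes and *memory-dependent value decay* produces
persistent (run-like) choices, (2) the bespoke sequence statistics used to
quantify preference bias and choice persistence, (3) maximum-likelihood
fitting and model comparison, and (4) a synthetic task library reproducing a
three-condition, four-option primate foraging experiment for simulation and
recovery studies.

## The model

Normalized attribute values `x_{k,i}` (divide-by-max per attribute) define a
**preference vector** with components `max_i x_{k,i} − min_i x_{k,i}`. With
unit components `u_k`, the angle between the vector and attribute axis `k`
is `θ_k = arccos(u_k)`. A threshold gate sets attention weights:

- **selective**: if `min_k θ_k < Θ_threshold` (default 30°), the most
  distinctive attribute gets weight 1, the rest 0;
- **divided**: otherwise `w_k = u_k`.

Learning, per trial and per attribute, with subjective reward
`r = N·x^γ`:

```
Q_c ← Q_c + α_c (r_c − Q_c)            chosen option
Q_u ← Q_u + α_u (0  − Q_u)             each unchosen option
α_u = α_c · Q_u^(μ−1)                  memory-dependent decay rate
```

Choices follow a softmax over `Q_i = Σ_k w_k Q_{k,i}` with inverse
temperature `β`. Free parameters: `α_c, μ, β, γ`. Sequence statistics:
**B-index** `1 − S_emp/ln(n)` (0 = uniform exploration, 1 = exploitation)
and **P-index**, the ratio of mean log-log area statistics between the
empirical run distribution and shuffled references versus the sorted
reference and the same shuffles (0 = history-independent,
1 = fully perseverative).

## Worked example

Simulate a synthetic subject on the food condition (four items of 2.06,
0.78, 0.15, 0.08 kcal/piece at counterbalanced locations), measure its
sequence statistics, and refit the model:

```r
library(attnrl)

spec <- builtin_condition(1)
condition_weights(spec)
#> <attention_weights> mode: selective
#>   attribute weight
#> 1 calorie        1
#> 2 proximity      0

log <- simulate_choices(spec, default_params(1), seed = 42)
dplyr::count(log, item_label, sort = TRUE)
#>   item_label     n
#> 1 PN          1211
#> 2 FG           225
#> 3 PL            42
#> 4 KR            22

bp_indices(choice_labels(log), sessions = log$session, n_options = 4,
           n_shuffles = 1000, seed = 42)
#>   b_index p_index n_shuffles  seed
#> 1   0.553   0.690       1000    42

fit <- fit_choice_model(log, spec, seed = 1)
tidy(fit)
#>   term    estimate
#> 1 alpha_c    0.839
#> 2 mu         2.83
#> 3 beta      21.0
#> 4 gamma      0.110

compare_models(log, spec, seed = 1, n_restarts = 6)
#> <model_comparison> favored by BIC: Qcu
#>   variant k_params   nll   aic   bic pseudo_r2
#> 1 Qcu            4  593. 1193. 1215.     0.715
#> 2 Qc             3  929. 1865. 1881.     0.553
```

The attention gate is selective on calories, so the simulated subject
concentrates on the highest-calorie item (PN) while its location choices
track the counterbalancing; the bias index of 0.55 and persistence index of
0.69 quantify exploitation and run structure. The refit recovers the
generating parameters (0.79, 2.82, 20.50, 0.09) within sampling error, and
BIC prefers the chosen+unchosen variant that generated the data over the
chosen-only variant.

A thin command-line front end wraps the same functions:

```sh
exec/attnrl simulate --condition 1 --seed 5 --out log.csv
exec/attnrl metrics  --log log.csv --out metrics.json
exec/attnrl fit      --log log.csv --out fit.json
exec/attnrl reproduce --seed 1 --out report.json
```

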