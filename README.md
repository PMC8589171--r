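# dpnn — differential prototype networks for treatment selection

`dpnn` implements a deep-learning approach to individualized treatment
selection for settings where patients fall into subgroups that differ in
*which* treatment works for them, but those subgroups are only visible
in a latent representation of the features — the situation believed to
hold in major depressive disorder, where observable symptom subtypes
predict antidepressant response poorly. The package is aimed at
methodologists working on treatment-selection policies who need a
reproducible benchmark: it ships the model, the counterfactual cohort
simulator it is evaluated on, the operational baselines, and the
ranking-oriented evaluation metrics.

## The model

A differential prototype network (DPNN) couples three trainable parts:
a symmetric autoencoder `e`/`d`, a layer of `ℓ` trainable latent
prototypes `p_1..p_ℓ`, and a classifier `h` that maps a patient's
squared-distance vector to the prototypes, concatenated with a one-hot
treatment, to a remission probability. All parts train jointly under

```
L = L1 + λ1·L2 + λ2·L3
```

where `L1` is binary cross-entropy on the observed outcome, `L2` the
autoencoder reconstruction distance, and `L3` the negated prototype
variance: the classifier is evaluated for every prototype × treatment
pair, giving an `ℓ × k` matrix `Y_P`, and `L3 = −(α·intra(Y_P) +
(1−α)·inter(Y_P))` rewards prototypes that disagree about which
treatment works (intra, within a prototype across treatments) and that
differ from each other under each treatment (inter). Minimizing `L`
therefore shapes the clustering by the treatment-response signal
instead of leaving it to an unsupervised step. Policies are derived by
`argmax` over the per-arm predicted probabilities.

The training core (hand-derived backpropagation through all three loss
parts, including the prototype paths, with Adam updates) is compiled
C++ via RcppArmadillo; gradients are verified against central finite
differences in the test suite.

## A worked example

```r
library(dpnn)

# a benchmark cohort with known counterfactuals: 5 latent subgroups in
# 10 dimensions, 2,000 patients each, 4 treatment arms, decoded to 20
# observed features
cohort <- generate_cohort(synthetic_config(seed = 1))
cohort
#> synthetic cohort: 10000 patients, 20 features, 4 treatment arms
#> observed remission rate: 0.308

config <- experiment_config(cohort,
                            methods = c("dpnn", "kmnn", "cbr", "random"),
                            n_repetitions = 5, master_seed = 1)
samples <- run_experiment(config)
subset(aggregate_metrics(samples), metric %in% c("mrr", "rpl"))
#>    method metric median       mad n
#> 1    dpnn    mrr 0.4565 0.0032000 5
#> 2    dpnn    rpl 0.1025 0.0108084 5
#> 10   kmnn    mrr 0.4277 0.0039917 5
#> 11   kmnn    rpl 0.2262 0.0204809 5
#> 19    cbr    mrr 0.4554 0.0001383 5
#> 20    cbr    rpl 0.1069 0.0002213 5
#> 28 random    mrr 0.3566 0.0003217 5
#> 29 random    rpl 0.5084 0.0011251 5
```

Read this as: over five repetitions of 5-fold cross-validation, the
DPNN's recommended treatment forfeits a median of ~0.10 in true
remission probability relative to an oracle that knows the
counterfactuals (`rpl`, lower is better), against ~0.51 for random
allocation. `mrr` is the mean reciprocal rank of the recommendation in
the true ordering of the arms, on the shifted scale used for this
benchmark (`1/(rank+1)`, ties sharing the best position): random
allocation scores ~0.36, a perfect oracle 0.50. The KMNN baseline
trails the jointly trained methods on this cohort draw: the random
remission functions here leave substantial within-subgroup
disagreement about the best arm, which caps any cluster-then-classify
policy. Statistical comparison of methods (Friedman, then pairwise
Wilcoxon signed-rank with Bonferroni correction) is available via
`compare_methods(samples, "rpl")`; note that five repetitions are too
few for the paired tests to reach `p <= 0.01` — the reference protocol
uses 100.

The same machinery is exposed on the command line:

```sh
Rscript inst/cli/dpnn.R simulate --seed 1 --out cohort/
Rscript inst/cli/dpnn.R train --cohort cohort/ --out model.json
Rscript inst/cli/dpnn.R predict --model model.json --cohort cohort/ --out pred.csv
Rscript inst/cli/dpnn.R experiment1 --seed 1 --reps 5 --out results/
Rscript inst/cli/dpnn.R sweep --seed 1 --out sweep/
```

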