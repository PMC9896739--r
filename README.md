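# dxrank — listwise learning-to-rank for differential diagnosis support

`dxrank` is the core of a clinical decision support system: a physician (or
a script) inputs a patient's observed symptoms, and the system returns a
ranked, scored list of candidate diseases. It is aimed at researchers in
clinical informatics who want a complete, reproducible reference
implementation of the listwise approach to diagnosis ranking — training,
metrics, baseline, evaluation protocol and synthetic data in one package.

## The method

Each diagnostic case is treated as a learning-to-rank query. The observed
symptoms form a multi-hot vector `x` over the symptom vocabulary; a
one-hidden-layer network scores every disease at once:

    s = W2 · relu(W1 x + b1) + b2

Supervision is graded per case: the confirmed disease carries the top
relevance score, differential diseases carry smaller positive scores, all
other diseases are graded 0. Ranking quality is measured by normalized
discounted cumulative gain,

    nDCG@k = DCG@k / IDCG@k,   DCG@k = Σ_{i≤k} g(rel_i) / log2(i + 1)

and the training loss is the differentiable Approximate-NDCG surrogate: the
rank of each item is replaced by a sum of logistic comparisons

    π̂_i = 1 + Σ_{j≠i} σ(α (s_j − s_i)),

and the loss is −ApproxNDCG with the exact ideal DCG as normalizer.
Gradients are analytic and finite-difference verified. A pointwise baseline
(same network, same training, mean-squared-error loss) is built in, and
`compare_systems()` runs the two under 5-fold cross-validation with
byte-identical folds and training configuration — only the loss differs.

Because real graded case corpora are private clinical data, the package
includes a seeded synthetic-corpus generator (`generator_config()`,
`generate_corpus()`) that emulates their structure: latent
characteristic-symptom profiles per disease, long-tailed prevalence, noisy
partial symptom observation, and overlap-ranked differentials with
geometrically decaying scores.

## Worked example

```r
library(dxrank)

# a synthetic graded case corpus: 200 diseases, 400 symptoms, 2000 cases
corpus <- generate_corpus(generator_config(seed = 7))

# train the listwise system
fit <- train(corpus, loss_config("approx_ndcg"), train_config(seed = 1))
fit
#> <dx_fit: approx_ndcg loss, 20 epochs>
#>  epoch      split      ndcg      mse
#>     20      train 0.9827041 18.51226
#>     20 validation 0.9229626 17.93238

# rank diseases for a patient's symptoms: rank / score / disease rows
case <- corpus$cases[[1]]
predict(fit$model, case$symptoms, top_n = 5)
#> Inputted symptoms: S149, S200, S262, S300, S221, S316, S225, S141, S246
#>  rank code     disease score
#>     1 D036  Disease 36  6.65
#>     2 D189 Disease 189  2.72
#>     3 D107 Disease 107  2.13
#>     4 D179 Disease 179  1.67
#>     5 D100 Disease 100  0.87

# progressive input: at which point does the confirmed disease enter the
# top 10?
traj <- rank_trajectory(fit$model, case$symptoms,
                        targets = confirmed_diseases(case), cutoff = 10)
head(as.data.frame(traj), 3)
#>   step symptom rank_D036   hit
#> 1    1    S149        12 FALSE
#> 2    2    S200         1  TRUE
#> 3    3    S262         1  TRUE
attr(traj, "first_hit")
#> [1] 2

# compare the listwise system against the pointwise MSE baseline,
# 5-fold cross-validation, identical conditions except the loss
report <- compare_systems(corpus, eval_config())
report
#> Value of evaluation functions (mean over folds)
#>          ndcg ndcg@5 ndcg@10 ndcg@20     mse
#> A-NDCG 0.9237 0.8641  0.8792  0.8996 13.9299
#> MSE    0.8773 0.7963  0.8239  0.8510  1.2220
```

The ndcg rows are the headline comparison: the listwise system (A-NDCG)
ranks held-out cases' graded diseases uniformly better than the pointwise
baseline at every cutoff. The large mse of the listwise row is expected —
a ranking loss has no reason to reproduce label magnitudes, which is
exactly why mse is a poor evaluation function for ranking.

A thin command-line front end over the same functions is installed at
`inst/cli/dxrank.R` (subcommands `generate`, `train`, `evaluate`,
`predict`, `trajectory`).

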