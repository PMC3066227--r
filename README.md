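# selectmeta

Weight-function selection models for quantifying selective reporting bias
across many related meta-analytic datasets — for example, the hundreds of
case-control genetic-association results that accumulate around a disease.

## The problem and the model

Published study results are a biased sample of performed studies: results
that miss formal statistical significance are less likely to be reported,
and the strength of that bias can depend on a study's position in its
marker's publication history (initial finding, early replication, late
replication — including the "Proteus" pattern where early replications are
biased *against* the initial result's direction). A single meta-analysis
rarely has the power to estimate such patterns; a corpus of many markers
assumed to share the same reporting mechanism does.

For marker *m*, published log odds ratios follow
X<sub>i</sub> ~ N(Δ<sup>(m)</sup>, σ<sub>i</sub>² + σ²<sup>(m)</sup>), and a
result is published with relative probability ω(z), a stepwise-constant
weight function of the standardized effect z = X/σ. The observed-data
density is ω(x/σ)·φ(x; Δ, σ²ᵢ+σ²) / Σ<sub>j</sub> w<sub>j</sub> B<sub>ij</sub>,
where B<sub>ij</sub> is the probability mass of the j-th z-interval under
the unselected model. All markers share the weight parameters; each has its
own mean and between-study variance; everything is estimated jointly by
maximum likelihood (BFGS + blockwise-inverted numerical information matrix),
and six model specifications — from an unbiased reference through a
16-interval high-resolution weight function to category- and sign-dependent
models — are compared by AIC against the unbiased baseline.

The package also ships a per-allele effect layer (log OR from 2×3 genotype
tables by dose logistic regression, Woolf–Haldane fallback), year-based
category assignment, a convergence-exclusion protocol, and a simulator of
selectively reported corpora used for validation by parameter recovery.

## A worked example

Simulate a corpus of 100 markers whose publication process follows the
sign-dependent (Proteus) model, then fit and compare the model family:

```r
library(selectmeta)

corpus <- simulate_corpus(sim_config(
  model = "proteus",
  log_weights = c(log_w_I = -0.81, log_w_E1 = -0.11,
                  log_w_E2 = -0.43, log_w_S = -0.08),
  seed = 1
)) |> categorize_studies()

report <- run_analysis(corpus,
  models = c("unbiased", "model1", "model2", "model3", "proteus"),
  verbose = FALSE)
print(report)
```

```
<selectmeta_report>
  corpus: 1510 studies on 83 markers (17 excluded)
  model comparison (differences to the unbiased model):
    unbiased         dL =    0.000  k_w = 0  dAIC =    0.000
    model1           dL =   10.758  k_w = 1  dAIC =  -19.516
    model2           dL =   17.031  k_w = 2  dAIC =  -30.062
    model3           dL =   18.046  k_w = 4  dAIC =  -28.091
    proteus          dL =   19.084  k_w = 4  dAIC =  -30.168  <- best
  derived reporting probabilities:
    model2     log_w_I      32.8% ( 21.6%,  49.7%)
    model2     log_w_S      70.9% ( 59.8%,  84.2%)
    ...
    proteus    confirming vs opposing   71.8% ( 52.0%,  99.2%)
```

Reading the output: 17 of 100 markers were removed by the convergence
protocol (the unrestricted between-study variance has no interior optimum
for them, under any model, so all models are compared on the same 83). The
Proteus model attains the lowest AIC — the generating model wins. A
non-significant *initial* study has about a 33% chance of publication
relative to a significant one, subsequent studies about 71%, and a
non-significant early replication that *confirms* the initial direction is
published with about 72% the probability of one that opposes it (95% CI
52–99%) — the Proteus signature. `tidy()`, `glance()`, `autoplot()` and
`corrected_estimates()` expose the fitted objects; `run_simulation()` runs
seeded recovery studies.

A thin command-line wrapper is installed at `inst/cli/selectmeta.R`
(`fit`, `simulate`, `recover` verbs).

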