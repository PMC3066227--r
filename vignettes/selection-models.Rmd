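---
title: "Modelling selective reporting across many related datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling selective reporting across many related datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selectmeta)
library(dplyr)
```

## The problem

When a field produces many case-control studies on many related questions —
here, per-allele odds ratios for genetic markers of a disease — the published
record is a biased sample of the studies actually performed: results that
miss formal significance are less likely to be written up, and the strength
of that bias can depend on *when* a study appears in a marker's publication
history. Initial reports tend to be the most heavily selected; early
replications may even be biased *against* the direction of the initial
finding (the Proteus phenomenon). Any single marker has too few studies to
estimate these patterns, but if the selection mechanism is shared across
markers, pooling hundreds of results makes it estimable.

## The model

For marker $m$, published log odds ratios are modelled as
$X_i \sim N(\Delta^{(m)},\, \sigma_i^2 + \sigma^{2(m)})$ with known
within-study variance $\sigma_i^2$, marker-specific mean $\Delta^{(m)}$ and
between-study variance $\sigma^{2(m)}$. Publication operates on the
standardized effect $Z_i = X_i/\sigma_i$ through a stepwise-constant weight
function $\omega(z)$: the relative probability of publication is $w_j$ when
$z$ falls in the $j$-th interval of a fixed boundary grid. The density of an
*observed* (published) result is the weighted density

$$ f(x_i) \;=\; \frac{\omega(x_i/\sigma_i)\,
    \varphi(x_i;\,\Delta,\,\sigma_i^2+\sigma^2)}
    {\sum_j w_j B_{ij}}, \qquad
   B_{ij} = \Phi\!\left(\tfrac{z_j \sigma_i - \Delta}{\sqrt{\sigma_i^2+\sigma^2}}\right)
          - \Phi\!\left(\tfrac{z_{j-1} \sigma_i - \Delta}{\sqrt{\sigma_i^2+\sigma^2}}\right), $$

with $z_0 = -\infty$, $z_k = +\infty$. The joint log likelihood sums this
over all studies of all markers, with *one shared set of weight parameters*
and per-marker $(\Delta, \sigma^2)$. Weights are parameterized on the log
scale (positivity for free) and the outer intervals are pinned at
$\log w = 0$, so every estimate is a publication probability *relative to
results beyond the outermost boundaries*.

Six specifications are provided (`build_model()`): an unbiased reference
($\omega \equiv 1$); a high-resolution function with 16 intervals spanning
$|z| \le 2.58$ used to inspect the shape of the bias; a one-parameter model
with boundaries $(-1.64, 1.64)$; a two-category model separating the initial
study from all later ones; a three-category model adding early replications
with interval split at $z = 0$; and the Proteus model, identical in
complexity but arranging the two early-replication weights by agreement with
the *sign of the initial study's* result rather than by fixed z-intervals.
For the Proteus model the weight function over $x$ is well-defined only once
the initial sign is known, so the early template exists in two variants
(initial $z > 0$ / $z \le 0$); a study's own sign then selects its weight
automatically through its z-interval.

Temporal categories follow the first publication year of each marker: same
calendar year = initial, next two years = early replication, later = late.
When several studies share the first year, the most extreme $|z|$ defines
the initial sign.

## Fitting

`fit_selection_model()` maximizes the joint likelihood over all free
parameters (up to 14 shared log-weights plus two parameters per marker) with
BFGS, from neutral starting values: inverse-variance means, DerSimonian–Laird
moment variances (truncated at zero, plus $10^{-6}$), and zero log-weights —
the unbiased model is the optimizer's origin. Because the likelihood
separates over markers given the weights, the finite-difference gradient
needs only two vectorized passes over the corpus per parameter block, and
the information matrix is block-sparse: a weights block, one $2\times 2$
block per marker, and their cross terms. Standard errors come from exact
blockwise inversion (Schur complement) of the symmetrized central-difference
information matrix — a failure to invert is reported as a failure, never
papered over with a pseudo-inverse. A joint Newton polish after BFGS drives
the gradient max-norm below $10^{-5}$, the fit's convergence criterion,
alongside optimizer success and positive definiteness.

The between-study variances are *unrestricted*, as in classical unrestricted
ML: $\sigma^{2(m)}$ may go negative as long as every study's total variance
stays positive. This keeps the estimator unbiased near $\sigma^2 = 0$ but
creates a known pathology: for some markers the likelihood increases
monotonically as $\sigma^{2(m)}$ approaches $-\min_i \sigma_i^2$ and no
interior optimum exists. Such boundary-chasing markers are detected (non
positive-definite marker block, runaway gradient, or total variance within
$10^{-6}$ of the boundary) and flagged, never silently dropped.
`exclusion_protocol()` then removes every marker that fails under *any*
requested model and refits all models on the shared surviving corpus, so that
likelihoods and AICs remain comparable. Exclusion is iterated to a fixed
point, because a refit on the reduced corpus occasionally exposes further
boundary-chasers; reported fits are always converged fits. On realistic
corpora this removes roughly 10–15% of markers, comparable to what the
method exhibits on real data. An optional `variance_floor` mode constrains
$\sigma^{2(m)} \ge 0$ (L-BFGS-B) and needs no exclusions; it is not the
default because the unrestricted likelihood is the canonical form of the
method, and at an active bound the $\sigma^2$ standard error is undefined.

Model comparison uses $\mathrm{AIC} = 2k - 2L$, reported as differences to
the unbiased fit on the identical corpus, where per-marker parameter counts
cancel and only the weight-parameter counts and $\Delta L$ remain
(`model_table()`). Derived quantities exponentiate: a log-weight estimate
$\hat\ell$ with standard error $s$ gives a relative reporting probability
$e^{\hat\ell}$ with 95% CI $e^{\hat\ell \pm 1.96 s}$; the early-replication
contrast uses $\mathrm{SE} = \sqrt{s_1^2 + s_2^2 - 2c_{12}}$ from the
estimated covariance, because both weights share the outer-interval
reference.

## Numerical choices

* Intervals are left-open/right-closed; a $z$ exactly on a boundary belongs
  to the lower interval. Ties have probability zero under the continuous
  model; the same convention is applied in evaluation and in the $B_{ij}$
  integrals, which is what actually matters.
* $B_{ij}$ cells are computed with the complementary normal CDF on the right
  half-axis to avoid cancellation, and floored at zero.
* The normalization $\sum_j w_j B_{ij}$ is accumulated in linear space
  ($k \le 16$, all terms bounded by $\max_j w_j$) and guarded against
  non-positive values; the optimizer treats such points as infeasible and
  backtracks.
* Gradient steps are $10^{-6}\max(1,|\theta|)$, information-matrix steps
  $10^{-4}\max(1,|\theta|)$, with $\sigma^2$ steps capped at 45% of the
  distance to the total-variance boundary.
* A $z$ of exactly 0 counts as negative sign, and a tie in extremeness
  between two initial studies of opposite sign resolves to positive, so
  categorization is invariant to row order.

## The simulator

`simulate_corpus()` generates the study collections used for validation.
Per marker it draws a true mean (a point mass at zero for 90% of markers,
otherwise $|\log \mathrm{OR}| \sim U(0.1, 0.5)$ with random sign), a
between-study variance $U(0, 0.05)$, and a target of 4–30 published studies;
candidate studies with $\sigma_i \sim U(0.08, 0.4)$ then arrive in calendar
time (year gaps of 0/1/2 years with probabilities 0.5/0.35/0.15) and are
published with probability $\omega(z)/\max(\omega)$ under the generating
model's weight function for the candidate's category. Candidates preceding
the first acceptance count as initial studies; the Proteus sign context is
the first *published* study's sign. These defaults emulate the shape of a
large gene-disease corpus — about a hundred markers, a few thousand
results, mostly null effects, moderate heterogeneity — and the acceptance
probability realizes the weight function exactly, which is what makes
`expected_interval_fractions()` (the closed form $w_j B_j / \sum w_j B_j$)
an analytic oracle for the simulator.

What the simulator does *not* emulate: real calendar dynamics (publication
lags correlated with results), marker-to-marker differences in the bias,
covariate-adjusted published p-values, or linkage between markers. Passing
recovery tests therefore demonstrates internal consistency of likelihood
and generator under the model's own assumptions, not robustness to
violations of them.

## What validation shows, and a caveat worth knowing

Four kinds of checks are run by the test suite and `scripts/acceptance.R`:
the weighted density integrates to one against adaptive quadrature
($<10^{-6}$); small fits match a dense grid search; the simulator's
published-study interval fractions match the closed form at $n = 10^5$; and
nested models never lose likelihood as parameters are added. A 25-replicate
recovery study (200 markers, two-category truth
$\log w^{(I)} = -0.8$, $\log w^{(S)} = -0.2$) and an AIC study (Proteus vs
the three-category model under a 0.4 sign effect) probe the full pipeline.

One finding from these studies deserves emphasis. The expected score of the
weighted likelihood at the true parameters is zero — generator and
likelihood agree exactly — yet the jointly estimated weights are
systematically too negative by roughly one reported standard error at these
corpus sizes, and profiling confirms the ML genuinely prefers the shifted
value. This is the incidental-parameters effect: hundreds of per-marker
$(\Delta, \sigma^2)$ nuisance parameters, each informed by only a handful of
studies, tilt the shared weight estimates, exactly as in Neyman–Scott
problems. The bias shrinks as studies-per-marker grow and is well below one
standard error at the precision of the published application, but it means
2-SE recovery of the truth should not be expected in much more than ~80% of
replicates at this design, rather than the nominal ~95%. Users comparing
models (the main use) are unaffected, since all models share the nuisance
structure; users reading absolute weight values should remember they are
mildly conservative (bias toward stronger apparent selection).

## Problem sizes

The validation studies use corpora of 100–200 markers with 4–30 studies per
marker (a few thousand results), 25 replicates for recovery and coverage
studies, $10^5$ published studies for simulator checks, and 100 random
parameter draws for quadrature checks — sizes chosen to mirror the corpus
shape the method targets while keeping a full validation run in the tens of
minutes on a single core.

## A worked example

```{r example, eval = FALSE}
corpus <- simulate_corpus(sim_config(
  model = "proteus",
  log_weights = c(log_w_I = -0.81, log_w_E1 = -0.11,
                  log_w_E2 = -0.43, log_w_S = -0.08),
  seed = 1
)) |> categorize_studies()

report <- run_analysis(corpus,
                       models = c("unbiased", "model1", "model2",
                                  "model3", "proteus"))
report$table
report$reporting
autoplot(report$fits$proteus)
```

## Limitations

Beyond the incidental-parameter caveat above: weight functions depend only
on $z$ and the study's category (no journal, study-size or covariate
effects); boundaries are fixed, not estimated; the random-effects
distribution is normal; categories derive from publication years only; and
the exclusion protocol, while honest about which markers it removes, makes
the reported corpus mildly outcome-dependent — the same trade-off the
method accepts on real data.
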