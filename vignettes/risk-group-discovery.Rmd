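---
title: "Risk group discovery by optimizing the area under the survival curve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk group discovery by optimizing the area under the survival curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survarea)
```

## The problem

Clinicians rarely want a continuous risk score for an individual patient;
they want to know whether the patient belongs to a *high*, *intermediate* or
*low* risk group, because treatment strategies are discrete. With censored
survival data the usual classification route is blocked: a censored subject
has no knowable group label, so there is nothing to train an ordinary
classifier on. What can always be computed is the Kaplan-Meier curve of any
*predicted* group, and groups can be judged by the properties of those
curves — median survival time, survival at the end of follow-up, and whether
the low-risk curve stays above the high-risk curve.

`survarea` trains classifiers directly against such a curve property: the
**area under the Kaplan-Meier curve** of the predicted group, restricted to a
fixed horizon \(t_N\),

\[
A \;=\; \sum_{i=0}^{N-1} S_i\,(t_{i+1}-t_i), \qquad 0 \le A \le t_N ,
\]

the exact integral of the product-limit step function with \(t_0 = 0\),
\(S_0 = 1\), and the last segment extended flat to \(t_N\) (readers familiar
with restricted mean survival time will recognize \(A\) as the RMST of the
selected group). A classifier hunting a **low-risk** group maximizes \(A\); a
**high-risk** classifier minimizes it, implemented as maximizing the
complement \(A' = t_N - A\) so that "higher is better" uniformly. Because a
single short-lived or long-lived patient yields a nearly extremal area, the
objective alone would collapse groups to singletons; a hard minimum group
size \(m\) is therefore part of the fitness:

\[
F \;=\; \begin{cases} A \text{ or } A' & M \ge m \\ 0 & \text{otherwise,} \end{cases}
\]

where \(M\) is the number of subjects the classifier votes into its group.
Optimizing the area implicitly drives up the group's median survival time and
end survival rate, the quantities risk groupings are compared on.

## The membership classifiers and their genetic training

Each classifier is a single-hidden-layer perceptron (tanh activations, four
hidden units by default, biases included) whose scalar output answers one
one-vs-rest question: *is this subject in my group?* A strictly positive
output means yes; an output of exactly zero maps to "no", the conservative
choice under the minimum-size constraint. The output unit applies tanh before
thresholding, which is mathematically equivalent to thresholding the
pre-activation at zero and kept for symmetry with the hidden layer.

\(F\) is a step function of the weights — moving one weight changes nothing
until some subject crosses the decision boundary — so gradient methods do not
apply. Training is a steady-state genetic algorithm over flat weight vectors
(genomes):

1. **Initialize** `n_pop` genomes with independent N(0, 1) weights, a scale
   matched to the z-normalized inputs, and evaluate all fitnesses.
2. **Select** two parents by tournaments: two members are picked uniformly at
   random (with replacement; the two picks may coincide) and the fitter wins.
3. **Crossover** with probability `p_crossover`: two cut positions are drawn
   uniformly from the `length + 1` boundary positions and the contiguous
   segment between them is exchanged between the two clones; equal cuts — or
   no crossover — leave the children as clones.
4. **Mutate** every weight independently with probability `p_mutation` by a
   zero-mean Gaussian step of standard deviation `mutation_sd`.
5. **Insert** the children; the two worst members of the enlarged pool are
   discarded (fitness ties culled oldest-first, so runs are deterministic
   under a seed). Parents are not removed by selection.
6. After `n_generations * n_pop` children have been born, return the best
   genome *ever observed*, not the best survivor.

Defaults (`ga_config()`): `n_pop = 200`, `p_crossover = 0.75`,
`p_mutation = 0.5`, `mutation_sd = 1.5`, `n_generations = 1000`. These are
full-scale training values; the package's tests and the examples below use
`n_pop = 50`, `n_generations = 100`, which already recover clean synthetic
structure in about a second per classifier.

## From classifiers to three risk groups

`train_ensemble()` trains `size/2` high-risk (minimize) and `size/2`
low-risk (maximize) classifiers — 17 + 17 by default — each on its own
bootstrap resample of the training data (bagging), each with a seed derived
from the master seed. Each half is odd-sized so a within-half "in group vs
not" vote can never tie. For a new subject, `predict()` counts the high votes
\(h\) and low votes \(l\) among \(k\) members per half and assigns:

* **intermediate** if neither half reaches a within-half majority
  (\(h \le k/2\) and \(l \le k/2\)), or if \(h = l\);
* otherwise the label with more votes.

Stated either as "both halves failing their majority vote" or as "a label
needs its own majority, then most votes wins", the rule is the same function:
the vote-count winner lacks a majority exactly when both halves lack one.
The test suite checks the implemented rule against the verbal rule
exhaustively over all vote splits.

### The horizon \(t_N\)

\(t_N\) is fixed once per training run as the maximum follow-up time in the
training data handed to `train_ensemble()` — not per candidate subgroup, and
not from any held-out data. A common maximum is what makes \(A\) and \(A'\)
comparable across candidate groups, and using the training split keeps the
holdout untouched. Subgroup curves are extended flat from their last
observation to \(t_N\) so every candidate is integrated over the same
interval. At evaluation time (`cross_validate()`, `cmd_evaluate()`) the
horizon is the maximum time in the evaluated fold, so end-survival rates are
comparable across models within a fold.

## Preprocessing

`preprocess_fit()` composes, in order:

1. **categorical binarization** — each declared categorical column becomes
   one 0/1 indicator per observed level;
2. **mean imputation** — missing entries replaced by the column mean of the
   observed values (done before normalization, the only order in which "the
   column's mean" is well-defined on the raw scale);
3. **z-normalization** — \((x - \bar x)/s\) with the sample (n − 1) standard
   deviation; constant columns are dropped with a warning.

Every statistic is fitted on training data and reapplied verbatim by
`preprocess_apply()`, so nothing leaks from test data. `split_stratified()`
holds out a fraction (default 1/4) stratified on the event indicator, keeping
the censored fraction of the test set within one subject of the cohort's.

## The synthetic generator

`simulate_survival()` draws event times from a Weibull proportional-hazards
mixture: stratum \(j\) with multiplier \(h_j\) has survival
\(\exp(-h_j (t/\lambda)^{\kappa})\) (shape \(\kappa = 1\), i.e. exponential,
by default; baseline scale 365 days). Censoring is an independent
exponential whose rate is calibrated to a target censored fraction —
analytically for the exponential case, by quadrature against the event-time
density otherwise; the public benchmark tables this emulates span roughly
28–86% censoring. Covariates are the stratum indicators plus optional
standard-normal noise columns; the latent stratum labels are returned
alongside and must never be fed to a model.

What the generator does *not* emulate: correlated or mixed-type covariates,
non-proportional hazards, informative censoring, and measurement noise on
the informative covariates — the indicators make the true grouping linearly
separable. Passing recovery tests therefore demonstrates that the
optimizer and voting machinery find a recoverable structure; they do not
certify performance on messy clinical tables.

```{r example}
sim <- simulate_survival(
  sim_spec(600, list(c(1/3, 1), c(1/3, 3), c(1/3, 9)),
           censor_rate = 0.3, p_noise = 2),
  seed = 1
)
set.seed(1)
split <- split_stratified(sim$data, 0.25)

cfg <- ensemble_config(
  size = 6, m_high = 112, m_low = 112,   # quartile of the training split
  ga = ga_config(n_pop = 50, n_generations = 100)
)
ens <- train_ensemble(split$train, cfg, seed = 1)
pred <- predict(ens, split$test$covariates)
table(pred$label)

t_n <- max(split$test$times)
low <- km_estimate(subset_dataset(split$test, pred$label == "low"))
high <- km_estimate(subset_dataset(split$test, pred$label == "high"))
c(low_median = median_survival_time(low),
  high_median = median_survival_time(high),
  end_diff = end_survival_difference(low, high, t_n))
```

Under these strata the theoretical median survival is \(365\ln 2 \approx
253\) days for the low-hazard stratum and \(253/9 \approx 28\) days for the
high-hazard one; the predicted groups' medians land close to both, and the
positive end-survival difference says the curves do not cross.

## Numerical choices and conventions

* **Tied times**: events are processed before censorings at the same time
  (the standard product-limit convention).
* **Membership threshold**: output > 0 is "in group"; exactly 0 is "out".
* **Median survival**: the smallest step time with \(S \le 0.5\); undefined
  (`NA`) if the curve never reaches 0.5, e.g. under heavy censoring. (On an
  exact-0.5 plateau some survival software reports the plateau midpoint
  instead of its start.)
* **Minimize-mode zero**: a candidate group whose members are all censored
  has a flat curve, \(A = t_N\), hence \(A' = 0\) — indistinguishable from a
  size violation by score alone. `ga_train()` warns if a whole run ends at
  fitness 0.
* **Degenerate inputs**: subjects with time 0 are legal (they step the curve
  at 0 if events); a prognostic-index tie straddling an `index_to_groups()`
  cut is broken by stable input order.
* **Index cuts on new data**: cut *values* learned on reference data are
  applied to new data, so group sizes match exactly only on the reference —
  the same drift between training and test sizes the benchmark comparisons
  show.

## Problem sizes in the test suite

The packaged tests run the method at reduced scale, chosen so the whole
suite completes in a few minutes while each property remains sharply
testable: oracle comparisons on 500 random small samples (n ≤ 30);
exhaustive fitness enumeration on 12 subjects (all 4096 groups); GA
optimality on a 20-subject instance with an enumerable optimum (20 seeded
runs, `n_pop = 50`, `n_generations = 100`); and stratum recovery at n = 600
with an ensemble of 6 over 10 seeds. Full-scale analyses should use the
`ga_config()` / `ensemble_config()` defaults.

## Limitations

* The one-vs-rest ensemble supports exactly three risk groups; more groups
  would need a different construction.
* There is no gradient training — the objective is piecewise constant — so
  compute cost scales with population size and generations.
* Imputation is single-value by the mean; no modeling of missingness.
* Vote counts are returned but are not calibrated probabilities.
* The log-rank statistic was deliberately not used as the training
  objective: it favors very small groups and does not directly improve
  median or end survival, which is why the area objective exists.
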