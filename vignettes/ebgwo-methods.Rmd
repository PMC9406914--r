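---
title: "Wrapper feature selection with Levy-enhanced binary grey wolf optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper feature selection with Levy-enhanced binary grey wolf optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Vocal-biomarker tables for Parkinson's disease screening are wide and
redundant: a few hundred recordings described by ~750 acoustic features
(jitter/shimmer variants, fundamental-frequency and harmonicity parameters,
MFCC statistics, wavelet and tunable-Q wavelet energies, vocal-fold
measures). Most columns are noisy or collinear, and classifiers trained on
the full table pay for it in variance and compute. Wrapper feature
selection searches the $2^{|C|}$ subset lattice directly, scoring candidate
subsets by the validation error of an induction classifier. `ebgwo`
implements that search with an enhanced binary grey wolf optimizer.

## The optimizer

**Continuous dynamics.** Each of $N$ wolves holds a position
$X \in [0,1]^{|C|}$, one coordinate per feature. The pack's three best
solutions — alpha, beta, delta — guide everyone else through the encircling
update

$$D = |C \circ X_p - X|, \qquad X' = X_p - A \circ D,$$

with coefficients $A = 2a\,r_1 - a$ and $C = 2 r_2$, $r_1, r_2 \sim
U(0,1)$ per dimension. A wolf takes one such step toward each leader and
averages the three candidates. The scalar $a$ decays linearly from 2 to 0
over the run ($a = 2 - 2t/T$), shifting the pack from exploration
(updates can overshoot the leaders when $|A| > 1$) to exploitation.

**Levy-flight enhancement.** Plain GWO commits to the incumbent basin too
eagerly on multimodal objectives. After its leader-guided move, each wolf
is, with probability `levy_prob` (default 0.5), instead relocated to
$X_\alpha + \alpha_{\mathrm{step}} \otimes \mathrm{Levy}(\beta)$: a jump
around the current alpha whose step lengths follow a heavy-tailed stable
law. Steps are generated by the Mantegna construction,
$u/|v|^{1/\beta}$ with $u \sim N(0, \sigma_u^2)$, $v \sim N(0,1)$ and

$$\sigma_u = \left\{ \frac{\Gamma(1+\beta)\,\sin(\pi\beta/2)}
  {\Gamma\!\left(\tfrac{1+\beta}{2}\right) \beta\, 2^{(\beta-1)/2}}
  \right\}^{1/\beta},$$

which evaluates to exactly 1 at $\beta = 1$ (a closed form the tests pin
down). Defaults $\beta = 0.5$ and $\alpha_{\mathrm{step}} = 0.1$ give
occasional jumps far larger than the box, which clipping turns into
corner-seeking exploration.

**Binary layer.** A continuous position is converted to a feature mask
through the steep sigmoid transfer
$s(x) = 1/(1 + e^{-10(x - 0.5)})$, with coordinate $i$ included when
$s(x_i) \ge r_i$, $r_i \sim U(0,1)$. The unit-interval encoding is what
makes the $x - 0.5$ centring meaningful: 0.5 is maximal indecision. A
third update mode — averaging three uniformly chosen pack members
("random triplet") — is applied with probability `p_explore` (default
0.2) to keep mask diversity up.

The composition of the three mechanisms per wolf per iteration is a design
choice the method's sources leave open; here it is: exploration (triplet)
with probability `p_explore`, otherwise leader-guided, then the Levy
relocation with probability `levy_prob`. All three probabilities are
configuration, not constants. The three leaders are carried over unchanged
each iteration (elitism), and the best mask ever evaluated is tracked
separately, which is what makes the convergence trace monotone.

## The wrapper fitness

A mask $R \subseteq C$ is scored by

$$\mathrm{fitness}(R) = \alpha \cdot \mathrm{ER}(R) +
  (1 - \alpha) \frac{|R|}{|C|},$$

where $\mathrm{ER}$ is the error rate of a $k$-nearest-neighbour induction
classifier ($k = 5$, odd so votes cannot tie) on an internal stratified
holdout, and $\alpha = 0.99$ keeps error dominant while breaking ties
toward smaller subsets. Both weights are configurable. Two details matter
numerically:

* the holdout (20% of the training partition by default) is drawn **once
  per run** from the run seed, so fitness is a deterministic function of
  the mask — without this the monotone-trace property would be vacuous and
  masks could not be cached;
* the empty mask gets a $+\infty$ sentinel; if a run somehow ends with no
  feature (only possible in degenerate settings), the selector falls back
  to the single best feature by univariate wrapper fitness, so the result
  always selects at least one column.

Fitness ties are broken toward fewer features, then lower wolf index.

## Data handling

* **Standardization** is the z-score $x' = (x - \mu)/\sigma$ with the
  population $\sigma$ (divide by $n$); the convention is immaterial at
  $n \approx 570$ but fixed for exactness. Constant columns
  ($\sigma = 0$) map to 0 instead of erroring. By default parameters are
  fitted on the training partition only; `scale_before_split = TRUE` reproduces
  the historical fit-on-everything order for comparability.
* **Splitting** is stratified with largest-remainder apportionment of the
  per-class test counts, so a 756-row table with 564 positives at
  `test_fraction = 0.25` gives exactly 567/189 rows and 141 positive test
  rows. Rows (recordings) are split independently by default — matching
  the protocol this table is usually analysed with — even though each
  subject owns three rows; `by_subject = TRUE` gives the leakage-aware
  variant that keeps a subject's recordings together.
* **Missing cells are a parse error**, not an imputation case: the table
  this package targets ships complete, and silently imputing a vocal
  biomarker would change its meaning.

## The synthetic cohort generator

`generate_cohort()` emulates the *shape* of the real table so the entire
pipeline is testable without downloads: 188 case and 64 control subjects,
three recordings each (756 rows), the published feature-group structure
(21 baseline, 11 time-frequency, 84 MFCC, 182 WT, 22 vocal-fold, 432
TQWT, plus gender drawn per subject at the cohort's male/female ratios).
Features are unit-variance Gaussians with a subject-level random effect
(intraclass correlation `within_subject_rho`, default 0.5 — repeated
recordings of one voice are similar but not identical) and
`n_informative` columns receive a between-class mean shift of
`effect_size` standard deviations. Where no source states a value the
defaults are one-time choices of what a biomarker simulation plausibly
needs: `n_informative = 30` and `effect_size = 1` give a signal that is
learnable but not trivial.

What the generator does **not** emulate: the heavy non-Gaussian marginals
of real dysphonia measures, the strong within-block covariance of
MFCC/WT/TQWT features, severity gradients across patients, or any
age/medication structure. Consequently, passing tests demonstrate that the
optimizer finds planted low-dimensional signal in correlated Gaussian
noise at realistic cohort geometry — they do not certify clinical
accuracy on real recordings, and the published headline accuracies are
treated as reference outcomes, not contracts.

## Determinism and RNG discipline

Every entry point takes a seed, consumed in a documented order (holdout,
pack initialization, then per wolf per iteration: explore gate,
triplet/coefficient draws, Levy gate, Levy normals). Classifier backends
are RNG-isolated so a cache hit and a cache miss leave the optimizer's
stream identical; equal seeds make runs bit-reproducible end to end. The
pipeline derives stage seeds from one master seed (cohort: $m$; split:
$m+1$; selection: $m+2$; classifiers: $m+3$).

## Problem sizes

The shipped tests and examples run the selector at desk scale: cohorts of
756 rows with 10-50 features, packs of 5-10 wolves, 10-100 iterations —
enough for the planted-recovery and null-signal properties to be sharp
while a full suite stays under a minute. The defaults
(`pack_size = 10`, `max_iter = 1000`) are the intended analysis-scale
settings for a ~750-feature table.

## Worked example

```{r example}
library(ebgwo)

coh <- generate_cohort(
  feature_schema(data.frame(group = "f", n = 50)),
  cohort_spec(n_cases = 188, n_controls = 64, n_informative = 5,
              effect_size = 2, seed = 1))
sp <- stratified_split(coh$table, 0.25, seed = 2)
params <- standardize_fit(sp$train)
train <- standardize_apply(sp$train, params)
test <- standardize_apply(sp$test, params)

fit <- select_features(train,
                       gwo_config(dim = 50, pack_size = 10,
                                  max_iter = 100, seed = 4))
summary(fit)
sum(coh$truth %in% fit$selected)  # planted features recovered
mean(predict(fit, test) == test$labels)
```

## Known limitations

* The wrapper is stochastic: the selected subset (and its size) varies
  across seeds, which is inherent to the method — report the seed with
  any result. The selected-count reported for the real table by the
  method's sources is likewise a single-seed outcome.
* k-NN fitness on hundreds of columns equalizes distances; with very weak
  signal the search plateaus early, and the size penalty (0.01) is too
  small to prune aggressively once the error term saturates at 0.
* Row-level splitting of repeated recordings leaks subject identity
  between partitions; that is faithful to the protocol being emulated,
  and `by_subject = TRUE` exists for honest generalization estimates.
* The gradient-boosted-trees evaluator uses leaf-wise (loss-guided) tree
  growth via xgboost; it is configured to the same algorithmic family as
  leaf-wise LightGBM but is not a bit-for-bit reimplementation of it.
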