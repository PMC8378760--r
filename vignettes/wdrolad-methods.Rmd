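---
title: "Distributionally robust absolute-deviation regression: model, solvers, and benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributionally robust absolute-deviation regression: model, solvers, and benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wdrolad)
```

## The estimator

Given samples $(x_i, y_i)$, $i = 1, \dots, N$, with $x_i \in \mathbb{R}^{m-1}$,
ordinary regression minimizes an empirical loss under the fiction that the
empirical distribution $\hat{\mathbb{P}}_N$ is the truth. When a fraction $q$
of the samples comes from an outlying distribution, that fiction is expensive.
The distributionally robust alternative minimizes the *worst-case* expected
absolute loss over an ambiguity set: every distribution within order-1
Wasserstein distance $\epsilon$ of $\hat{\mathbb{P}}_N$, where the transport
metric on the joint point $z = (x, y)$ is induced by a norm $\lVert\cdot\rVert$:

$$\inf_{\beta} \; \sup_{\mathbb{Q}: W_1(\mathbb{Q}, \hat{\mathbb{P}}_N) \le \epsilon}
  \mathbb{E}_{\mathbb{Q}}\,\lvert y - x'\beta \rvert .$$

Because the absolute loss has growth rate $\kappa(\beta) =
\lVert(-\beta, 1)\rVert_*$ (the dual norm of the extended coefficient
vector), the worst-case objective is bounded by — and for full support equals —
a penalized empirical loss, which is what the package minimizes:

$$\frac{1}{N}\sum_{i=1}^N \lvert y_i - \beta_0 - x_i'\beta\rvert
  \;+\; \epsilon\,\lVert(-\beta, 1)\rVert_* .$$

The choice of transport metric decides the regularizer:

| metric on $(x,y)$ | dual norm | penalty $\kappa(\beta)$ | reformulation |
|---|---|---|---|
| $\ell_2$ | $\ell_2$ | $\sqrt{\lVert\beta\rVert_2^2 + 1}$ | second-order cone |
| $\ell_1$ | $\ell_\infty$ | $\max(\lVert\beta\rVert_\infty, 1)$ | linear program |
| $\ell_\infty$ | $\ell_1$ | $\lVert\beta\rVert_1 + 1$ | linear program |
| $\lVert v\rVert_M = \sqrt{v'Mv}$ | $M^{-1}$-weighted | $\sqrt{(-\beta,1)'M^{-1}(-\beta,1)}$ | second-order cone |

The trailing "+1" (in whatever form the dual norm expresses it) is the cost of
transporting mass along the response axis. Penalizing $\lVert\beta\rVert$
alone — classical penalized least absolute deviations (LAD) — corresponds to an
*infinite* transport cost along $y$: with $M = \mathrm{diag}(1, \dots, 1, c^2)$
and $c \to \infty$ the weighted DRO estimator converges to the
$\ell_2$-penalized LAD, and the $\ell_\infty$-metric objective differs from
the $\ell_1$-penalized LAD objective by exactly the constant $\epsilon$. Both
limits are verified numerically in the test suite. The practical difference
matters: $\sqrt{\lVert\beta\rVert_2^2+1}$ has zero slope at $\beta = 0$, so the
DRO estimator never collapses to the null fit no matter how large $\epsilon$
is, whereas a $\lambda\lVert\beta\rVert$ penalty kills every coefficient once
$\lambda$ exceeds the loss's subgradient bound $\max_j \frac1N\sum_i |x_{ij}|$.

The intercept $\beta_0$ is fitted as a free, unpenalized variable and excluded
from the transport metric: a constant coordinate has no transport
interpretation, and the underlying interceptless theory is recovered by
setting it to zero. This is a documented interpretation; the benchmark's
generating models all carry an intercept.

## How the solvers work

**Linear programs** (plain LAD, $\ell_1$- and $\ell_\infty$-metric DRO,
$\ell_1$-penalized LAD, and the optional feasibility constraint
$\lVert\beta\rVert_1 \le l$) are transcribed exactly with epigraph variables
($b_i \ge \pm r_i$ for residuals, $a \ge \pm\beta_j$, $a \ge 1$ for the
$\ell_1$-metric penalty) and solved by a dense Mehrotra predictor–corrector
interior-point method written for this package. Coefficients stay genuinely
free variables (no sign-splitting) via an augmented KKT solve; the
regularization of that system is frozen at its first-iteration scale because
growing it with the diverging barrier diagonal floors the attainable
feasibility. One step of iterative refinement absorbs the residual bias.
Feasibility, dual feasibility and duality gap are driven below $10^{-9}$
(relative). On the rare instance where the KKT system degenerates before
tolerance, the solver falls back to the simplex method (`boot::simplex`),
which is exact but slower; the test suite cross-checks the interior-point
objectives against simplex on randomized instances at $10^{-7}$. When an
$\ell_1$-type penalty provably zeroes every coefficient
($\lambda \ge \max_j \frac1N \sum_i |x_{ij}|$), the zero fit with a median
intercept is returned analytically.

**Cone-penalized problems** ($\ell_2$ and $M$-weighted metrics,
$\ell_2$-norm-penalized LAD) have a smooth penalty but a nonsmooth loss. They
are solved by hyperbolic smoothing with continuation:
$\lvert r\rvert \approx \sqrt{r^2 + \mu^2}$, Newton iterations with Armijo
backtracking at each smoothing level, and $\mu$ driven from the response
scale down to $10^{-10}\times$ that scale. The objective error of the
returned point is $O(\mu)$, far below the $10^{-6}$ reporting tolerances;
dense grid-search oracles in the tests confirm agreement to $10^{-4}$ and
better on low-dimensional instances. The $\ell_1$-ball constraint on this
route is imposed through its exact Lagrangian, with a bisection on the
multiplier. The reported `objective` of every fit is recomputed from the
returned coefficients with the generic formula, so it is consistent by
construction with what the estimator claims to minimize.

Ties among optima (the LAD loss is piecewise linear) are resolved arbitrarily
by the solver; tests therefore compare objective values, never raw
coefficients, unless the optimum is provably unique.

## The synthetic benchmark

The generator defines the benchmark's contamination designs; its
defaults are the study conditions, not tunable knobs.

* **Mixture step.** Each training sample independently is an outlier with
  probability $q$ (one uniform draw per sample — the outlier *count* is
  binomial, not fixed). Test sets are drawn from the clean component only,
  because the estimand is the clean regression plane. $q \ge 0.5$ is allowed
  but warned about: outliers are by definition the minority.
* **Clean component.** $x \sim N_{m-1}(0, \Sigma)$ with compound-symmetric
  $\Sigma$ (unit variances, correlation $\rho$),
  $y \sim N(\beta_0^* + x'\beta^*, \sigma^2)$. Either $\sigma$ is given or it
  is derived from a target signal-to-noise ratio
  $SNR = \beta^{*\prime}\Sigma\beta^*/\sigma^2$.
* **Coefficient families.** Dense: $\beta_0^* = 0.3$, twenty coefficients of
  $0.5$. Sparse: $\beta_0^* = 3$,
  $\beta^* = (0.05, 0, 0.006, 0, -0.007, 0, 0.008, 0, \dots, 0)$.
* **Outlying component.** Predictor shift $+N(5e, I)$ (dense families and
  `sparse_x`) or perturbation $+N(0, 0.25I)$ (`sparse_xy`); response shift
  $+5\sigma$ added deterministically to a clean-noise draw in the `*_xy`
  families, clean response given $x$ in the `*_x` families.
* **Detection cloud.** Thirty predictors i.i.d. $N(7.5, 4^2)$,
  $y = 0.3 + 0.5\sum_j x_j + N(0, \sigma^2)$; outliers form a tight cube of
  side $0.25$ around a uniform centre in $(7.5 \pm 12)$, placed exactly
  $\delta_R$ off the regression plane.

Every generating function takes an explicit integer seed and is
bit-reproducible; experiment drivers derive per-replicate substreams from a
single master seed. What the generator does *not* emulate: heavy-tailed or
skewed noise, heteroscedasticity, dependent contamination, or predictor
measurement error. Passing benchmarks here demonstrates behavior under the
stated Gaussian mixture, nothing stronger.

One stated design is ambiguous: when the SNR is swept, the predictor
correlation is described as "0.8 times a random noise uniformly distributed
on [0.2, 0.4]". We read this as $\rho = 0.8 \times U(0.2, 0.4)$ drawn once
per dataset, giving $\rho \in [0.16, 0.32]$.

## Tuning

Penalty parameters are selected on a single validation split (75/25, seeded;
the protocol fixes only that the
training samples are divided into a fit set and a validation set, so the
fraction is our choice). The candidate grid runs log-equally
from $0.005\,a$ to $a = \lVert X'y\rVert_\infty$ in 50 points; for
absolute-deviation methods the elementwise square root of that grid is used,
since the absolute loss is the square root of the squared loss on a single
sample. The selection criterion is the minimum *median absolute validation
residual* — read literally as the median of $|r|$, not the scale estimator
about the median — which hedges against contaminated validation rows. Ties
break toward the smaller penalty for determinism. The
$\epsilon \propto N^{-1/m}$ asymptotic rule is provided as a utility
(`epsilon_from_rate()`) but is not the default at benchmark sample sizes.

## Evaluation

Against a known truth, with $\Delta = \hat\beta - \beta^*$ and
$s = \beta^{*\prime}\Sigma\beta^*$: relative risk
$RR = \Delta'\Sigma\Delta / s$ (perfect 0, null 1); relative test error
$RTE = (\Delta'\Sigma\Delta + \sigma^2)/\sigma^2$ (perfect 1, null
$SNR + 1$); proportion of variance explained
$PVE = 1 - (\Delta'\Sigma\Delta + \sigma^2)/(s + \sigma^2)$ (perfect
$SNR/(SNR+1)$, null 0); plus test-set mean squared error. The identity
$RTE = RR \cdot SNR + 1$ is exact and property-tested.

Outlier detection flags sample $i$ when
$|r_i| > \text{threshold} \times \hat\sigma$, with $\hat\sigma$ the sample
standard deviation (denominator $n-1$) of the residuals over the entire
training set. ROC curves sweep the threshold through every distinct score;
AUC is the rank statistic with ties counted one half. In the detection
experiment the AUC is computed *out of sample*: a second cloud dataset is
generated from the same parameters with a derived seed, and residuals,
$\hat\sigma$ and labels all come from that evaluation set. The mechanics of
the out-of-sample evaluation are our choice and apply identically to every
method.

A benchmark-specific caveat: the cloud predictors are uncentred (mean 7.5),
which makes $\lVert X'y\rVert_\infty$ — and hence the whole tuning grid — sit
above the collapse threshold of the $\beta$-only $\ell_1$ penalty. Across
that grid the $\ell_1$-penalized LAD is the intercept-only fit, so its
AUC-versus-$\lambda$ curve is degenerate-flat rather than peaked-and-falling,
while the DRO curve stays informative. The flatness comparison between the
two curves is therefore reported by the experiment but not asserted by the
acceptance tests.

## Generalization bounds

`generalization_bound()`, `tail_bound()`, `min_n_expected()` and
`min_n_tail()` evaluate the Rademacher-complexity-based out-of-sample
guarantees: with probability $1 - \delta$,

$$\mathbb{E}\lvert y - x'\hat\beta\rvert \le
  \frac1N \sum_i \lvert y_i - x_i'\hat\beta\rvert
  + \frac{2\bar B R}{\sqrt N} + \bar B R \sqrt{\frac{8\log(2/\delta)}{N}},$$

where $R$ bounds $\lVert(x, y)\rVert$ almost surely and $\bar B$ bounds
$\kappa(\beta)$ over the feasible set; logarithms are natural. The helpers
estimate $R$ and $\bar B$ by plug-ins (maximal observed data norm,
$\kappa(\hat\beta)$), clearly flagged as plug-ins rather than almost-sure
bounds. All four evaluators enforce $\delta \in (0,1)$; the coverage of the
expectation bound is property-tested on truncated-support resampling (200
replicates at $\delta = 0.1$). The deeper estimation-error theory
(restricted eigenvalues, Gaussian widths, unspecified universal constants) is
deliberately not turned into numbers: those constants are not computable from
the source material, and a calculator that invents them would be noise. A
$1/\sqrt{N}$-consistent stand-in — parameter recovery improving from
$N = 100$ to $N = 2000$ — is tested instead.

## Problem sizes and numerical choices

The shipped tests reproduce the benchmark at its native sizes
($N = 100/M = 60$ dense scenarios with 10 replicates, $N = 60$ clouds with 20
replicates, 200 randomized solver-oracle instances, 50,000-draw moment
checks), which keeps the whole suite in the minutes range on a single core.
Solver tolerances: interior point $10^{-9}$ relative; smoothing floor
$10^{-10}\times$ response scale; a fitted $\lvert\beta\rvert_1 < 10^{-5}$
is snapped to exactly zero only when the zero fit's objective is no worse
within $10^{-10}$. Degenerate inputs are handled explicitly: zero-signal
truths are rejected where RR would divide by zero, constant residuals warn
and make flagging all-or-nothing, single-class detection problems error
rather than return a vacuous AUC, and rank-deficient OLS designs return the
minimum-norm solution.

## Worked micro-example

```{r example}
spec <- scenario_spec("dense_xy", q = 0.3, snr = 0.5, rho = 0.25,
                      n_train = 100, n_test = 60, seed = 7)
ds <- generate_dataset(spec)
train <- ds$data[setdiff(names(ds$data), "is_outlier")]

fit <- fit_wdro(train, epsilon = 0.1, norm = "l2")
glance(fit)
score_estimate(fit, ds$truth, ds$test)
```

```{r roc, fig.width = 4, fig.height = 4}
cloud <- generate_cloud_dataset(60, q = 0.3, sigma = 0.5,
                                delta_r = 2.5, seed = 1)
ctrain <- cloud$data[setdiff(names(cloud$data), "is_outlier")]
det <- detect_outliers(fit_wdro(ctrain, epsilon = 1, norm = "l2"), cloud$data)
autoplot(det)
```

## Known limitations

* The worst-case inner problem is handled through its convex relaxation
  (exact for full-support ambiguity sets); the supremum over distributions is
  never solved directly, and no stochastic/first-order large-scale solver is
  provided — the intended regime is hundreds of samples and tens of
  predictors.
* Only order-1 Wasserstein balls: higher orders drive the growth rate to
  zero and erase the ambiguity-set structure for this loss.
* M-estimation implements the classical Huber/Talwar/Fair weights with
  textbook tuning constants (1.345, 2.795, 1.4) and MAD/0.6745 rescaling per
  iteration from an OLS start; the weight families enter the benchmark by
  name only, so the classical defaults are an assumption, exposed as
  parameters.
* LMS/LTS/S/MM estimators are out of scope; they appear in the robustness
  literature the method is positioned against, not in the comparisons.
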