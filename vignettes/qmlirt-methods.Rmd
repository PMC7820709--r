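---
title: "Quantile multilevel IRT: model, sampler, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile multilevel IRT: model, sampler, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Multilevel IRT couples a measurement model for item responses with a
regression ("structural") model for the latent trait.  `qmlirt` fits the
two-level model

$$P(Y_{ik} = 1 \mid \theta_i) = \Phi\!\big(a_k(\theta_i - b_k)\big),
\qquad \theta_i = X_i^{\top}\beta_\tau + \delta_i,$$

where $Y_{ik}$ is person $i$'s dichotomous response to item $k$,
$a_k > 0$ and $b_k$ are discrimination and difficulty, and the second
level is *quantile* regression: $X_i^\top\beta_\tau$ is the $\tau$th
conditional quantile of the latent trait, i.e. the only assumption on
$\delta_i$ is that its $\tau$th quantile is zero.  Compared with the
usual linear structural model ($\delta_i \sim N(0,\alpha^2)$, fitted
here by `mmlirt()` as the baseline), the quantile formulation describes
how covariate effects differ across the low, middle and high parts of
the ability distribution, and is robust to skewed or heteroscedastic
latent-trait errors.  With symmetric errors the two models coincide at
$\tau = 0.5$, which the test suite checks empirically.

For Bayesian computation the error is given the asymmetric Laplace
*working* likelihood $\delta_i \sim \mathrm{ALD}(0, \omega, \tau)$ with
density $f(u) = \tfrac{\tau(1-\tau)}{\omega}
e^{-\rho_\tau(u)/\omega}$, whose mode-finding corresponds to check-loss
minimization.  The ALD admits a normal–exponential mixture: with
$e_i \sim \mathrm{Exp}(\text{mean } \omega)$,

$$\theta_i \mid \beta_\tau, \omega, e_i \sim
N\!\big(X_i^\top\beta_\tau + k_1 e_i,\; k_2\,\omega\,e_i\big),
\qquad k_1 = \frac{1-2\tau}{\tau(1-\tau)},\quad
k_2 = \frac{2}{\tau(1-\tau)}.$$

The package verifies this identity by quadrature in its test suite; it
is what makes every full conditional below a standard distribution.

One item (the *anchor*, item 1 by default) has $(a,b)$ fixed at
$(1,0)$: the 2PNO latent scale is otherwise only identified up to an
affine map.

## The Gibbs sampler

Each sweep updates, in order:

1. **Augmented data** $z_{ik} \sim N(a_k(\theta_i - b_k), 1)$ truncated
   to $(0,\infty)$ if $y_{ik}=1$, to $(-\infty,0]$ if $y_{ik}=0$
   (probit data augmentation).  Missing cells — the booklet designs of
   large assessments leave most cells unanswered — are simply skipped,
   here and in every sum below.
2. **Discriminations** $a_k$: conjugate normal, truncated to
   $(0,\infty)$.  The conditional is usually printed untruncated; the
   prior $N(\mu_a,\sigma_a^2)I(a_k>0)$ forces the truncation, which is
   numerically negligible at $\sigma_a = 200$ but kept for correctness.
3. **Difficulties** $b_k$: conjugate normal.
4. **Abilities** $\theta_i$: conjugate normal combining the person's
   item information $\sum_k a_k^2$ with the structural prior
   $N(X_i^\top\beta_\tau + k_1 e_i,\, k_2\omega e_i)$.
5. **Scale** $\omega$: the mixing variables are integrated out
   analytically, giving
   $\omega^{-1} \sim \Gamma\big(n + \alpha_{0\omega},\,
   \beta_{0\omega} + \sum_i \rho_\tau(\theta_i -
   X_i^\top\beta_\tau)\big)$.  Together with step 6 this is a valid
   *blocked* draw of $(\omega, e)$ given $(\theta, \beta_\tau)$.
6. **Mixing variables**: $e_i^{-1} \sim
   \mathrm{InvGauss}\big(\sqrt{2k_2+k_1^2}/|\theta_i -
   X_i^\top\beta_\tau|,\; (2k_2+k_1^2)/(k_2\omega)\big)$.
7. **Coefficients** $\beta_\tau$: multivariate normal with precision
   $H_{0\beta}^{-1} + \sum_i X_iX_i^\top/(k_2\omega e_i)$.

The baseline `mmlirt()` shares steps 1–4 and replaces 5–7 with the
conjugate normal/inverse-gamma updates of a linear regression.

The sweep is implemented twice: a compiled engine (Rcpp) used by
default, and a pure-R reference built from the exported `sample_*`
step functions.  Every conditional is tested against closed-form,
moment, or grid-normalization oracles; the two engines are compared
statistically; and a replicated-sweep "getting it right" check verifies
that a sweep started from an exact draw of the prior joint stays in
that distribution.  (A single long chain is deliberately *not* used for
that check: $\omega$'s prior tail is heavy enough that one chain visits
it through rare long excursions and batch-means standard errors become
anti-conservative.)

## Priors and tunable parameters

Defaults (all changeable through `qmlirt_priors()`):

| Parameter | Prior | Default |
|---|---|---|
| $a_k$ | $N(\mu_a, \sigma_a^2)I(>0)$ | $\mu_a=0$, $\sigma_a=200$ |
| $b_k$ | $N(\mu_b, \sigma_b^2)$ | $\mu_b=0$, $\sigma_b=100$ |
| $\beta_\tau$ | $N_q(\Lambda_{0\beta}, H_{0\beta})$ | $0$, $100I$ |
| $\omega^{-1}$ | $\Gamma(\alpha_{0\omega}, \beta_{0\omega})$ | $28$, $4$ |
| $\alpha^2$ (baseline) | Inv-$\Gamma(a_0,b_0)$ | $1$, $1$ |

$\sigma_a$ and $\sigma_b$ are prior *standard deviations*.  Note that
$\Gamma(28,4)$ is **not** weak: it concentrates $\omega$ near $1/7$.
These defaults are kept because they define the package's reference
protocol (the simulation-table reproductions depend on them), but users
fitting their own data should treat `omega_shape`/`omega_rate` as
substantive choices.

Chain protocol (`chain_config()`): 10 000 iterations with 5 000 burn-in
is the reference protocol; the recovery studies use a desk-scale
3 000/1 500 protocol, which is adequate for posterior-mean point
estimates.  It is *not* adequate for the between-chain convergence
diagnostic: the anchor-identified scale direction (the trade-off
between the spread of $\theta$ and the discriminations, which drags
$\beta_\tau$ and $\omega$ along) has an autocorrelation time of a few
hundred sweeps, so 1 500-draw chains leave max PSRF around 1.15–1.3
regardless of how the chains are started, while the reference protocol
brings it below 1.03.  The PSRF < 1.10 check therefore runs at the
reference protocol.  Thinning defaults to 1.

**Initialization.**  All blocks start at neutral values
($a_k = 1, b_k = 0, \beta = 0, \omega = \alpha^2 = 1, e_i = 1$) except
$\theta$, which starts at independent $N(0,1)$ draws.  Starting
$\theta \equiv 0$ is *not* safe: the first discrimination conditional
then degenerates to its near-flat prior, the initial $a_k$ land in the
hundreds, and the chain settles in a collapsed-scale mode (tiny
$\theta$ scale, inflated discriminations, structural coefficients
biased toward zero).  Additional chains get mildly overdispersed jitter
so multi-chain PSRF is an honest diagnostic.

**Intercept.**  `fit_intercept` is on by default for data analysis.
The recovery studies fit without an intercept: only the slopes are
recovery targets there, any $\tau$-dependent location shift is absorbed
by the item difficulties, and item recovery is judged by
affine-invariant metrics (below).  With standard-normal covariates the
check-loss population minimizer of the slopes is unaffected by the
omitted intercept.

## What the synthetic-data generator emulates

`simulate_study_data()` reproduces a three-case design with true slopes
$\beta = (0.5, 0.5)$ on two independent $N(0,1)$ covariates:

* **Case 1** (normal, homoscedastic): $\delta_i \sim N(0, 0.5)$
  (variance 0.5 — every "$N(0, 0.5)$" in the design is read as a
  variance; the generator exposes `error_var` so the
  standard-deviation reading can be probed).
* **Case 2** (heteroscedastic): $\theta_i = v_i - \rho_\tau|v_i| +
  |v_i|\delta_i$ with $v_i = 0.5X_{i1}+0.5X_{i2}$,
  $\delta_i \sim N(0,1)$, $\rho_\tau = \Phi^{-1}(\tau)$; by
  construction its $\tau$th conditional quantile is exactly $v_i$ for
  every $\tau$.
* **Case 3** (skewed): $\delta_i \sim \Gamma(0.5, 1) - 0.5$.

Items: $a_k \sim U(0.5, 1.5)$, $b_k \sim N(0, 0.5)$, with item 1 then
set to the anchor values so that truth and constraint coincide.
Responses are complete by default; booklet missingness is available
through `missing_mask`.

The generator does *not* emulate: clustered (school-level) structure,
polytomous or multidimensional items, covariate measurement error, or
informative missingness.  A green recovery test therefore establishes
correctness of the sampler under the stated design, not robustness to
those features.

## Diagnostics

*Item-parameter scale comparison.*  Item parameters estimated at
different quantiles (or under different models) live on affinely
related latent scales: if $\theta^* = p\theta + t$ then
$a_k^* = a_k/p$ and $b_k^* = p b_k + t$.  Raw bias of item parameters
is therefore not meaningful across quantiles.  The package reports the
uncentered cosine of discrimination vectors (equal to 1 under any
common rescaling) and the centered cosine — numerically the Pearson
correlation — of difficulty vectors (equal to 1 under any increasing
affine map).

*Convergence.*  `psrf()` implements the Gelman–Rubin potential scale
reduction factor from multiple chains (a single chain is split in
half), with 1.10 as the working threshold.  The anchor item is constant
by construction and reported as `NA` (undefined), not 1.

*Model comparison.*  `joint_dic()` computes the deviance information
criterion from the joint hierarchical likelihood conditioned on
parameters at all levels,
$f(\theta, Z \mid \xi, \beta_\tau, \omega, e) = f(Z\mid\theta,\xi)\,
f(\theta\mid\beta_\tau,\omega,e)$ for the quantile model and
$f(Z\mid\theta,\xi)\,f(\theta\mid\beta,\alpha^2)$ for the baseline.
Because the published definition prints the deviance without fixing the
evaluation point, the report exposes $\bar D$ (posterior mean
deviance), $\hat D$ (deviance at the posterior means of all conditioned
quantities, including the augmented data), $p_D = \bar D - \hat D$, and
$DIC = \bar D + p_D$, so either convention is recoverable.  The
headline number evaluates the measurement level on the augmented-data
scale, matching the conditioning on $Z$; `scale = "observed"`
substitutes the Bernoulli likelihood as a sensitivity check.  DIC
values are comparable between `qmlirt` and `mmlirt` fits of the same
data (both condition on the same augmented structure), and within
`qmlirt` across quantiles.

## Numerical choices

* Truncated normals use rejection sampling in the compiled engine
  (plain rejection near the bulk, translated-exponential rejection in
  the tail) and a stable inverse-CDF transform in the R reference
  (tail probabilities computed on the side that avoids catastrophic
  `qnorm(1 - tiny)` evaluations).  Both are tested against the
  truncated CDF by Kolmogorov distance.
* Inverse-Gaussian draws use the transformation-with-rejection scheme;
  the smaller quadratic root is computed through the product of roots,
  which stays accurate when the mean/shape ratio is extreme.
* A zero structural residual would send the inverse-Gaussian mean to
  infinity; residuals are clamped below at $10^{-8}$ in absolute value
  (a measure-zero event under the continuous model).
* Bernoulli probabilities in the observed-scale likelihood are clipped
  to $[10^{-12}, 1-10^{-12}]$.
* Posterior summaries are means and SDs of post-burn-in draws; the
  replication protocol derives per-replication seeds as
  `base_seed + replication index` and records them in the run manifest.

## Scope and limitations

* Reduced protocol: the shipped recovery studies use 20 replications of
  3 000-iteration chains (the reference protocol is 100 × 10 000);
  Monte-Carlo tolerances in the acceptance tests are set accordingly
  (two standard errors for bias cells, 15% relative for RMSE cells).
  The full grid is a documented long-running option of the `study` CLI
  subcommand, not something the test suite executes.
* Quantiles are fitted one at a time; nothing prevents crossing of
  fitted quantile surfaces across separate fits.
* The ALD is a working likelihood: posterior spread of $\beta_\tau$
  inherits its usual mild miscalibration; the recovery studies measure
  bias/RMSE of point estimates, not interval coverage.
* Three-level (group) structure, polytomous items, latent covariates,
  and variable selection are out of scope.
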