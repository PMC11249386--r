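---
title: "Methods: SNR-optimal aggregation of rank-calibrated classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNR-optimal aggregation of rank-calibrated classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moca)
```

## The problem

Suppose M pre-trained binary classifiers each assign a real-valued score to
the same N samples, higher scores meaning "more likely positive". The scores
live on incompatible scales — posterior probabilities, SVM margins,
correlation coefficients — so before they can be combined each classifier is
*rank-calibrated*: within each classifier the samples are ranked so that
rank 1 goes to the sample with the largest score. All of the mathematics in
this package operates on that M x N rank matrix. Ties receive average ranks,
which keeps every row sum at exactly N(N+1)/2 and makes the rank-based AUC
coincide with the Mann-Whitney statistic with half credit for ties.

## The SNR and the optimal linear ensemble

Classifier performance is measured by the signal-to-noise ratio of its ranks,

$$S_i = \frac{\mu_{i|0} - \mu_{i|1}}{\sqrt{\sigma^2_{i|1} + \sigma^2_{i|0}}},$$

where $\mu_{i|y}$ and $\sigma^2_{i|y}$ are the mean and variance of
classifier $i$'s ranks conditioned on the true class $y$. A classifier that
follows the rank-1-is-most-positive convention and beats chance has $S_i > 0$;
for Gaussian class-conditioned scores the AUC is $\Phi(S/\sqrt 2)$
(`snr_to_auc()` / `auc_to_snr()`). A perfect classifier (AUC = 1) attains the
closed-form ceiling

$$S_{\max}(\rho, N) = \frac{\sqrt 3}{\sqrt{(1-\rho)^2 + \rho^2 - 2/N^2}}
  \le \frac{\sqrt 6}{\sqrt{1 - 4/N^2}},$$

with $\rho$ the positive-class prevalence (`max_snr()`); the bound is attained
at $\rho = 1/2$. All variances here are population-normalized (divide by the
class count): under that convention the ceiling is exact at finite N — the
perfect discrete ranking's SNR equals $S_{\max}$ identically, which the test
suite checks on a grid of $(\rho, N)$.

A linear ensemble scores sample $k$ as $s_k = \sum_i w_i r_{ik}$; because low
ranks are positive-leaning, *smaller ensemble scores mean more likely
positive*, an orientation every metric in the package respects. The ensemble
SNR is

$$S_{ens}(w) = \frac{w^\top \Delta}{\sqrt{w^\top C w}},
\qquad \Delta_i = \mu_{i|0} - \mu_{i|1},
\qquad C = C_0 + C_1,$$

with $C_y$ the class-conditioned covariance matrices of the rank rows. It is
maximized, over all weight directions, by the Fisher-discriminant weights

$$w^* \propto C^{-1}\Delta, \qquad
  S_{ens}(w^*) = \sqrt{\Delta^\top C^{-1}\Delta},$$

so correlated classifiers are automatically down-weighted while strong,
independent ones dominate. With diagonal C (class-conditionally independent
classifiers) this reduces to $w_i \propto \Delta_i/(\sigma^2_{i|1} +
\sigma^2_{i|0})$ and the optimal SNR to $\sqrt{\sum_i S_i^2}$ — for M equally
strong independent classifiers the ensemble SNR grows as $\sqrt M$.

## Supervised fitting

With labels, `moca(ranks, labels)` estimates $\Delta$ and $C$ by their
empirical class-conditioned moments and applies the closed form. Two
controls matter:

* `ridge` (default 0) — a singular pooled covariance (duplicated or affinely
  dependent classifiers) is a hard error by default; `ridge = x` solves with
  $C + x\,\bar c\,I$ instead ($\bar c$ = mean diagonal entry). The default is
  deliberate: silent regularization would change the estimator unnoticed.
* `select = TRUE` — greedy forward selection. Start from the classifier with
  the largest individual SNR; at each step add the classifier that most
  increases the optimal subset SNR $\sqrt{\Delta_S^\top C_S^{-1}\Delta_S}$
  (moments recomputed on each candidate subset); stop when no addition
  improves the criterion by a relative $10^{-9}$; ties go to the lowest
  classifier index. The training-SNR criterion was an open design choice —
  we prefer it over held-out AUC because it is deterministic, label-efficient
  and matches the quantity the weights maximize. Candidates that make the
  subset covariance singular (exact duplicates) cannot increase the
  criterion and are skipped, so at most one copy of a duplicated classifier
  is ever selected.

## Unsupervised fitting

Without labels, `moca(ranks)` assumes *class-conditioned independence* and
recovers the quantities in the diagonal-C weight formula from moments that
need no labels. Writing $\rho$ for the prevalence, the unconditioned rank
moments of a two-class mixture satisfy

$$Q_{ij} = \rho(1-\rho)\Delta_i\Delta_j \quad (i \ne j), \qquad
  T_{ijk} = \rho(1-\rho)(2\rho - 1)\Delta_i\Delta_j\Delta_k
  \quad (i, j, k \text{ distinct}),$$

where $Q$ is the covariance matrix and $T$ the third central-moment tensor
of the rank rows. The pipeline (`fit_umoca()`) is:

1. **Rank-one covariance fit.** Only the off-diagonal entries of $Q$ carry
   the signal (the diagonal adds conditional variances), so $Q \approx \ell
   uu^\top$ is fit by iterated diagonal imputation: take the leading
   eigenpair, replace the diagonal with that of $\ell uu^\top$, repeat until
   the diagonal is stationary. The sign of $u$ is chosen so its entries sum
   to a positive value.
2. **Single-factor CP tensor fit.** $T_{ijk} \approx t_i t_j t_k$ on the
   distinct-index entries only (repeated indices mix in variance terms), by
   alternating least squares initialized from $u$. The tensor is odd-order,
   so the sign of $t$ is identified by the data.
3. **Prevalence and separations.** With $c$ the tensor scale along $u$, the
   scalar $\gamma = -c/\ell^{3/2} = (1-2\rho)/\sqrt{\rho(1-\rho)}$ yields
   $\rho$ from a quadratic, taking the root below 1/2 when $\gamma > 0$; then
   $\hat\Delta = \sqrt{\ell}\,u/\sqrt{\hat\rho(1-\hat\rho)}$. The model has
   an exact joint ambiguity — flipping the sign of $\Delta$ while swapping
   $\rho \leftrightarrow 1-\rho$ leaves every moment unchanged — which is
   resolved by requiring a majority of positive separations (the
   wisdom-of-crowds premise that the average classifier beats chance). At
   $\gamma \approx 0$ the prevalence is unidentifiable (the off-diagonal
   tensor vanishes at $\rho = 1/2$); we then fix $\hat\rho = 1/2$ with a
   warning rather than fail, since $\hat\Delta$ remains recoverable from the
   covariance alone.
4. **Conditional-variance sums.** Per classifier, the mixture identities
   $$m_2 = \rho\sigma^2_{|1} + (1-\rho)\sigma^2_{|0} + \rho(1-\rho)\Delta^2,
   \qquad
   m_3 = 3\rho(1-\rho)\Delta(\sigma^2_{|0}-\sigma^2_{|1})
       + \rho(1-\rho)(2\rho-1)\Delta^3$$
   are solved as a linear system for the two conditional variances, taking
   the conditional distributions as skewless — that is the model assumption
   behind the estimator, stated openly. For tie-free ranks $m_2 = (N^2-1)/12$
   and $m_3 = 0$ exactly, giving the closed form
   $(N^2-1)/6 - \Delta^2[2\rho(1-\rho) + (1-2\rho)^2/3]$. When
   $|\hat\Delta_i|$ is numerically zero the skew equation is ill-posed and
   the skew term is dropped; a non-positive solution is floored at a small
   positive value; both cases are flagged in the diagnostics.

The weights are then $w_i \propto \hat\Delta_i/(\hat\sigma^2_{i|0} +
\hat\sigma^2_{i|1})$, unit-normalized. No function in this path accepts
labels. The estimator needs $M \ge 3$ (the off-diagonal moment systems are
otherwise unidentifiable) and degrades gracefully — but measurably — when
conditional independence is violated; the test suite demonstrates the
degradation on simulations with a dependence dial.

## Numerical choices

* Rank-one fits: `tol = 1e-6`, `max_iter = 1000` by default. Convergence of
  the diagonal imputation is linear; the exact-recovery tests tighten `tol`
  to `1e-13` and invert analytically constructed population moments to
  relative error below $10^{-6}$.
* $\Phi$ and $\Phi^{-1}$ are `pnorm`/`qnorm` — double precision, no
  approximations.
* `binarize_by_prevalence()` breaks score ties by sample index, making hard
  predictions deterministic.
* Linear solves use `solve()` on the symmetrized matrix; no silent
  pseudo-inverse.

## The simulator

`simulate_predictions()` draws class-conditioned Gaussian scores: negative
class mean 0, positive class mean $\sqrt 2\,\Phi^{-1}(\mathrm{AUC}_i)$, unit
variances, both classes sharing a user-supplied conditional correlation
matrix (identity = conditional independence), then rank-transforms. Class
sizes are deterministic, $N_1 = \mathrm{round}(\rho N)$, matching the
fixed-split framing of the SNR ceiling rather than Bernoulli labels.
`sample_dependence_matrix()` emulates heterogeneous dependence with a seeded
two-factor model scaled by a `strength` dial; it is a synthetic stand-in for
correlation structures harvested from real submission data, not a
reproduction of any dataset.

What passing tests on this generator do and do not show: simulated scores
are exactly Gaussian with equal class variances and zero conditional skew —
precisely the regime in which the unsupervised moment system is exact. Real
classifier panels have skewed, heavy-tailed, variably dependent conditionals;
the dependence dial probes the independence violation, but nothing here
certifies behavior under conditional skew or non-Gaussian tails beyond the
rank transform's monotone invariance.

## Evaluation harness

`cross_validate()` runs repeated stratified k-fold cross-validation
(default 5 folds). Within each fold the training and test rank submatrices
are *re-ranked within the split*: ensemble weights act on ranks, and rank
scales grow with split size, so re-ranking keeps the weight semantics
split-size-free (whether to re-rank inside folds was an open choice; this is
the package's contract). Supervised methods fit on training columns;
the unsupervised method ignores the training labels by contract; the
best-individual baseline picks the classifier with the highest training AUC
(ties to the lowest index); the wisdom-of-crowds baseline needs no fitting.
AUC, balanced accuracy and F1 are computed on test ensemble scores, hard
labels coming from the training-prevalence quantile cut. Reported values are
mean ± SEM over all folds pooled across repeats.

Problem sizes used by the test suite and the reproduction script — chosen as
comfortable desk-scale settings for a laptop CPU: weight-recovery runs use
10 classifiers with AUCs evenly spaced in [0.55, 0.9], prevalence 0.4,
2500 samples, 25 seeds; the cross-validation dominance experiment uses the
same panel at 400 samples over 50 seeds; exact identities are checked at a
few hundred to a thousand samples.

## Known limitations

* The unsupervised estimator is derived under class-conditioned
  independence with skewless conditionals; under strong dependence its
  weight estimates (and especially $\hat\rho$) are biased, and the package
  intentionally reports diagnostics (`gamma`, convergence flags, flagged
  variance sums) rather than attempting a higher-rank correction.
* Prevalence is unidentifiable at exactly $\rho = 1/2$ from these moments.
* Greedy selection is a heuristic: it is guaranteed not to underperform the
  best single classifier on the training criterion, but not to find the best
  subset.
* Missing predictions are rejected, not imputed; partial rankings are out of
  scope.
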