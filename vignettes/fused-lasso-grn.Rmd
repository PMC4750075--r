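---
title: "Inferring gene regulatory networks with a weighted fused LASSO over multiple condition data sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene regulatory networks with a weighted fused LASSO over multiple condition data sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fusegrn)
```

## The problem and the model

A transcription factor (TF) that regulates a target gene leaves two
signatures in time-resolved expression data: the target's profile is
partially explained by the TF's profile, and the two genes tend to
respond jointly when the cell is perturbed.  `fusegrn` reconstructs a
directed, signed TF-to-target network from $k$ expression data sets
$X^i$ (genes $\times$ $N^i$ time points), gathered under $k$ different
conditions, each with a matched control data set $X^{c,i}$ of replicate
measurements of the unperturbed state.

For every response gene $Y$ the package solves one penalized
regression over all conditions at once.  The $k$ per-condition designs
are stacked block-diagonally into $X$ (rows $=\sum_i N^i$ time points,
columns $=k$ blocks of the $P$ TF regressors), the response profiles
are stacked into $Y$, and the coefficients $\beta = (\beta^1, \dots,
\beta^k)$ — one block per condition — are estimated by

$$\hat\beta = \arg\min_\beta \;\; \lVert Y - X\beta \rVert_2^2
  + \lambda_1 \lVert D_1 \beta \rVert_1
  + \lambda_2 \lVert D_2 \beta \rVert_1 .$$

Three biological constraints are encoded here:

1. **Sparsity.** Each gene is regulated by few TFs, so the $L_1$
   penalty shrinks most coefficients to exactly zero.
2. **Cross-condition similarity.** True regulatory interactions should
   not depend on which perturbation was applied.  $D_2$ is the fusion
   matrix: each row encodes one difference $\beta^i_j -
   \beta^{i+1}_j$ between consecutive condition blocks ($(k-1)P$ rows,
   one $+1$ and one $-1$ each), so the fusion term penalizes
   disagreement between the $k$ per-condition networks.  The chain
   couples consecutive pairs in the (arbitrary but fixed) load order of
   the data sets.
3. **Similar differential behavior.** $D_1 = \mathrm{diag}(w)$ carries
   a weight per coefficient: a TF whose differential-expression profile
   resembles the response's is penalized less, because a differentially
   behaving regulator is the likely cause of a differentially behaving
   target.

## Differential-expression probabilities and the penalty weights

The weights come from an empirical-Bayes analysis of
treatment-versus-control contrasts.  For gene $g$ at time point $t$ of
condition $i$ the contrast is the treatment value minus the mean of the
control replicates (data are assumed already on the log2 scale and
normalized; no background correction is applied).  Gene-wise variances
$s_g^2$ with $d = m - 1$ degrees of freedom ($m$ control replicates,
$m \ge 2$ required) are shrunk through the standard hierarchical model
for array variances: a scaled inverse chi-square prior $(d_0, s_0^2)$
is fitted by moment matching on $\log s_g^2$, giving posterior
variances

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

which lie between $s_g^2$ and $s_0^2$; homogeneous variances give
$d_0 = \infty$ and $\tilde s_g^2 = s_0^2$.  The moderated $t$ uses
$\tilde s_g$ with the contrast's unscaled standard error
$u = \sqrt{1 + 1/m}$.  The B statistic is the log posterior odds that
the true contrast is non-zero under a two-component mixture: a point
mass at zero with prior weight $1 - p$ and a normal effect component
with unscaled variance $v_0$ (prior DE probability $p$ defaults to
0.01).  Equivalently, B is the log density ratio of the
variance-inflated $t$ distribution to the null one, plus the prior log
odds — a closed form the test suite verifies directly against the
density ratio, and whose variance shrinkage is cross-checked against
the independent `limma` implementation.  $v_0$ is estimated from the
upper tail of the moderated $t$ statistics (the top $p/2$ fraction,
matched to their mixture quantiles); when the tail carries no excess
spread the documented fallback $v_0 = 9u^2$ (typical true effects of
three standard errors) is used.  Probabilities are
$\mathrm{pr} = e^B / (1 + e^B)$.

The weight between response $Y$ and regressor $j$ in condition $i$ is
the mean absolute difference of their probability profiles,

$$w^i_{Y,j} = \frac{1}{N^i} \sum_{t=1}^{N^i}
   \left| \mathrm{pr}^i_{Y,t} - \mathrm{pr}^i_{j,t} \right| ,$$

which is zero exactly when the profiles coincide (both genes
responsive, or both unaffected), lies in $[0,1]$, is symmetric with a
zero diagonal as an all-pairs matrix, and — being a mean of absolute
differences — satisfies the triangle inequality.  The $1/N^i$ scaling
keeps weights comparable across conditions with different numbers of
time points; only the relative penalization within a condition would
change under the unscaled sum.  Note a deliberate consequence: a pair
of genes that are *both* strongly differentially expressed gets weight
near zero and its edge is nearly unpenalized, which is the model's
stated preference for linking jointly responsive genes.

## Numerical choices

**Standardization.** Within each condition block every regressor column
is centered and scaled to unit standard deviation over that condition's
time points, and the response is centered (no intercept).  $L_1$
penalties are scale-sensitive and the condition blocks may sit on
different intensity scales; coefficients are reported on the
standardized scale.  This is configurable (`standardize = off`) because
fitting on raw values is a legitimate alternative when all data sets
share a common scale.

**Solver.** The objective is minimized by local quadratic approximation
(LQA): each $|u|$ is majorized at the current iterate by
$u^2 / (2\sqrt{u_0^2 + \varepsilon}) + c$, turning every step into the
ridge system

$$\left( X^\top X + \tfrac{\lambda_1}{2} D_1^\top A_1 D_1
  + \tfrac{\lambda_2}{2} D_2^\top A_2 D_2 \right) \beta = X^\top Y,
  \qquad A_r = \frac{1}{\sqrt{(d_r^\top \beta_{\mathrm{prev}})^2 + \varepsilon}},$$

solved by Cholesky decomposition.  Because this is a
majorize-minimize scheme the $\varepsilon$-smoothed objective is
non-increasing across iterations (asserted in tests).  Defaults:
$\varepsilon = 10^{-10}$, at most 500 iterations, convergence when the
largest coefficient change drops below $10^{-8}$, and coefficients
below $10^{-6}$ reported as exact zeros.  The smoothing constant is
deliberately small: the bias of the smoothed solution grows like
$\sqrt{\varepsilon}$ per active penalty row, and $10^{-10}$ keeps the
LQA objective within about $10^{-6}$ relative of the independent
convex solution on random instances while the Cholesky factorization
remains well conditioned (an escalating-jitter fallback guards the
degenerate case of unpenalized rank-deficient systems).  Iterations
start from a ridge solution with penalty
$10^{-3}\,\mathrm{tr}(X^\top X)/(kP)$ — deterministic and never exactly
zero, which matters because the LQA weights are undefined at the
all-zero point.

A caveat of the reported-zero convention: a coefficient whose penalty
weight $w$ is very small is barely penalized by design, and its LQA
fixed point scales like $\sqrt{\varepsilon}/(\lambda_1 w^2)$, so at
extreme $\lambda_1$ only coefficients with non-negligible weights
collapse below the zero threshold.  This mirrors the model: edges
between genes with identical differential behavior are meant to
survive penalization.

**Verification oracle.** `fit_oracle()` solves the identical convex
program by ADMM on the splitting $z = D\beta$ with soft-threshold
updates — independently coded, sharing nothing with the LQA path — and
is used throughout the tests to certify solver correctness within
$10^{-4}$ relative objective error (measured agreement is around
$10^{-6}$).  A size guard restricts it to small instances.

**Cross-validation.** $(\lambda_1, \lambda_2)$ are chosen from the
default grids $\{0.05, 0.1, 0.5, 1, 1.5\}$ and
$\{0.1, 0.5, 1, 1.5, 2\}$ by 10-fold cross-validation on the stacked
rows, minimizing held-out mean squared prediction error.  Folds are
stratified by condition so every training split contains all $k$
blocks; an unstratified partition can orphan an entire condition.
Every condition therefore needs at least as many time points as folds
— with short series the fold count must be lowered (the package raises
an informative error).  Exact ties on the CV surface are broken toward
larger $\lambda_1 + \lambda_2$, preferring the sparser, more fused
model.  The fold assignment is drawn from a seed derived
deterministically from the run seed and the response gene ID, so
results do not depend on the order (or parallelization) of the
per-response fits.

## Network assembly and evaluation

Per response, every regulator with a non-zero coefficient in at least
one condition contributes an edge carrying its $k$ per-condition
coefficients.  The consensus coefficient is either the arithmetic mean
(`average`) or the coefficient of largest magnitude with its sign
(`max`, the default; on an exact magnitude tie the earlier condition
block is taken).  Edge weights are normalized to $|{\cdot}|$ divided by
the largest magnitude, sorted descending (ties broken lexicographically
by regulator then target for bit-reproducible output) and the top
$n$ retained (default 100,000, configurable for small networks).  The
regulatory type (activating/repressing) is the sign of the
pre-normalization consensus coefficient, which is preserved alongside
the normalized weight.

Evaluation against a signed gold standard treats every ordered
regulator-target pair of the universe (self-pairs excluded) as
scoreable; pairs not in the network score 0.  The threshold sweep is
grouped at distinct scores, which makes the trapezoidal AUROC equal the
Mann-Whitney probability that a random true edge outranks a random
non-edge with ties counted one half — the tie convention enforced by a
brute-force oracle in the tests.  AUPR uses step integration of
precision over recall.  TPR at a requested FPR (default 0.03) is read
from the step curve at the largest achieved FPR not exceeding the
request; an interpolating convention would differ only between steps.
The selector value is the normalized weight of the highest-ranked true
positive.  The OverallScore across data sets averages the geometric
means of the AUROCs and of the AUPRs.  For the regulatory-type report,
the true-negative denominator is taken as all non-gold ordered pairs of
the universe — a convention this package fixes explicitly since the
quantity is otherwise underdetermined.

## What the synthetic generator emulates — and what it does not

`simulate_truth()` plants a sparse signed network: each of 30 targets
receives 2 distinct regulators among 10 TFs, signs equiprobable,
effect magnitudes uniform on $[0.5, 2]$; each of the $k = 3$ conditions
perturbs a random 40% of the TFs with a constant shift of magnitude
2–4 (random sign).  `simulate_study()` builds log2-scale data: gene
baselines $\mathcal{N}(7, 1)$, smooth two-mode sinusoidal TF courses,
targets as the planted linear combination of the observed TF deviations
plus $\mathcal{N}(0, 0.3^2)$ noise, $N^i = 8$ time points per
condition and 4 control replicates of baseline plus noise.  The
constant perturbation shift drives the differential-expression
contrast (hence the penalty weights) while the smooth course provides
the within-condition variation the regression exploits; after
per-block centering the shift itself carries no regression signal,
which cleanly separates the two information channels.

These choices emulate the *shape* of multi-condition microarray stress
experiments, not their hardness: real data have correlated TF
profiles, unmodeled regulators, nonlinear and lagged kinetics,
condition-dependent regulation and heteroscedastic noise.  Recovery
results on the generator (AUROC $\ge 0.8$, $\ge 70\%$ sign agreement
in the test suite) therefore certify that the pipeline is correctly
assembled and can invert its own generative model — they do not
predict performance on biological data.  A mild saturating variant can
be emulated by transforming the generated treatment matrices before
analysis.

End-to-end runs in the test suite use 4 cross-validation folds rather
than the default 10: stratification requires every condition to
populate every fold, and an 8-point series cannot cover 10 folds.
This is a structural consequence of the generator's series length, not
a tuning choice.

## Degenerate inputs and edge cases

* A condition with fewer than two control replicates cannot support
  variance estimation; the loader directs the user to
  `supply_probabilities()`, which injects externally computed
  probability matrices (e.g., from a dedicated differential-expression
  pipeline) into the identical downstream path.
* Genes present in only some data sets are dropped with a warning
  (every regressor must exist in every block); genes with missing
  values are rejected at load time.
* An empty inferred network evaluates to AUROC 0.5 (all pairs tie at
  score zero) and selector value 0, each with a warning rather than an
  error.
* All-zero gene variances abort hyperparameter fitting with a
  descriptive error; isolated non-positive variances are excluded from
  the fit with a warning.

## Known limitations

* The fusion chain couples only consecutive condition pairs in load
  order; with many heterogeneous conditions an all-pairs or
  graph-guided coupling could be preferable but is out of scope.
* One $(\lambda_1, \lambda_2)$ pair is selected per response gene;
  sharing a single pair across all genes (a large speed-up noted in the
  field) is possible by fixing singleton grids.
* Coefficients are reported on the standardized scale; translating
  them back to raw-scale effects requires the stored per-block scale
  factors and is intentionally not done for ranking, which only uses
  relative magnitudes.
* The B statistic assumes exchangeable replicate noise and a single
  variance per gene per condition; array-weight or duplicate-spot
  refinements of the empirical-Bayes machinery are not implemented.
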