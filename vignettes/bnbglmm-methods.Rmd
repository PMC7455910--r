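---
title: "Bayesian negative binomial mixed models for clustered RNA-seq: methods and design"
author: "bnbglmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian negative binomial mixed models for clustered RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnbglmm)
```

## The problem

RNA-seq studies increasingly collect repeated measures: the same subject
sampled at several time points, paired tissues, or related individuals.
Counts from the same cluster are correlated, and tools that assume
independent samples pay for that assumption with inflated false positive
rates on between-subject comparisons or lost power on within-subject ones.
A second, subtler problem is that negative binomial (NB) tools typically plug
in a point estimate of the dispersion and then act as if it were known, so
their test statistics ignore a real source of uncertainty — a problem that is
worst exactly where RNA-seq lives, at small sample sizes.

`bnbglmm` addresses both issues with a per-gene Bayesian NB generalized
linear mixed model (GLMM) fit by Markov chain Monte Carlo. For gene $g$,
subject $i$ and observation $j$,

$$
Y_{gij} \sim \mathcal{NB}(\mu_{gij}, \alpha_g), \qquad
\log \mu_{gij} = X_{ij}\beta_g + Z_{ij} b_{gi} + \rho_{ij}, \qquad
b_{gi} \sim \mathcal{N}(0, \sigma^2_{gb}),
$$

with $\mathrm{Var}(Y) = \mu + \alpha_g \mu^2$, a fixed-effect vector
$\beta_g$ of length $p$, a subject-level random intercept $b_{gi}$ inducing
compound-symmetric within-subject correlation, and a per-sample offset
$\rho_{ij}$ (log size factor) absorbing sequencing-depth differences.
Because the dispersion $\alpha_g$ is a parameter with its own posterior, the
posterior of $\beta_g$ automatically carries dispersion uncertainty.

The current interface supports one random intercept per subject ($q = 1$) or
none ($q = 0$, a Bayesian NB GLM for independent samples). Random slopes and
nested random effects are out of scope.

## Priors

* $\beta_g \sim \mathcal{MVN}(M_g, T)$ with $T = \mathrm{diag}(49)$ —
  an sd of 7 on the log scale, effectively flat for fold changes. The first
  element of $M_g$ is $\log(\text{mean raw count of gene } g)$ and the rest
  are 0, i.e. the prior is centred on "no effects, one common mean".
  Non-zero prior means for effects are deliberately not offered as defaults.
* $\sigma^2_{gb} \sim \mathrm{InvGamma}(U, V)$ with $U = V = 0.01$.
  The density is parameterized as $x^{-(U+1)} e^{-V/x}$ (shape $U$, scale
  $V$); this convention matters for reproducing the Gibbs update and is
  stated here once and used everywhere.
* $\log \alpha_g \sim \mathcal{N}(A_g, B)$, with $(A_g, B)$ built
  empirically, below.

### The information-sharing dispersion prior

Per-gene dispersion cannot be estimated well from a handful of samples, so
the prior borrows strength across genes, in the same spirit as the
trend-based shrinkage of the major NB pipelines:

1. Scale counts to the median library size; compute per-gene mean $m_g$ and
   variance $v_g$ (denominator $S-1$) and the method-of-moments estimate
   $(v_g - m_g)/m_g^2$.
2. Regress $\log$ of the positive estimates on mean $\log(\mathrm{CPM})$
   with LOESS (span 0.75, degree 2; `surface = "direct"` so evaluation at
   arbitrary points is exact). Mean log CPM is computed as the mean of
   $\log(\mathrm{CPM} + 0.5)$; the pseudo-count keeps genes with zero counts
   in some samples finite and is the field's convention.
3. $A_g$ is the trend value at gene $g$'s mean log CPM — for *all* genes,
   including those whose own estimate was nonpositive; outside the fitted
   range the trend is clamped to its endpoint values.
4. $B = (k\tau)^2$ where $\tau$ is the residual sd of the LOESS fit and $k$
   (default 2) inflates the prior: the naive moments absorb fixed- and
   random-effect variability and therefore over-state dispersion, so the
   prior must admit smaller values than the estimates suggest. Smaller $k$
   is more conservative, larger more liberal; the influence fades with
   sample size. If $\tau = 0$ (degenerate flat trend) $B$ is floored at
   $(0.1k)^2$ to avoid a point mass.

At least 20 genes with strictly positive moment estimates are required;
otherwise the user must supply `A` and `B` directly.

## Posterior sampling

Each gene runs an independent chain (default 30,000 iterations, first 10%
discarded). Per iteration:

1. **Joint $(\beta_g, b_g)$ update** by Metropolis–Hastings with a one-step
   weighted-least-squares proposal: from the current state compute IRLS
   weights $w = \mu/(1 + \alpha\mu)$ and working response
   $z = (\eta - \rho) + (y - \mu)/\mu$; the proposal is Gaussian with
   precision $C'WC + P$ and mean $(C'WC+P)^{-1}(C'Wz + Pm_0)$, where
   $C = [X\,|\,Z]$, $P = \mathrm{blockdiag}(T^{-1}, I/\sigma^2)$ and
   $m_0 = (M_g, 0)$. The proposal is asymmetric, so the reverse-move density
   is recomputed at the proposed state and enters the acceptance ratio.
   One IRLS step per proposal (not iterated to convergence) keeps the
   proposal local while adapting to the posterior's curvature.
2. **Dispersion update** by a Gaussian random walk on $\log \alpha_g$.
3. **$\sigma^2$ update** by its exact inverse-gamma full conditional
   $\mathrm{InvGamma}(U + I/2,\; V + \tfrac12\sum_i b_{gi}^2)$ — a Gibbs
   draw, always accepted.

Design choices the literature leaves open, fixed here once:

* **Initialization**: intercept at $\log \bar y$ minus the mean offset,
  other coefficients and random effects at 0, $\log\alpha$ at $A_g$,
  $\sigma^2$ at 0.1 — cheap values inside the prior bulk.
* **Step-size adaptation**: the random-walk sd starts at 0.5 and is tuned by
  Robbins–Monro towards 40% acceptance *during burn-in only*, then frozen,
  so the retained chain is a fixed-kernel Markov chain with the right
  invariant distribution.
* **Numerical safeguards**: linear predictors are clamped at $\pm 30$; a
  Cholesky failure of the proposal precision is retried once with a
  $10^{-8}$ diagonal jitter and otherwise the move is rejected; a gene with
  more than half its iterations numerically unusable is marked failed.
* **Reproducibility**: each gene's RNG stream is seeded from a hash of the
  master seed and the *gene identifier*, so results are bit-identical across
  worker counts, input orderings and gene subsets.

The per-gene kernel is compiled (Rcpp); the regression block exploits the
arrow structure that unit subject indicators give the WLS normal equations,
so cost per iteration grows linearly, not quadratically, in the number of
subjects. Chains are summarized gene-by-gene and discarded, keeping memory
flat in the number of genes.

## Inference

Contrasts are linear combinations $c'\beta_g$ evaluated draw-wise. For each
gene and contrast the package reports the posterior median, the equal-tailed
95% credible interval, and the **contour probability**

$$
p_c = \min\left(1,\ \frac{2}{R}\,\#\{j : \theta^{(j)} \hat\theta < 0\}\right),
$$

twice the share of draws on the opposite side of zero from the posterior
median $\hat\theta$ — the Bayesian analogue of a two-sided p-value. Draws
exactly at zero never count as opposite (strict inequality), so a fully
one-sided chain yields $p_c = 0$; the resolution is $2/R$ (about
$7.4\times10^{-5}$ at the default 27,000 retained draws), and longer chains
are the only way to refine it. A perfectly symmetric chain with median
essentially zero degenerates to $p_c = 0$; the implementation warns when it
detects that edge case. Under null simulations the $p_c$ distribution across
genes is close to uniform, which is what licenses the final step: a
Benjamini–Hochberg adjustment of the contour probabilities, applied per
contrast across genes. Genes flagged as convergence failures are reported
with raw summaries but excluded from the BH pool by default (adjusted value
`NA`), since pooling unreliable chains would contaminate the ranking.

## Convergence screening

Two screens per gene, combined into one flag:

* **Acceptance rates** of the regression block and the dispersion walk over
  the retained iterations (the always-accepted Gibbs step is ignored); a
  rate below 10% fails the gene.
* **Geweke mean-equality tests** comparing the first 20% to the last 50% of
  the retained chain, for every $\beta$ element, $\log\alpha$ and
  $\log\sigma^2$ (the log scale symmetrizes the variance chain). The
  variance of each segment mean uses the spectral density at frequency zero
  estimated from an AR fit. This is the classical form of the diagnostic:
  with the plain two-sample (iid) variance the statistic is overdispersed on
  autocorrelated chains — in our null runs it flagged the great majority of
  perfectly healthy genes — while the spectral form reduces to the iid
  version exactly when draws are independent. Geweke p-values are BH
  adjusted across genes separately per parameter; any adjusted value below
  0.05 fails the gene.

On simulated paired designs at $n = 10$ per group with default settings,
well under 1% of genes are flagged (the acceptance suite checks this).

## The simulation module

`simulate_dataset()` generates the paired two-group design used throughout
the validation suite: $n$ subjects per group, each with a baseline and a
follow-up sample, and per gene

$$
\log \mu = \beta_{g0} + \beta_{g1} I_{\text{trt}} + \beta_{g2} I_{\text{fup}}
 + \beta_{g3} I_{\text{trt}} I_{\text{fup}} + b_{gi},
$$

with both main effects zero for every gene and the interaction $\beta_{g3}$
zero for 80% of genes and $\pm$ES for 10% each; ES is gamma with mode
$\log 2$ and sd 0.5 (the mode/sd system is solved in closed form by
`es_gamma_params()`). The three reported contrasts — between-subject
($\beta_{g1}+\beta_{g3}$), within-subject ($\beta_{g2}+\beta_{g3}$) and
interaction ($\beta_{g3}$) — then share one truth labelling.

The per-gene nuisance parameters $(\beta_{g0}, \alpha_g, \sigma^2_{gb})$
come from a documented parametric source chosen to look like bulk RNA-seq
from human cohorts: mean $\log(\mathrm{CPM}) \sim \mathcal{N}(\log 16,
1.5^2)$ truncated to $[\log 1, \log 4000]$ and mapped to counts through a
nominal 25-million-read library; $\log \alpha_g = -1.8 - 0.3(\log\mathrm{CPM}
- \log 16) + \mathcal{N}(0, 0.6^2)$, so the mean–dispersion trend that the
empirical prior exploits is present; and $\sigma^2_{gb} \sim
\Gamma(\text{shape }2, \text{scale }0.25)$, putting most genes'
between-subject sd in the 0.3–1 range on the log scale. All three are
replaceable via `parameter_source`. Library sizes are equal by default
(offsets 0), with optional lognormal depth variation. What the generator
does *not* emulate: empirical mean–dispersion relationships from any
specific cohort, gene–gene correlation, outlier samples, or library-
composition artefacts — so passing tests demonstrate internal correctness
and calibration under the model, not robustness to real-data pathology.

`evaluate_testing_characteristics()` computes type-1 error on null genes at
unadjusted thresholds $\{10^{-4}, 0.01, 0.05, 0.1\}$ and FDR and power at
BH-adjusted thresholds $\{0.01, 0.05, 0.1\}$; the FDR of an empty discovery
set is defined as 0. Per-dataset tables are averaged unweighted by
`run_simulation_study()`.

## Preprocessing defaults

* **Size factors**: median-of-ratios against the geometric-mean reference,
  computed on genes with no zero counts, with the log factors used as model
  offsets. The median is taken on the log-ratio scale (exponentiated), which
  is the convention of the reference implementation of this normalization;
  for an odd reference set it is identical to the raw-ratio median.
* **Filtering**: a gene is kept iff CPM $> 1$ (strict) in at least $m$
  samples, with CPM computed on the unfiltered matrix and $m$ defaulting to
  the size of the smallest cross-classified cell of the categorical design
  covariates.
* Counts must be raw integers; pre-normalized matrices are rejected because
  both the NB likelihood and the size-factor estimator assume counts.

## Validation scales

The shipped test and acceptance runs are scaled to desk size as the
package's own validation design: grid-exactness on single genes; 200 genes
at $n = 10$ for parameter recovery and credible-interval coverage; 2,000
null genes at $n = 5$ (10,000 iterations) for calibration; 4 datasets of
2,000 genes for FDR control; 500 genes at $n = 10$ with full-length chains
for the convergence-failure rate. Monte Carlo tolerances are stated in the
tests as multiples of the relevant standard errors.

## Known limitations

* One random intercept only; no random slopes, nested clusters or
  autocorrelation structure.
* Contour probabilities cannot resolve below $2/R$; extremely small
  p-values are reported as 0 and tie at the bottom of the BH ranking.
* The Geweke screen tests mean stationarity between chain segments; it has
  no power against pathologies that leave segment means equal.
* The BH step treats contour probabilities as p-values; this is motivated
  by their near-uniform null behaviour, not by a formal guarantee.
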