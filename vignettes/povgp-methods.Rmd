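---
title: "Methods: multi-source GP small-area estimation in povgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-source GP small-area estimation in povgp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(povgp)
```

## The estimation problem

Commune-level poverty statistics are expensive to measure directly: census
microdata arrive on multi-year cycles, while auxiliary signals — aggregated
mobile-phone behaviour, environmental and infrastructure layers — are cheap
and frequent but only indirectly related to deprivation. `povgp` treats
each auxiliary source as an independent predictor of a commune-level
target (typically the multidimensional poverty index MPI, its headcount H
or intensity A), quantifies each source's predictive uncertainty, and
fuses the sources per commune by inverse variance. This vignette documents
the model, its assumptions, the tunable parameters, the synthetic data
generator, and the numerical and design choices, so that a practitioner
can judge what the package's validation does and does not demonstrate.

## Model and assumptions

For one source, commune $i$ with feature vector $x_i$ and projected-km
centre $s_i$:

$$y_i = \beta^\top x_i + f(x_i, s_i) + \varepsilon_i,\qquad
\varepsilon_i \sim N(0, \sigma_n^2),\qquad
f \sim \mathrm{GP}(0, k),$$

$$k\big((x,s),(x',s')\big) = \sigma_f^2
\exp\!\Big(-\tfrac{\lVert x-x'\rVert^2}{2\ell^2}\Big)
\exp\!\Big(-\tfrac{\lVert s-s'\rVert^2}{2\ell_s^2}\Big).$$

Assumptions worth making explicit:

* **Additivity and Gaussianity.** The target is a noisy sum of a linear
  trend and a smooth residual surface; both the GP and the noise are
  Gaussian. Bounded targets such as MPI $\in [0,1]$ are modelled on the
  raw scale — predictions near the boundary can leave $[0,1]$ and are not
  clipped.
* **A single shared feature length-scale** (isotropic kernel). This is
  only meaningful if features are on a common scale, which is why the fit
  standardizes every column to zero mean and unit variance before both
  the linear term and the kernel. A per-dimension length-scale (ARD) is
  out of scope.
* **Space enters the kernel, not the mean.** Spatial coordinates are
  never part of $\beta$; spatial structure is modelled entirely as
  correlated residual (the kriging view).
* **No intercept in the printed model.** Since the features are centred,
  $\beta^\top x$ has mean zero, so the package centres the target as well
  and restores the stored centre at prediction time. Without this, the
  prior mean would be systematically biased for any target that does not
  happen to average to zero.

The posterior at a new commune is Gaussian with

$$\bar y_* = \beta^\top x_* + k^\top (K+\sigma_n^2 I)^{-1}(y - X\beta),
\qquad
\sigma_*^2 = k_* - k^\top (K+\sigma_n^2 I)^{-1} k + \sigma_n^2.$$

The residual form $y - X\beta$ in the mean is the one consistent with the
nonzero prior mean $E[y] = X\beta$; a variant that conditions on $y$
directly is inconsistent with that prior and is not implemented. The
predictive variance depends only on inputs — replacing every training
target leaves it unchanged (asserted in the tests) — and is bounded below
by $\sigma_n^2$.

## Fitting: penalized marginal likelihood

All parameters are estimated by maximizing

$$J(\beta,\ell,\ell_s,\sigma_n^2,\sigma_f^2)
 = \log p(y\,|\,X) - \big(\alpha\lambda \lVert\beta\rVert_2^2
 + (1-\alpha)\lambda \lVert\beta\rVert_1\big),$$

where $\log p(y|X)$ is the Gaussian marginal likelihood computed through a
Cholesky factorization (never an explicit inverse). Note the elastic-net
convention: **$\alpha$ multiplies the L2 term** and $1-\alpha$ the L1
term, so $\alpha = 1$ is pure ridge and $\alpha = 0$ pure lasso.

Numerical choices:

* **Non-smooth L1.** $|\beta_j|$ is smoothed as
  $\sqrt{\beta_j^2+\epsilon^2}$ with $\epsilon = 10^{-8}$ inside the
  optimizer only; reported objectives use the exact penalty. The smoothing
  error is $O(\epsilon \lambda d)$ and irrelevant at any useful tolerance;
  coefficients driven to "zero" by large $\lambda$ land at magnitudes
  comparable to $\epsilon$, which is why `feature_importance()` flags
  pruned features by a magnitude threshold (default $10^{-4}$) rather
  than exact zeros.
* **Positivity.** $\ell, \ell_s, \sigma_f^2, \sigma_n^2$ are optimized on
  the log scale.
* **Optimizer.** `stats::optim` with analytic gradients (the standard
  trace identities for kernel hyperparameters; gradients are verified
  against central finite differences in the tests). The default method is
  BFGS; nonlinear conjugate gradients (`method = "CG"`) is available and
  is the historical choice for this objective, but BFGS reaches the same
  optima in far fewer function evaluations on problems of this size
  (a few hundred communes), so it is the default. If no restart reports
  convergence the fit warns and returns the best iterate — never
  silently.
* **Restarts and initialization.** Default 3 seeded restarts. The first
  starts from a ridge solve for $\beta$, median pairwise distances for
  $\ell$ and $\ell_s$, and an even split of the residual variance between
  $\sigma_f^2$ and $\sigma_n^2$; later restarts perturb the length-scales
  over roughly two orders of magnitude. The returned objective never
  falls below its value at initialization.
* **Conditioning.** The kernel matrix receives an escalating diagonal
  jitter ($10^{-8}$ to $10^{-4}$ of the mean diagonal) before
  factorization; failure after maximal jitter raises an error naming the
  variance settings.

Parameter defaults: $\alpha = 0.5$; $\lambda = 0.1$ as a fixed default,
with `lambda = NULL` selecting among a 5-point grid
$10^{-2} \ldots 10^{1}$ by inner 5-fold cross-validation on the training
split (the grid search refits the model $5\times5$ times, so routines
that refit per split, such as `run_cv()`, typically pass a fixed
$\lambda$).

## Inverse-variance fusion

Two source posteriors $N(m_c, \sigma_c^2)$ and $N(m_e, \sigma_e^2)$ for
the same commune combine as a two-component mixture with weights
$w_c \propto 1/\sigma_c^2$. The mixture's exact moments are

$$E[y] = w_c m_c + w_e m_e, \qquad
\mathrm{var}[y] = w_c\sigma_c^2 + w_e\sigma_e^2
 + w_c w_e (m_c - m_e)^2.$$

The disagreement term means the fused variance may exceed both component
variances — by design: sources that contradict each other should not
yield an overconfident fusion. Variances are floored at $10^{-12}$ before
inversion (the weights are undefined at exactly zero variance); if both
fall below the floor the weights are set equal with a warning. Communes
present in only one source pass through unfused with a provenance flag.
The fused point estimate is the mixture mean (not the best-source mean);
`best_source_map()` reports the lower-variance source per commune, with
exact ties labelled `"tie"`.

## Alkire–Foster statistics

Households are scored as $c_i = \sum_d w_d\,\mathrm{dep}_{i,d}$ over 10
binary indicators (education and health indicators weigh $1/6$ each,
standard-of-living indicators $1/18$; each dimension sums to $1/3$
exactly). A household is poor iff $c_i > \theta$ — strictly, so a
household at exactly $\theta = 0.3$ is not poor. Per commune, $H$ is the
poor share, $A$ the mean score among the poor (undefined, reported `NA`,
when no household is poor — MPI is then 0), and $\mathrm{MPI} = H\times A$.
Cutoff sensitivity is examined with `theta_sweep()` over
$\theta = 0.2, 0.25, \ldots, 0.75$; $H$ is non-increasing in $\theta$ by
construction.

Two conventions the underlying methodology leaves open:

* **Missing indicators.** A household's score is computed over observed
  indicators with weights renormalized, provided at least $2/3$ of total
  weight is observed; otherwise the household is dropped (common MPI
  practice). Per-indicator commune proportions divide by households with
  that indicator *observed*, not the raw household count.
* **Sampling weights.** Households are equally weighted; the typical
  input is an evenly drawn census sample.

## CDR aggregation

* **Home antenna**: per subscriber-month, the antenna with the most
  events in the nocturnal window $[19{:}00, 07{:}00)$ — half-open, so an
  event at exactly 07:00 is daytime. The yearly home is the modal monthly
  home. All modal ties break to the lexicographically smallest antenna id
  (deterministic and order-independent).
* **Retention**: a month qualifies when it has $\ge 5$ interactions and a
  defined monthly home; retention requires $\ge 6$ qualifying months —
  the natural conjunction of a minimum-activity rule and "active at least
  half the year". Features are pooled at the *yearly* home; monthly homes
  are computed but the year-modal antenna anchors the aggregation.
* **Features**: a 13-feature representative set per subscriber-month
  (activity counts and days, call/text ratio, interevent-time mean/SD in
  seconds, contact count and entropy, nocturnal and initiated fractions,
  antenna count and entropy, radius of gyration in km). Entropies are in
  natural log. Months with a single event have undefined interevent
  statistics; these are emitted as `NA` and *excluded* from antenna means
  rather than imputed as zero.
* **Aggregation**: antenna means over retained subscribers, then commune
  values as overlap-weighted antenna means with
  $w_{c,a} = \mathrm{Area}(c \cap a)/\mathrm{Area}(a)$, renormalized over
  antennas that carry data; communes with no covered antenna get `NA`
  and are listed in a coverage attribute.

All geometry is planar, in projected km; real inputs must be projected
(e.g. equirectangular) before entry. Polygon machinery (bounded Voronoi
tessellation by half-plane intersection, convex clipping) is implemented
in the package and validated against hand-constructed rectangle oracles
and partition-of-unity identities.

## Spatial cross-validation

Random 10-fold CV overstates performance when deprivation is spatially
autocorrelated: a held-out commune usually has trained neighbours. The
spatial protocol instead samples a region, then a seed commune within it,
and trains on every commune within distance $d$ of the seed, growing $d$
from 100 km in 50 km steps until the training set reaches its floor —
225 communes on the 552-commune geography, $\lceil 0.4\,n\rceil$
otherwise (the printed absolute floor and the 40% rule disagree slightly
at $n = 552$; the absolute value wins there). Everything else is
evaluation. Degenerate draws where the radius swallows the whole map are
resampled (capped). Hyperparameters are refitted within every training
split — anything else leaks evaluation information into the fit. Metrics
(Pearson, Spearman on mid-ranks, RMSE) are pooled over each repeat's
evaluation set and summarized as mean (SD) over repeats. On a square
geography a few central communes can fall inside every training disc;
`run_cv()` checks evaluation coverage and warns when a commune is never
evaluated.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *statistical structure* the model assumes:

* a commune tessellation (Voronoi cells of uniform seeds, clipped to a
  square) with the smallest cells flagged urban and k-means-contiguous
  regions; defaults mirror the target geography (552 communes, 121
  urban, 14 regions, 700 km extent);
* a latent spatially autocorrelated deprivation field (GP with
  $\ell_s = 50$ km by default);
* two feature sources linked to that field — either a forward draw
  `generate_latent_field()` where $y = X\beta_{true} + f + \varepsilon$
  exactly (each component returned, so tests can verify the
  decomposition bit-for-bit), or `generate_multisource()` where both
  sources' informative columns load linearly on a shared field with
  independent noise;
* household censuses whose indicator probabilities follow the latent
  field through a logistic link, with an optional shared-frailty
  mechanism for within-household correlation;
* CDR event logs with known ground-truth homes: Poisson monthly event
  counts (default mean 25), a nocturnal share (default 0.35), nocturnal
  events at the home antenna with probability 0.9, daytime events split
  between home and the three nearest antennas, Zipf-weighted contact
  pools, and urban communes three times denser in subscribers.

One antenna sits at each commune's Voronoi *generator point* — the point
whose cell is exactly the commune — plus extra antennas at random interior
points of urban communes. Placing the base antenna at the polygon
centroid instead would make the antenna tessellation mismatch commune
boundaries everywhere by construction, a geometric artifact with no
analogue in real antenna layouts.

Deliberately **not** emulated: real geography and population rasters,
calibrated telecom behaviour (event volumes, mobility, market share),
raster-derived environmental features (the linear+GP link in the
generator is the model's own assumption, not an empirical
data-generating truth), questionnaire coding of indicators, or survey
design. Consequently, passing tests demonstrate *correctness of the
machinery and recoverability under the assumed model* — they do not
certify accuracy on real CDR or census data, whose headline numbers
require proprietary inputs.

## Problem sizes and seeds

Everything is seeded and bit-reproducible (`with_seed` isolates the RNG;
derived seeds stay within 32-bit range). The validation suite exercises:
exact-oracle GP equivalence on 50 random instances ($N\le20$, $d\le5$,
tolerance $10^{-8}$); mixture moments against $10^6$-draw stratified
Monte-Carlo samples (3 SE) plus exact worked examples; Alkire–Foster
exactness against an explicit-loop oracle on censuses of up to 50
households; Voronoi partition identities at $10^{-6}$; home recovery on a
25-commune log; coefficient-support and length-scale recovery on a
300-commune forward draw with 25 spatial-CV repeats; fusion quality on a
350-commune two-source draw with 25 repeats; and the 225-commune training
floor over 250 splitter repeats at full 552-commune size. These sizes
were chosen so the whole suite runs in well under a minute of compute per
criterion on a single core; full-scale studies would use 250 CV repeats
throughout.

## Known limitations

* Exact GP algebra is $O(n^3)$; fine for hundreds of communes, not for
  tens of thousands (no sparse approximations).
* Gaussian likelihood on bounded indices; no link function.
* Fusion handles exactly two sources (the generalization is mechanical
  but untested here), and reports only the mixture's first two moments.
* The isotropic feature kernel makes the nonlinear term weak when many
  irrelevant features dilute the distance metric; the elastic net prunes
  the linear term but not the kernel metric.
* Conversation-threading features (response delays) are not computed —
  reconstructing dyadic conversations from an event log requires
  assumptions the aggregation deliberately avoids.
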