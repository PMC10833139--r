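---
title: "Models and methods in mvintegrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mvintegrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvintegrate)
```

This vignette is the package's own account of its statistical machinery: the
models and their assumptions, the tunable parameters and their defaults, the
numerical choices made where the design was genuinely open, what the
synthetic generators do and do not emulate, and the known limitations. It
states no empirical result that the test suite does not itself compute.

## The problem

Two or more data modalities ("views") — proteomics, transcriptomics,
clinical measurements — are observed on the same $n$ samples, with
$p_d \gg n$ features in view $d$. Two complementary goals:

* **Unsupervised**: find per-view linear combinations whose scores are
  maximally correlated across views, using few features (sparse CCA).
* **Supervised**: find per-view sparse directions that simultaneously
  separate known classes within each view and keep the views' scores
  associated (sparse integrative discriminant analysis).

Both produce low-dimensional per-sample scores that can then be related to a
clinical outcome by ordinary regression.

## Data model and filtering

All tables are samples-in-rows, features-in-columns (the natural layout when
$n \ll p$). Views are aligned by intersecting sample identifiers, reordered
to the first view's order, with a warning listing dropped samples —
real multi-omics tables rarely match exactly, so an error would be
unhelpful. Missing values abort assembly by default; an explicit
`na_action = "impute"` mean-imputes per feature. Upstream omics-specific QC
(batch correction, library-size normalization) is assumed done elsewhere.

Supervised filtering tests one feature at a time: simple linear regression
slope (continuous outcome), single-predictor logistic regression Wald z
(binary), Welch $t$ (binary), or Kruskal–Wallis (any number of groups).
Adjusted p-values (Benjamini–Hochberg by default, $\alpha = 0.05$) drive the
keep decision. Three conventions worth stating:

* the effect column holds the difference of group means for $t$/KW — equal
  to the log2 fold change exactly when the matrix is on the log2 scale —
  and the model coefficient for linear/logistic; re-taking log2 inside the
  test would be ill-defined after centering or scaling;
* a feature that perfectly separates the classes makes the logistic MLE
  diverge; `glm` often "converges" silently with a gigantic standard error,
  so separation is detected directly (disjoint class ranges, or the
  fitted-probability warning) and the feature is excluded with a missing
  p-value rather than a meaningless one;
* standardization, when requested, happens before testing; $t$ and KW are
  invariant to it, linear/logistic coefficients change scale but not their
  p-values.

Unsupervised filtering ranks by unbiased sample variance or by the type-7
(linear-interpolation) IQR — a fixed quantile convention is needed for
reproducible rankings — keeping the top `ceiling(keep_fraction * p)`, ties
resolved by column order. The log2 option computes $\log_2(x + 1)$ so that
zero counts survive.

Every transform and every filter is estimated on the training data only.
The transform record (means, standard deviations, kept columns, in order) is
sufficient to replay the mapping on new data; `apply_filter()` and
`preprocess(train_params =)` never re-estimate anything, so test-set column
means are generally nonzero after centering — that is the contract.

## Sparse CCA by soft-thresholded updates

With column-centered views, the working cross-covariance is
$S_{12} = X_1^\top X_2 / (n-1)$. The nonsparse directions are its leading
singular triplets $(\tilde a_k, \tilde b_k, d_k)$; treating within-view
covariances as identity is the standard high-dimensional simplification
(estimating and inverting $p_d \times p_d$ covariances at $n \ll p$ is
hopeless, and diagonal working covariances make the sparsification
subproblem separable). Each direction is sparsified by

$$\min_u \|u\|_1 \quad \text{s.t.} \quad \|c - \rho u\|_\infty \le \tau,$$

with $c = S_{12} \tilde b$ (view 1) or $S_{12}^\top \tilde a$ (view 2) and
$\rho = d_k$. Because the constraint is coordinate-wise, the exact solution
is soft-thresholding, $u_j = \mathrm{sign}(c_j)\max(0, |c_j| - \tau)/\rho$
— the test suite verifies this against an independent linear-programming
solver. Nonzero solutions are rescaled to unit norm, so loading magnitudes
are comparable within a component and "larger weight = larger
contribution" is meaningful. The two views' updates alternate until the
largest loading change falls below $10^{-6}$ (cap 50 iterations, warning on
cap).

**Tuning.** Each view's threshold grid has 10 log-spaced values from 5% to
95% of $\max_j |c_j|$ at the first iteration — bracketing "all selected"
to "almost none selected". Five-fold cross-validation scores every pair by
the mean held-out absolute correlation of the two score vectors. CV
estimates are noisy, so "prefer the sparser model on ties" is implemented
as the one-standard-error rule (the glmnet convention): among pairs within
one standard error of the best mean, the sparsest (largest thresholds) wins.
An exact-equality tie rule would never fire in practice and leaves the
selection at the mercy of CV noise on the flat part of the correlation
curve, where solutions are unnecessarily dense.

**Multiple components.** After component $k$ the cross-covariance is
deflated with the *nonsparse* triplet,
$S_{12} \leftarrow S_{12} - d_k \tilde a_k \tilde b_k^\top$ (Hotelling
deflation), keeping successive components orthogonal in the working metric
regardless of how aggressively each was sparsified. Inside cross-validation
the fold-level $S_{12}$ is deflated with the full-training-data triplets of
the earlier components; re-estimating the deflation per fold would let the
folds disagree about what "component 2" means. Thresholds are re-selected
per component. The per-component reported `maxcorr` is the absolute Pearson
correlation of the training scores; it is reported in fitted order but not
forced to be monotone.

**Sign convention.** The largest-magnitude entry of each left singular
vector is made positive (flipping its partner in step), so results are
reproducible and flipping the sign of one input column flips only the
corresponding loading entries.

## Outcome models on canonical variates

`fit_outcome_model()` regresses the outcome on the score columns
$U_1..U_K, V_1..V_K$ (plus optional covariates, unpenalized) *post hoc*:
the representation is learned without the outcome, then related to it. Only
canonical links are offered (identity, logit, log) — mirroring the
four-family interface — and survival uses a Cox partial-likelihood fit with
the Efron tie approximation (the standard default) and no intercept.
Binomial label metrics threshold the predicted probability at 0.5; the
threshold is deliberately not tunable, and the rank-based AUC (Mann–Whitney
with midrank ties) is reported alongside so the threshold choice is not
load-bearing.

## Sparse integrative discriminant analysis

For view $d$, with between-class scatter
$S_b^d = \sum_k (n_k/n)\, m_k m_k^\top$ (class means of centered data) and
cross-covariances $M_{dj} = X_d^\top X_j/(n-1)$, the working matrix is

$$A_d = c\, S_b^d + \frac{1-c}{D-1} \sum_{j \ne d} M_{dj} \Gamma_j
\Gamma_j^\top M_{dj}^\top .$$

The balance weight $c \in (0, 1]$ defaults to 0.5 — equal weight on
separation and association; $c = 1$ with identical views reduces to sparse
LDA (a reduction the tests verify). The algorithm alternates over views:
top-$q$ eigenvectors of $A_d$ ($q = K - 1$, the classical LDA bound; the
between-class scatter has rank at most $K-1$), each column soft-thresholded
via the same SELP step with $c$-vector $A_d \tilde\gamma_l$, $\rho$ the
eigenvalue, and $\tau = \lambda_d$. Iteration stops when the relative
objective change $\sum_d \mathrm{tr}(\Gamma_d^\top A_d \Gamma_d)$ falls
below $10^{-4}$ (cap 20, warning on cap). A column may threshold to zero —
that happens legitimately when class means are collinear and the
discriminant space has rank $< q$ — but a view losing *all* columns
invalidates the candidate threshold.

$\lambda_d$ is selected by class-stratified five-fold CV on the held-out
nearest-centroid misclassification rate, with the same one-standard-error,
sparsest-on-ties rule. With two views the full grid product (8 × 8
log-spaced candidates) is scored; with three or more views a single shared
threshold is tuned to keep the candidate count linear — the spec's
"per-view over a shared grid" reading, restricted for tractability.
If the winning threshold empties a support on the full-data refit (fold and
full-data eigen scales differ slightly), the next candidate is tried instead
of aborting.

Classification projects each view onto its loadings, sums squared distances
to the per-view class centroids, and takes the arg-min class (ties to the
lowest label). Covariates, when requested, join as an extra view with
$\lambda = 0$ that is never penalized — they are always retained, and no
claim is made that they are "selected".

**Networks.** `fit_sidanet()` replaces the eigen-step with the generalized
problem $A_d \gamma = \eta (I + \kappa L_d) \gamma$, where $L_d = I -
D^{-1/2} A D^{-1/2}$ is the normalized Laplacian (isolated nodes zeroed, so
an empty graph gives $L = 0$). Directions that vary across connected
variables are shrunk, favoring connected, similarly-behaving features.
$\kappa$ defaults to 1; how the Laplacian enters is a gap-filling choice —
the generalized-eigenvalue form is the standard way to impose a quadratic
smoothness penalty in an eigenproblem, and it reduces *exactly* (bit for
bit, same code path) to the plain fit at $\kappa = 0$ or an empty network.

**On the reported training correlation.** The model records the mean
pairwise absolute correlation of the first score columns on the training
data. Like any in-sample quantity after selection, it is optimistically
biased: on pure-noise views it concentrates near the noise ceiling
$\approx (\sqrt{p_1} + \sqrt{p_2})/\sqrt{n}$ rather than 0, and grows with
$p$. Held-out correlation is the honest null measure; the property tests
check the training quantity only at modest $p$ and check held-out behavior
separately.

## Synthetic generators: what a green test establishes

`generate_selp_data()` draws a single latent factor $Z \sim N(0,1)$ per
sample and sets $X_d = Z w_d^\top + E_d$ with $w_d$ the equal-weight unit
vector on the first $s_d$ features and independent $N(0, \sigma^2)$ noise.
Equal weights ($1/\sqrt{s}$) make support recovery symmetric and tolerances
clean; random weights are available but off by default. The population first
canonical correlation is $1/(1+\sigma^2)$ — the default $\sigma^2 = 0.25$
gives 0.8 — and a binary outcome $\mathbf 1(Z + \varepsilon > 0)$ supports
the prediction tests.

`generate_sida_data()` places class $k$'s mean in view $d$ at
$\delta_k u_d$ with $\delta_k = (k - (K+1)/2)\Delta$, adds a shared latent
term $\psi Z u_d^\top$ across views, and independent noise. The same $u_d$
carries both the discriminant and the association signal, so the joint
objective has a single well-defined target. For $K = 2$ the per-view Bayes
error along $u_d$ is $\Phi(-\Delta/(2\sqrt{\psi^2 + \sigma^2}))$ and the
within-class cross-view correlation of the $u_d$-projections is
$\psi^2/(\psi^2+\sigma^2)$. Note that permuting the *labels* does not make
the views independent: the true class assignment remains a shared latent
factor in the features. A genuine null requires $\Delta = 0, \psi = 0$.

These generators emulate *structure* — sparse association and
discrimination with known supports — not omics realism: marginals are
Gaussian, features are exchangeable outside the support, there is no
heteroscedasticity, no batch structure, no count overdispersion. A green
test establishes that the algorithms recover planted low-rank sparse signal
at realistic $n/p$; it says nothing about robustness to real-data
pathologies, which the filtering stage is meant to blunt.

`generate_survival_from_scores()` draws exponential event times with rate
$\exp(X\beta)$ and independent exponential censoring whose rate is solved
numerically so the expected censored fraction matches the request.

## Numerical and interface choices

* Rounding in stratified splits is half-away-from-zero (base R rounds half
  to even), with the total's rounding residue absorbed by the largest class
  and every multi-member class retaining at least one test sample.
* All randomness (splits, folds, generators, UMAP) flows from explicit
  integer seeds; helper code saves and restores the caller's RNG state, so
  library calls do not perturb user scripts.
* Model files are a native-serialization archive with a manifest (format
  tag, format version, package version, model class): bit-exact numeric
  round-trip is the contract, and a version newer than the reader refuses
  to load.
* $-\log_{10}(p) = \infty$ is capped at 300 in volcano tables, with a flag.
* Relevance-network edges are direct empirical Pearson correlations between
  the model-selected variables of the two views, kept at $|r| \ge$ cutoff
  (default 0.5, a user parameter); positive edges are tagged solid, negative
  dashed. Biplot arrows use the correlation-biplot convention — the arrow
  for a variable is its correlation with the two plotted score axes — which
  bounds arrows to the unit disk and makes them testable; the between-view
  biplot uses view 1's axes by default with `axes_view = 2` as the symmetric
  alternative.
* UMAP is delegated to uwot (single-threaded for determinism); the CLI
  accepts YAML or JSON configs (identity handlers keep YAML-1.1
  boolean-like keys such as `n` intact).

## Limitations

Sparse CCA is strictly pairwise (two views); multi-view association with an
outcome is the discriminant model's job. No kernel or nonlinear variants, no
longitudinal structure, no subtype discovery. The Poisson and survival
families have no performance-report counterpart (by design, matching the
binomial/gaussian report surface). The discriminant CV with $D > 2$ views
shares one threshold across views. Outcome models are unpenalized
maximum-likelihood fits and assume $n$ exceeds the (small) number of score
and covariate terms.
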