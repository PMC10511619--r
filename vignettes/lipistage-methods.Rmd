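---
title: "Staging colorectal cancer from plasma lipid panels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging colorectal cancer from plasma lipid panels: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The modelling problem

A plasma lipidomics study of colorectal cancer (CRC) produces a samples ×
features intensity table — a few hundred annotated lipid peaks over a few
dozen patients — together with clinical metadata: disease group
(cancer-free CFI, staged CRC, liver-metastatic CLM), CRC stage, chemokine
concentrations, ternary gene-mutation statuses and survival endpoints.
`lipistage` implements the analysis such a study needs:

1. **Ordinal coding.** Disease severity is coded as an integer and treated
   as a regression target: CFI 0 / CRC 1 / CLM 2 in the three-group
   scenario; CFI 0 and stages I–IV as 1–4 in the staging scenario; CFI 0
   vs merged disease 1 in the multi-omics scenario. Regressing on ordinal
   codes presumes biomarkers shift monotonically with severity, which is
   the biological rationale for the design; it also makes the ±1-stage
   tolerance accuracy a natural error metric.
2. **Sparse panel selection** by MLR-EM, a Laplacian-prior linear
   regression solved by expectation–maximization.
3. **Non-linear prediction** by a Bayesian-regularized neural network
   (BRANN) trained on the MLR-selected panel only.
4. **Evaluation** on a stratified 20% test split via truth tables, exact
   and tolerance accuracy, r² and RMSE.
5. **Survival comparison** across disease groups (Kaplan–Meier, log-rank).

All computation lives in the package (`R/`); the `analysis/` scripts are
thin narrative drivers over it, and the synthetic-cohort generator stands
in for patient data everywhere.

# MLR-EM: sparse linear regression by iteratively reweighted ridge

With z-scored columns $X$ and centred response $y$, the Laplace
(double-exponential) prior on weights is handled by the standard
majorize–minimize/EM bound, giving the iteration

$$\left(\tfrac{1}{n}X^\top X + \beta D^{(t)}\right) w^{(t+1)} =
  \tfrac{1}{n}X^\top y, \qquad
  D^{(t)} = \mathrm{diag}\!\left(\frac{1}{\max(|w_i^{(t)}|,\ \varepsilon)}\right),$$

with $\varepsilon = 10^{-9}$ guarding the division. Features whose weight
falls below `prune_tol` ($10^{-6}$ on the standardized scale) leave the
active set permanently. The fit is initialized at the deterministic ridge
solution with per-sample penalty $\beta$; there is no randomness anywhere
in the fitter. At $\beta = 0$ the iteration's fixed point is ordinary
least squares, which the tests verify against `lm()` to $10^{-6}$
relative error.

**Why the $1/n$ normalization.** The penalty is applied per sample so that
$\beta$ means the same thing at any cohort size. Two consequences drove
the choice: a single informative feature among noise columns is isolated
at $\beta \approx 1$ (without normalization, the L1 stationarity threshold
$|z_j^\top e| \le \beta$ is crossed by pure-noise columns at any usable
$\beta$, and no setting isolates it), and the useful range of $\beta$ on
cohorts of 50–70 samples lands at roughly 0.1–1, the range in which
sparsity coefficients for this family of methods are conventionally
quoted.

**Why iteration stops on panel stability.** Run to convergence, the
scheme reaches an L1 stationary point, and L1 penalties are
winner-take-all on correlated predictors: of a group of collinear
informative lipids, one survives and the rest are zeroed. That endpoint is
wrong for a *feature-selection* method whose product is the panel — real
biomarker groups (lipids co-varying with severity) would be silently
halved. The two processes run on different timescales: noise features
collapse within a few iterations (their reweighted penalty explodes),
whereas erosion inside a correlated informative group is slow drift. The
fitter therefore stops when no feature has been pruned for `stable_iters`
(default 10) consecutive iterations, or earlier if the weights themselves
converge (`conv_tol` $10^{-8}$, which is what terminates clean low-noise
fits). The default of 10 came from a sensitivity grid over
`prune_tol` × `stable_iters` on synthetic cohorts: pruning events arrive
in dense bursts, so a quiet stretch of 10 iterations reliably marks the
end of the noise cascade while correlated planted biomarkers are still
intact; at 30, winner-take-all erosion has already begun.

**Panel-size rule.** `choose_beta()` scans a sweep and takes the smallest
$\beta$ whose panel lands in a 9–12-feature window — the practical size
for a clinical readout panel — falling back to the entry maximizing
training r² minus 0.005 per selected feature. Both the window and the
penalty are advisory defaults, exposed as arguments.

**Inference.** t and p values per selected feature come from an
unpenalized least-squares refit (residual-variance SEs, Student t with
$n-k-1$ df). They are *nominal, post-selection* values — the selection
event is not conditioned on — and should be read as descriptive, matching
how such coefficient tables are usually reported alongside panel
histograms. Exact fits report SE 0 and the smallest representable p,
flagged; aliased columns are dropped with a warning; a panel that prunes
to nothing yields a flagged intercept-only model that predicts the class
mean.

# BRANN: evidence-framework regularization

The network is one hidden layer of `n_hidden = 3` tanh units with a linear
output — 34 weights for a 9-feature panel, sized for cohorts of this
scale. Training minimizes

$$F(w) = \beta_n E_D + \alpha E_W, \quad E_D = \sum_i (y_i - f(x_i))^2,
  \quad E_W = \tfrac12 \sum_k w_k^2$$

by damped Gauss–Newton (Levenberg–Marquardt) steps, with the
hyperparameters re-estimated from the evidence approximation:
$\gamma = N_w - \alpha\,\mathrm{tr}(H^{-1})$,
$\alpha = \gamma / (2 E_W)$, $\beta_n = (n - \gamma)/(2 E_D)$, where
$H = 2\beta_n J^\top J + \alpha I$ is the Gauss–Newton Hessian. $\gamma$
is the effective number of parameters; regularization replaces early
stopping, so no validation data is consumed. Weights are initialized from
a seeded stream scaled by $1/\sqrt{\text{fan-in}}$ and training is
bit-reproducible given the seed.

Two numerical choices matter. First, hyperparameters are re-estimated only
after a bounded inner minimization (at most 25 LM steps), not after every
step: re-estimating against the large residuals of a half-trained network
locks $\beta_n$ low and the fit stalls in a self-consistent under-fit.
Second, the updates are clamped — $\alpha \in [10^{-8}, 10^8]$,
$\beta_n \le 10^{12}$, with $\beta_n$ frozen and flagged when $E_D$
reaches the numerical floor or $\gamma \ge n$ — because the evidence
update is undefined at zero residuals. The total step budget defaults to
1000 (a fit takes ~0.2 s at these sizes); noiseless targets need most of
it, since each outer round raises $\beta_n$ and tightens the fit.

**Known limitation: memorization on separable cohorts.** When the classes
are nearly separable in the panel features — which strong planted effects
make common — the network can drive training residuals to ~0, the
evidence concludes the noise is negligible, $\beta_n$ escalates, and the
training set is memorized ($\gamma \to N_w$); test accuracy on such seeds
drops 10–20 points below the linear model. A noise-precision floor strong
enough to prevent this would destroy the framework's ability to fit
genuinely noiseless data (the two demands conflict), so the behaviour is
left intact and visible in `objective_trace`, `gamma_effective` and the
`beta_noise_clamped` flag. Across seeds the signed accuracy delta between
BRANN and MLR-EM is centred near zero (`analysis/06_model_comparison.R`),
which is the study-level observation that matters: the class structure is
essentially linear in these biomarkers, so the network does not
systematically beat the linear model.

# Preprocessing choices

* **Scaling**: raw LC-MS peak areas (~10⁵–10⁶) are divided by a
  configurable factor, default 100,000, bringing intensities to order
  unity for the regularized fits. Division is linear, so scaling twice by
  $a$ then $b$ equals scaling by $ab$ (tested).
* **Replicate outliers**: within each feature and replicate group of ≥ 3
  present values, a value is masked when its leave-one-out z-score (mean
  and SD of the *other* replicates) exceeds `k_sd = 3`. Leave-one-out
  keeps one wild replicate from inflating its own reference SD; computing
  all z-scores against the original values makes masking order-invariant.
  Groups of fewer than three present values are never touched.
* **Collapsing**: replicates average to one row per biological sample;
  all-masked cells become missing.
* **Imputation**: feature means computed over *all* samples (never per
  class, so class labels cannot leak into the design); features with no
  present values are dropped with a warning. Fancier missing-not-at-random
  imputation is out of scope.
* **Clinical covariates**: continuous columns (age, waist, chemokines) are
  z-scored by default so they are commensurate with scaled lipid columns;
  gender becomes one 0/1 indicator; gene statuses code as +1 (mutation
  positive), −1 (negative), 0 (unknown), so untested samples exert no
  pull. Chemokines are used on their raw (then z-scored) scale — whether a
  log-transform is more appropriate is study-dependent and was left to the
  caller.
* **Stage-0 CRC**: excluded from the staging scenario by default (the
  stage codes 1–4 carry the ordinal signal); a flag re-admits them as
  code 0.

# Evaluation conventions

* **Rounding**: predictions map to the nearest class code, exact midpoints
  to the *lower* code (deterministic and order-preserving), out-of-range
  values clip to the end codes.
* **r²** is the squared Pearson correlation between truth and prediction;
  the 1 − SSE/SST variant is also exported (`r2_sse`). Constant
  predictions report r² = 0 with a flag.
* **"Standard error"** is the root-mean-square prediction error on the
  continuous code scale — on unit-spaced codes an RMSE of ~0.4 means
  typical errors well under one stage. This definition is stated
  prominently because "standard error" is ambiguous in informal use.
* **Stratified split**: per class, `round(test_frac · n)` test samples,
  minimum one, drawn without replacement from the seeded stream; 16/32/18
  at 20% gives test counts 3/6/4.

# Survival analysis

Kaplan–Meier estimation and the log-rank test are computed via the
`survival` package behind the package's own interface; the test suite
checks the product-limit values against an independent explicit risk-set
loop on random datasets, exactly. Ties between events and censorings at
one time resolve events-first (the standard convention). Disease-free
survival is administratively censored at 60 months and overall survival at
96 (configurable); at-risk tables are reported at 12-month ticks. At 66
samples the stage-wise (5-group) log-rank is underpowered and frequently
non-significant — the three-group CFI/CRC/CLM contrast is the powered
comparison, and `analysis/02_survival.R` reports both.

# The synthetic-cohort generator

The generator emulates the statistical structure the analysis assumes,
not mass spectra. For sample $s$ and feature $j$,

$$\log I_{sj} \sim N\!\big(\mu_0 + e \cdot c_s \cdot d_j,\ \sigma^2\big),$$

log-normal because peak intensities are positive and right-skewed. Here
$c_s$ is a graded severity code — CFI 0, CRC stage $s$ as $s/2$, CLM 2 —
chosen so one cohort serves all three scenarios: it agrees with the
three-group codes at the endpoints, is monotone in group, and gives the
staging scenario stage-graded signal. Directions $d_j = \pm 1$ alternate
over the planted features (default 9 informative among 333). Defaults:
baseline $\mu_0 = \log(5 \times 10^5)$ (Orbitrap-scale peak areas), shape
$\sigma = 0.5$ (roughly a 50% coefficient of variation, a realistic
mid-range for plasma lipids), effect size 1.0 log-units per severity unit,
3 technical replicates per sample, 2% missing cells and 1% eight-fold
outliers injected at replicate level (after replicate expansion, so the
masking rule has something to find). Chemokines shift linearly with
severity around plausible baselines; gene statuses are ternary draws with
per-gene prevalences; survival times are exponential with group-median
anchors (CFI 120 / CRC 48 / CLM 20 months DFS, OS at twice the DFS
median), graded within CRC by stage severity so stage IV runs shorter
than stage I while the group-level median stays at its anchor; censoring
is an independent Bernoulli (30%) with censoring times drawn uniformly
before the event. One root seed drives fixed sub-streams per component
(structure, intensities, outliers, missingness, demographics, chemokines,
genes, survival), so adding a component does not perturb the others and
cohorts are bit-reproducible.

**What passing tests do and do not show.** The generator's planted signal
is rank-one (every informative feature tracks the same severity scalar),
noise is independent log-normal, and there are no batch effects, no
adduct/isotope structure, no correlated lipid classes, no informative
missingness. Recovering planted panels here shows the selector behaves
correctly under the model's own assumptions — it does not certify
performance on real LC-MS data, where correlated noise and annotation
ambiguity will erode both recall and the nominal p-values.

# Problem sizes and runtime

The shipped tests and the acceptance script run the full-size synthetic
study — 66 samples × 333 features (three replicates each) for the
three-group scenario, 59 × 289 for staging, 48 × ~350 for multi-omics —
with 10–20 seed replicates for the Monte-Carlo properties and 1000
replicates for the log-rank type-I-error check. The whole test suite runs
in about a minute on one CPU; the acceptance script in about one minute;
each analysis script in seconds.

# Limitations

* Post-selection p-values are nominal, not selection-adjusted.
* The β scale is implementation-specific; only the qualitative
  sparsity-vs-β behaviour (and the practical 0.1–1 range) is meaningful
  across implementations.
* The evidence framework can memorize separable training sets (above).
* Exponential survival with independent censoring is a deliberately simple
  model; no Cox regression or competing risks.
* The generator's severity grading and two-class-per-gene prevalences are
  scientific defaults, not fitted to any dataset.
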