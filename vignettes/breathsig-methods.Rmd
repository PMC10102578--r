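---
title: "Methods: from raw breath spectra to discriminative metabolic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw breath spectra to discriminative metabolic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathsig)
```

# Scope and model

`breathsig` implements the full computational path of an online-breath
metabolomics case/control study measured by secondary electrospray
ionization high-resolution mass spectrometry (SESI/HRMS): participants
exhale directly into the instrument, producing a time series of mass
spectra in which exhalation phases appear as plateaus of the total ion
current (TIC). The pipeline has four stages:

1. **Preprocessing** — raw scans are interpolated onto a fixed m/z grid
   (step 0.0005 Th over 50–500 Th), scans associated with exhalation are
   averaged, peaks are picked on the averaged spectrum and integrated by
   the trapezoidal rule, and per-sample peak tables are aligned into a
   samples × features matrix of log2 TIC-normalized intensities
   ("breath profiles").
2. **Differential analysis** — surrogate variable analysis (SVA) estimates
   latent batch/confounder factors from the profile matrix; an
   empirical-Bayes moderated t-test contrasts cases against controls per
   feature; Benjamini–Hochberg step-up adjustment controls the FDR at
   0.05.
3. **Classification** — repeated stratified k-fold cross-validation with
   in-fold Boruta feature selection and a class-weighted linear SVM; fold
   ROC curves are vertically averaged on a fixed FPR grid with a bootstrap
   pointwise confidence band.
4. **Annotation** — exact-mass matching of feature m/z against a compound
   library under adduct/loss rules with proton–electron bookkeeping,
   bounded molecular-formula enumeration, isotope/adduct satellite
   grouping, Schymanski-style identification levels, and a
   mummichog-style permutation test for pathway enrichment.

A synthetic-data module generates cohorts and raw recordings with known
ground truth so that every stage is testable without any external data.

# The moderated t-test

For sample-level log2 profiles $y_g$ (feature $g$) and design matrix $X$
(intercept, binary group, optional surrogate columns), per-feature least
squares yields $\hat\beta_g$ and residual variance $s_g^2$ on $d = n - p$
degrees of freedom. The variances are assumed to follow a scaled
inverse-$\chi^2$ prior with parameters $(d_0, s_0^2)$, estimated by
method of moments on $e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$: the mean
of $e_g$ identifies $s_0^2$ and its excess variance over $\psi'(d/2)$
identifies $d_0$ through the trigamma function, inverted by Newton
iteration (tolerance $10^{-8}$). The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ moderates the statistic
$\tilde t_g = \hat\beta_g / (u \tilde s_g)$ on $d_0 + d$ degrees of
freedom, where $u$ is the unscaled coefficient standard deviation from
$(X^TX)^{-1}$. When the moment estimate of the spread is non-positive the
$d_0 = \infty$ branch applies: all posterior variances collapse to
$s_0^2$ and the reference distribution is normal. Features with exactly
zero residual variance are flagged and assigned $p = 1$ rather than
dropped. The group indicator is coded control = 1 so that a *negative*
coefficient means higher average expression in the case (asthmatic)
group; the test suite verifies the whole fit against the standard
Bioconductor implementation as an independent oracle.

# Surrogate variable analysis

The number of surrogates is chosen by permutation parallel analysis on
the residuals of the primary model (20 permutations, per-component level
0.05, counting consecutive leading components). Scores are refined by an
iteratively reweighted SVD: each iteration weights every feature by the
empirical probability of association with the current surrogates times
the probability of *no* association with the group (both derived from
F-test p-values), and takes the leading left singular vectors of the
weighted, column-centered data matrix. Two choices deserve emphasis:

* Working on the weighted **data** rather than the residuals is what
  allows a confounder partially aligned with the group to be recovered in
  full from the group-null features; residual-space SVD can only see the
  orthogonal component.
* The default is **20 reweighting iterations**, not the 5 initially
  considered: in the batch-confounded validation scenario the surrogate
  direction is still measurably off after 5 iterations (correlation with
  the planted batch ≈ 0.96, adjusted empirical FDR ≈ 0.2) and converges
  by 10–20 (correlation ≈ 0.99, FDR at the nominal level). Each iteration
  costs two vectorized F-tests and one SVD, so the extra iterations are
  essentially free.

For cross-validation the model is frozen: held-out samples are centered
with training feature means and projected onto the training loadings by
least squares; nothing is re-estimated from held-out data.

# Boruta and the classifier

Boruta pairs every undecided feature with a freshly permuted "shadow"
copy, fits a random forest (500 trees by default, $\sqrt{p}$ candidate
features per split, OOB permutation importance), and scores a hit when a
real feature's importance exceeds the maximum shadow importance.
Decisions use a binomial test against hit probability 0.5, Bonferroni
corrected over *features × evaluations performed* — the decision is
re-checked after every iteration, and uncorrected sequential peeking
measurably inflates false confirmations on pure-noise data. The shadow
pool is kept at the original feature count throughout, so the max-shadow
bar does not weaken as features are rejected. Residual tentatives are
left tentative by default (matching the reference implementation's
default); the median-importance rough fix is available as an option but
note that on finite samples it resolves the luckiest in-sample noise
feature by what amounts to a coin flip.

The classifier is an L2-regularized hinge-loss linear SVM solved by dual
coordinate descent, with per-class cost balancing ($C_i = C\,n/(2 n_{c})$,
default $C = 1$). Kernel and hyperparameters are fixed defaults, exposed
in the API. If a fold confirms no features the classifier falls back to
all features, which keeps permutation-null folds honest instead of
degenerate.

Cross-validation is leakage-proof by construction: per fold, SVA,
standardization statistics, Boruta, and the SVM are fit on training rows
only and applied frozen to held-out rows. The test suite audits this by
corrupting held-out rows and asserting bit-identical training artifacts.
The headline AUC is the mean of per-fold trapezoidal AUCs (matching the
"average ROC curve ... with an average AUC" convention); the area under
the vertically averaged curve is computed and reported alongside, and the
two are checked to agree within 0.02 on the default synthetic scenario.
The bootstrap band resamples fold curves 10,000 times and takes pointwise
2.5/97.5 percentiles.

# Mass arithmetic and annotation

All adduct rules carry their full elemental and charge bookkeeping: the
proton mass is defined as H minus an electron, and, e.g., the ammonium
adduct delta is $N + 4H - e$. The ppm error uses the *theoretical* mass
in the denominator; this reproduces the printed reference values, and the
measured-denominator variant differs below print precision. Formula
enumeration searches C 0–40, H 0–80, N 0–6, O 0–10, S 0–2 with ring-plus-
double-bond equivalents ≥ 0, the integer-RDBE nitrogen rule, and an
H/C ≤ 3.1 heuristic applied only when C > 1 — single-carbon molecules
such as urea (H/C = 4) are chemically valid and exempt. Satellite
grouping links feature pairs whose m/z difference matches the 13C
spacing or a standard neutral gain/loss (H2O, NH3, CO, CO2, HCOOH)
within 5 mTh *and* whose cross-sample intensities correlate at
Pearson r ≥ 0.9; connected components form groups with the most intense
member as primary ion. Pathway enrichment maps all detected features to
library compounds under the adduct rules and compares each pathway's
distinct-compound hits from the significant set against draws of equally
many features from the detected set,
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$. MS² evidence
(spectral library matches, in-silico candidates, reference standards) is
represented only as caller-supplied evidence flags feeding the 1–5
identification level; no fragmentation modeling is attempted.

The bundled compound library covers the breath metabolites of the
relevant pathways (lysine degradation, tyrosine metabolism,
2-oxocarboxylic acid metabolism, arginine and proline metabolism,
arginine biosynthesis, linoleic acid metabolism) and chemical-family tags
(fatty acid metabolites, monosaccharides, aldehydes, fatty amides, fatty
acids); masses are recomputed from formulas at load time. Family tags
overlap metabolic pathways by design (a dicarboxylic acid is both), so
enrichment ranks should be read per tag, not as a partition.

# The synthetic world

`sim_config()` defaults state the emulated study: 48 cases / 56 controls,
2,315 m/z features of which 375 differ between groups (179 up in cases,
196 down) with |log2| effects uniform in 0.15–1.1; recordings with at
least three exhalation plateaus (trapezoidal, 1 s rise/fall) at 0.5 s per
scan; Gaussian m/z peaks with $\sigma = m/z / (R \cdot 2.355)$; 13C
isotopologue satellites with binomial natural-abundance intensity from
the feature's carbon count (drawn Poisson with mean 8 when not mapped to
the library) and water adduct/loss satellites; log-normal multiplicative
subject noise (SD 0.3 on the log2 scale — at the upper end of the range
under which the planted-recovery guarantees are stated); 4 batches with
per-feature log2 shifts of SD 0.2. The instrument resolving power is not
stated by the emulated study; the default 30,000 is an explicit
placeholder exposed in the configuration. Exhalations plus breaks are
sized so the baseline occupies the majority of the recording — the
median-plus-MAD exhalation detector requires a minority duty cycle, which
the stated breathing maneuver (long exhalations with pauses) satisfies.

What the generator does **not** emulate: electrospray ionisation physics,
ion suppression and matrix effects, m/z calibration drift, peak-shape
asymmetry, missingness mechanisms other than below-threshold peaks, and
MS² spectra. A green end-to-end test therefore establishes that the
pipeline's inferential machinery is correct under the stated statistical
structure, not that it is robust to every instrumental artifact.

# Numerical and design choices

* **Exhalation association**: TIC > median + 3×MAD for ≥ 3 s, gaps of
  ≤ 2 scans bridged; all parameters exposed. A plateau covering more than
  half the recording defeats a median threshold by construction; the
  generator and the breathing maneuver both keep exhalation duty cycle
  below one half.
* **Feature alignment**: pooled apex m/z values are chained with a
  10 ppm gap rule (a new feature starts where the sorted gap exceeds the
  tolerance) — the practical reading of single-linkage binning, since a
  strict diameter cap splits arbitrarily. Features present in < 70% of
  samples are dropped; remaining absences are imputed at half the
  sample's smallest positive normalized value before log2.
* **Zero handling**: the half-minimum rule keeps the matrix complete, as
  the downstream tests require; it is standard metabolomics practice.
* **Recalibration**: the proprietary vendor recalibration step is
  replaced by an optional two-point linear m/z correction (not applied by
  default).
* **Polarity**: recordings are preprocessed per polarity and the
  matrices may be pooled afterwards; whether the emulated study pooled or
  analyzed per polarity is unstated, and pooling is the default here.
* **Degenerate inputs**: constant TIC yields zero exhalations (flagged);
  zero-variance features are flagged with p = 1; empty Boruta
  confirmations fall back to all features; identical fold ROC curves
  produce a zero-width bootstrap band.
* **Determinism**: every stochastic step (cohort simulation, parallel
  analysis permutations, shadows, fold assignment, bootstrap) flows from
  a single master seed; the C++ forest and SVM use their own
  Mersenne-Twister streams seeded from R so results are identical across
  platforms.

# Known limitations

Tree building in the forest is exact CART on continuous features without
surrogate splits or missing-value handling; the SVM is linear only. The
mzML reader supports the subset the writer emits (uncompressed 64-bit
float arrays, MS1). Identification confidence levels above exact-mass
matching depend entirely on caller-supplied evidence flags. Enrichment
p-values are permutation-based and hence granular at small $n_{perm}$.
The printed reference table contains one mass-error value (the
glucuronate row) that differs from the recomputed value by 0.1 ppm at
print precision and one 13C row that does not reproduce under any
bookkeeping consistent with the other rows; both are documented in the
tests rather than silently adjusted.
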