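---
title: "Methods: NMR metabonomics discrimination of thyroid tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMR metabonomics discrimination of thyroid tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Distinguishing malignant from benign thyroid nodules preoperatively is a
real clinical gap: fine-needle aspiration is indeterminate in a substantial
fraction of cases. Tissue metabonomics attacks it by reading the small-
molecule profile of the tissue directly. This package implements the full
statistical pipeline for that analysis: 1D ¹H NMR spectra of tissue (intact
or aqueous extract) are reduced to fixed-width chemical-shift buckets,
modelled with projection methods, validated by cross-validation, and read
out as metabolite-level change tables; a parallel GC-FID/MS branch analyses
fatty-acid composition.

The discriminant core is **OPLS-DA** (orthogonal projections to latent
structures discriminant analysis). With the unit-variance-scaled bucket
matrix $X$ ($n$ samples × $p$ buckets) and the centred class membership
$y \in \{0,1\}$ as the single response, the predictive weight is
$w \propto X^\top y$ (unit norm). Each orthogonal component captures
X-variation uncorrelated with $y$: with $t = Xw$ and loading
$p = X^\top t / (t^\top t)$, the orthogonal weight is
$w_o \propto p - (w^\top p)\,w$, scores $t_o = X w_o$, loadings
$p_o = X^\top t_o/(t_o^\top t_o)$, and $X$ is deflated by $t_o p_o^\top$.
The final predictive score is $t = X_{\text{deflated}} w$ with inner
regression $b = t^\top y / (t^\top t)$. For a single response no NIPALS
iteration is needed — the solution is closed-form — and with zero
orthogonal components the model coincides exactly with single-component
PLS1, which the test suite verifies against an independently written NIPALS
oracle.

Model quality is reported the way the field reports it:

* $R^2X$, $R^2Y$ — fractions of (scaled) X- and Y-variance modelled;
* $Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}_{tot}$ from stratified 7-fold
  cross-validation, where every fold refits both the scaling and the model
  on the training portion only;
* **CV-ANOVA**: $F = \frac{(\mathrm{SS}_{tot}-\mathrm{PRESS})/d_1}
  {\mathrm{PRESS}/d_2}$ with $d_1$ the model degrees of freedom and
  $d_2 = n - d_1 - 1$, read against the $F(d_1, d_2)$ upper tail;
* ROC/AUC computed from the *cross-validated* predicted $\hat y$, with the
  single reported operating point chosen by Youden's $J$.

Bucket-level interpretation uses correlation-scaled back-transformed
loadings: for each bucket, the Pearson correlation $r$ with the predictive
score (colour scale, significance against the critical value
$r_{crit} = t^*/\sqrt{t^{*2} + (n-2)}$) and the covariance-based
coefficient in original intensity units, so the plot reads like a spectrum.
$r_{crit}$ is displayed truncated — not rounded — to two decimals (0.29 at
$n=44$, 0.39 at $n=25$, $\alpha=0.05$): any correlation above the printed
cutoff is significant, so flooring is the conservative display convention.

# Preprocessing parameters

| parameter | default | why |
|---|---|---|
| bucket width | 0.004 ppm | standard fine bucketing; robust to small shift errors while keeping multiplets resolved |
| bucket range | 0.5–9.0 ppm | the informative ¹H window; 2125 buckets |
| water exclusion | δ 4.20–5.20 (closed) | residual water/solvent suppression artefacts; removes 250 buckets, 1875 remain |
| normalization | total integral (intact) / wet weight (extract) | intact spectra have no absolute scale; extracts carry a known tissue mass (mg, divided as g) |
| PCA scaling | mean-centre | variance structure is the object of interest |
| OPLS-DA scaling | unit variance | every bucket, weak or strong, contributes comparably |

Buckets are left-closed right-open intervals; values are trapezoidal
integrals of the piecewise-linear spectrum, exact for linear interpolants
and conservative of the total integral (tested at 1e-6 relative). The ppm
axis is stored ascending regardless of display convention.

**Order of operations.** The water window is excluded *before*
normalization, so residual water cannot distort row sums. The alternative
order gives measurably different rows; a regression test pins the chosen
order.

# The synthetic cohort

No patient spectra are distributed with this kind of study, so the package
carries a generator whose defaults *are* the study conditions: 46 healthy
adjacent tissues, 25 benign nodules (nodular goiter + follicular adenoma),
28 malignant (papillary carcinoma) nodules. Each spectrum is a sum of
Lorentzian lines (HWHM 0.003 ppm — NMR lines are Lorentzian) over a
38-metabolite template library spanning amino acids, choline metabolites,
TCA intermediates, lactate, glutathione, taurine, inositols and
purine/pyrimidine metabolites, plus i.i.d. Gaussian noise (sd 0.5 intensity
units — a high signal-to-noise floor typical of well-shimmed spectra).
Per-sample metabolite levels are log-normal (sdlog 0.25, ≈25% CV) around
group-specific medians: concentrations are positive and right-skewed.
Intact-tissue mode adds broad lipid envelopes (widths ×20) at δ 0.9 / 1.3 /
2.0 / 5.3; extract mode omits lipid entirely and instead carries per-sample
wet weights (uniform 45–55 mg).

Planted effects follow the published **direction** pattern (lesions: amino
acids, lactate, choline metabolites, taurine, inositols, GSH up, lipid
down; malignant vs benign: lactate and choline phosphometabolites up,
citrate, inositols, inosine, uridine down) at a uniform fractional median
shift of 0.5. The magnitude is a testability choice, fixed once: the source
reports only signs and correlation coefficients, never effect sizes, so
recovery *rates* on synthetic data say nothing quantitative about the
clinical effect sizes.

What the generator does **not** emulate: chemical-shift drift and peak
misalignment, baseline and phase artefacts, J-coupling multiplet structure,
inter-metabolite correlation (levels are drawn independently), and T2
filtering of macromolecules. Passing recovery tests therefore demonstrate
that the *pipeline* is correct and calibrated, not that real thyroid
cohorts would separate this cleanly.

# Identifiability: why sign recovery is scored on extracts

Total-integral normalization makes intact-mode rows compositional: a large
genuine *decrease* in the dominant lipid signal mechanically inflates every
other bucket's relative share, and metabolites overlapping the broad lipid
envelopes (e.g. branched-chain amino acids around 0.9–1.0 ppm) inherit the
lipid's correlation sign. In that regime the planted per-metabolite
direction is simply not identifiable from bucket signs — a property of the
method on intact tissue, not a defect. Recovery checks therefore run on the
extract-mode cohort (wet-weight normalization preserves absolute scale, no
lipid envelope), where ground truth is identifiable; intact mode is still
exercised end-to-end for model quality.

# Numerical and statistical choices

* **Class encoding**: $y \in \{0,1\}$ centred; predicted class threshold at
  the centred midpoint (0.5 on the decoded scale).
* **Component signs**: PCA forces the largest-magnitude loading element
  positive; OPLS-DA forces $\mathrm{cor}(t, y) \ge 0$. Results are
  deterministic.
* **Zero-variance buckets** are dropped with a warning before unit-variance
  scaling; in loading reports their correlation is reported as 0 with an
  explicit flag rather than NaN.
* **Orthogonal components**: default 1; `select_n_ortho()` offers
  Q²-guided selection (stop when the gain drops below 0.01). The original
  software's per-model component counts are unreported, so this is a stated
  substitute, not a reproduction.
* **CV-ANOVA degrees of freedom**: $d_1 = 2 + 2 n_{ortho}$ (predictive
  component + score/loading pair per orthogonal component + intercept) — a
  component-counting convention pinned by a regression test.
* **Folds**: stratified, seeded; each class is shuffled and dealt to folds
  in rotation, so $K = n$ degenerates to leave-one-out and class balance is
  within one sample per fold.
* **ROC ties**: midranks, making AUC identical to the normalized
  Mann–Whitney U and to the trapezoidal area; verified against an
  exhaustive pair count at 1e-12.
* **t-tests**: Student's pooled-variance by default (the named convention
  for the assay tables); Welch behind `var_equal = FALSE`. No
  multiple-testing correction by default, matching per-feature p < 0.05
  reporting; Benjamini–Hochberg behind `adjust = "BH"`.
* **D6D index**: product/precursor concentration ratio C18:3n6 / C18:2n6
  (the standard estimated-activity convention; the alternative
  C20:3n6-based ratio sits behind `d6d_alternative`). Reported missing when
  the precursor is absent.
* **Fatty-acid group tests** run on concentrations (μmol/g) for species and
  class roll-ups — the scale on which levels are reported — with molar
  percentages kept as descriptive output.

# Known limitations

* **CV-ANOVA is conservative under the null.** Under permuted labels the
  cross-validated PRESS typically exceeds the total sum of squares, so F
  floors at zero and the realized type-I error is well below the nominal
  α = 0.05 (measured ≈0.012 at 500 replicates, n = 28, one orthogonal
  component). A calibration band of 3–7% around the nominal level is
  therefore not attainable for this statistic; the package reports the
  conservative behaviour as is. Its power on genuine effects is ample (the
  default planted effect yields p ≈ 1e-20).
* Two-class models only; the three-group design is analysed as the two
  pairwise comparisons (lesion vs healthy, malignant vs benign), matching
  the source analysis. No multi-class or kernel variants.
* The metabolite region map is a static input derived from the template
  library; no automated peak assignment.
* Chemical-shift referencing is assumed already applied upstream.

# Problem sizes used in the checks

The shipped verification suites run at deliberately modest sizes chosen for
tight feedback: oracle equivalences on 20×40 matrices; null calibrations at
500 replicates (28 samples × 40 variables per replicate); Q² null at 50
replicates; spectral sign recovery at 100 replicates of the full 99-sample
extract cohort on the standard 0.001-ppm grid; fatty-acid flag rates at 200
replicates of the default cohort. The end-to-end model-quality run uses the
full default cohort once per tissue mode.
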