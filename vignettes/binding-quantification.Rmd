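---
title: "Quantifying 5-HT1A binding potential and its stress and methylation correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 5-HT1A binding potential and its stress and methylation correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petbpf)
```

## The problem

Serotonin 1A (5-HT1A) receptor availability in brain is measured *in
vivo* with [11C]WAY100635 PET. The outcome is the binding potential
referenced to free plasma ligand,

$$\mathrm{BP_F} = \frac{V_T(\mathrm{ROI}) - V_T(\mathrm{REF})}{f_P},$$

where $V_T$ is a region's total volume of distribution (equilibrium
tissue-to-plasma concentration ratio), the reference region is
cerebellar white matter (essentially devoid of 5-HT1A receptors), and
$f_P$ is the fraction of tracer unbound to plasma proteins.
$\mathrm{BP_F}$ is proportional to available receptor density over the
dissociation constant.

`petbpf` implements this quantification from raw arterial and PET data
and the downstream statistical analysis relating regional
$\mathrm{BP_F}$ to recent life stress (Recent Life Changes
Questionnaire life-change units, LCU), childhood adversity, the rs6295
(C(-1019)G) promoter polymorphism, and DNA methylation at three
promoter CpG sites (-1019, -1007, -681) in a case-control design (major
depressive disorder vs healthy volunteers). Because the clinical data
the design comes from are not public, the package ships a calibrated
synthetic generator so that every stage is testable end to end.

## Kinetic quantification

### Metabolite-corrected arterial input function

Arterial samples give total plasma radioactivity over time plus, on a
subset of draws, the fraction of activity still attributable to
unmetabolised parent tracer. The parent fraction is fit with a
decreasing Hill function

$$pf(t) = f_{\infty} + (1 - f_{\infty})\,
  \frac{t_{50}^{h}}{t_{50}^{h} + t^{h}},$$

which equals 1 at injection, decays with half-time $t_{50}$ and Hill
coefficient $h$, and levels off at an asymptotic parent fraction
$f_\infty \in [0, 1)$. This 3-parameter decreasing form is the standard
parent-fraction variant of the Hill family; it guarantees the boundary
behaviour $pf(0) = 1$ and monotone decline for all admissible
parameters. Total activity times $pf(t)$ gives the metabolite-corrected
input samples.

The corrected samples are modelled piecewise: a straight line before
the curve peak and a sum of three decreasing exponentials
$\sum_i A_i e^{-\lambda_i t}$ after it. Three choices here are ours
because the procedure leaves them open:

* **Peak location** is the time of the maximum corrected sample
  (earliest sample on ties); no interpolation rule is imposed.
* **The pre-peak line is anchored at the origin** and ends at the
  *fitted* tri-exponential value at the peak, so the piecewise function
  is continuous by construction and the nonlinear fit stays
  unconstrained. (Fitting the line to pre-peak samples instead would
  generally leave a jump at the peak.)
* **Rates are kept strictly ordered** ($\lambda_1 > \lambda_2 >
  \lambda_3$) to resolve the label-switching degeneracy of exponential
  mixtures.

The piecewise form admits a closed-form convolution with
$e^{-\alpha t}$ (`convolve_exp()`), including the $\alpha \to \lambda_i$
and $\alpha \to 0$ limits via series expansions, so tissue-model
predictions are exact rather than grid-based. The test suite verifies
the closed forms against adaptive quadrature and a trapezoidal
discrete-convolution oracle.

### Constrained two-tissue compartment model

The reference region is fit with a one-tissue model; its $K_1'/k_2'$
estimates the non-displaceable volume of distribution $V_{ND}$ (a
one-tissue model is the minimal model providing that ratio; a
two-tissue reference is available via `run_config(reference_model =
"two_tissue")` for sensitivity analyses). Each ROI is then fit with the
two-tissue compartment model whose impulse response is

$$h(t) = \frac{K_1}{\alpha_2 - \alpha_1}\left[(k_3 + k_4 - \alpha_1)
  e^{-\alpha_1 t} + (\alpha_2 - k_3 - k_4) e^{-\alpha_2 t}\right],
  \qquad
  \alpha_{1,2} = \frac{(k_2 + k_3 + k_4) \mp
  \sqrt{(k_2+k_3+k_4)^2 - 4k_2k_4}}{2},$$

with the free parameters $(K_1, k_3, k_4)$ and the *constraint*
$k_2 := K_1 / V_{ND}$, so that $K_1/k_2$ equals the reference value
exactly. Then $V_T = (K_1/k_2)(1 + k_3/k_4)$ and
$\mathrm{BP_F} = (V_T - V_T(\mathrm{REF}))/f_P$. Negative
$\mathrm{BP_F}$ can arise from noise and is returned (flagged), not
floored.

Optimisation is bounded Levenberg-Marquardt from a fixed grid of five
log-spaced starts; ties in residual sum of squares break toward the
lower $k_4$. Because the start grid is fixed, fits are deterministic.
Other defaults the acquisition description does not pin down:

* **Frame evaluation**: the model is evaluated at the frame mid-time
  (`frame_mode = "midpoint"`); duration-averaged integration over each
  frame is available (`"average"`) and uses the closed-form running
  integral.
* **Fit weighting**: uniform across frames by default;
  `tac_weighting = "duration"` weights by frame length.
* **No vascular (blood-volume) term** is included, as none is part of
  the quantification being reproduced.
* Dispersion/delay correction and plasma-to-whole-blood conversion are
  out of scope.

### Bootstrap standard errors and observation weights

Per-region precision of $\mathrm{BP_F}$ comes from a residual bootstrap
of the TAC fit (`bootstrap_bpf()`): fitted residuals are standardized
by the frame noise shape $\sigma_i \propto
\mathrm{activity}_i/\sqrt{\mathrm{duration}_i}$ (the count-statistics
scaling of frame variance), resampled with replacement, rescaled onto
the predicted frames, and the constrained fit is repeated; the SE is
the standard deviation of the replicate $\mathrm{BP_F}$ values. The
standardization is what keeps the scheme calibrated under
heteroscedastic acquisition noise — with homoscedastic residuals it
reduces to the plain residual bootstrap. The AIF and the reference fit
are held fixed, so the SE reflects the TAC fit alone; resampling the
plasma data as well would be a straightforward extension hook.

Down-stream models weight observations by $w_i = se_i^{-2}$ on the
log-binding scale (quantification SEs are mapped to the log scale by
the delta method $se/\mathrm{BP_F}$), normalized to mean 1 across the
modelling set; normalization leaves point estimates unchanged and keeps
variance components interpretable.

## Statistical pipeline

Methylation fractions and $\mathrm{BP_F}$ enter models on the natural
log scale (natural rather than base-10 log only rescales
coefficients). After transformation, outliers more than 1.5
interquartile ranges outside the quartiles (linear-interpolation
quartiles, `quantile()` type 7) are censored to the nearest *retained
observation* — the literal "nearest non-outlier value", not the fence.
Censoring is applied once, across the full modelling sample (a
config-independent choice documented here; per-group censoring would be
an alternative), and per region for binding (each region's binding is
one variable). One caveat: single-pass censoring is not mathematically
idempotent for very small samples (n of 4-8 with extreme tails), where
one replacement can move the interpolated quartiles enough to expose a
new value; at the sample sizes used here the operation is idempotent
and the audit report records what was changed.

Genotype is coded as a three-level factor with CC reference
(`genotype_coding = "allele_count"` switches to G-allele counts). GG
carriers lack the methylatable -1019 site: a GG row with a -1019 value
is treated as a data error (coerced to missing with a warning), and any
model involving -1019 methylation excludes GG rows. Because childhood
adversity is rare among controls, all adversity analyses run in the MDD
group only. Missing covariates are handled by available-case analysis;
no imputation.

The analysis proceeds in three steps, after preliminary covariate
models (logistic: adversity ~ genotype + age + gender in MDD; linear:
stress ~ genotype + group + age + gender):

1. **Exposure to methylation** — per CpG site, linear model of log
   methylation on the exposure, genotype, their interaction, age and
   gender (plus group for stress).
2. **Exposure to binding** — weighted mixed model of log
   $\mathrm{BP_F}$ over all regions with brain region as a main effect
   and in interactions with the predictors, and a subject-specific
   random intercept; for stress, diagnostic group enters as a main
   effect and in interactions. Where region interactions are
   significant, region-level weighted least squares follow per group,
   reporting raw and standardized (per predictor SD) estimates.
3. **Methylation to binding** — the same structure with the three
   methylation sites entered jointly (a single joint model is the
   default; the wording admits per-site models, available by fitting
   sites separately), group in main effect and interactions, GG rows
   excluded.

Non-significant interactions are removed backwards one at a time at
p >= 0.05 (threshold configurable), never removing main effects and
respecting marginality (a two-way term is only removable once no
remaining three-way contains it); the removal order is logged. No
multiplicity adjustment is applied anywhere, by design — output tables
deliberately carry no adjusted-p columns.

Wald t/F statistics use denominator degrees of freedom equal to the
number of observations minus the fixed-effect rank (`df_method =
"residual"`, matching the large denominator df this analysis style
reports for region terms); a containment-style between/within split is
available (`"between_within"`). Estimation is REML; a singular
random-intercept fit falls back to weighted least squares with the
variance reported as zero — the regime in which the mixed fit provably
equals the ordinary weighted solve, which the tests exploit as an
oracle. Gender keeps an "other" level; cells with fewer than 2
observations are collapsed to the modal level and noted.

## The synthetic generator

`generate_cohort()`, `generate_binding()` and `generate_pet_subject()`
emulate the statistical structure the analysis assumes, at the study's
composition: 192 MDD / 88 controls with a 69/50 PET subset; genotypes
in Hardy-Weinberg proportions; childhood adversity prevalence 0.33
(MDD) vs 0.06 (controls) with 7% missing; gamma-distributed LCU totals
(shape 2, scale 75) with a constant MDD shift calibrated to Cohen's
d = 0.46 and 21% missing; trivariate methylation generated as a
logistic transform of a latent normal (so values stay in (0,1) and log
transforms are well defined) with a -1019/-1007 rank correlation of
0.28 (the latent Pearson correlation is set to $2\sin(\pi\rho_s/6)$ so
the *rank* correlation hits the target) and a small stress-to--681
slope; and log binding built from region baselines, a diagnosis effect
of 0.23, MDD-only stress slopes (0.001 per LCU) in amygdala, orbital
cortex and insula, and MDD-only -1007 slopes (0.3 per unit log
methylation) in seven regions, over a subject random intercept and
per-observation Gaussian noise.

Choices the study design does not pin down, made once here:

* **G-allele frequency 0.5** (only a non-significant Hardy-Weinberg
  test is reported; no allele counts), configurable.
* **LCU totals are generated directly** as gamma sums; item-level
  questionnaire simulation is out of scope (item weights are not
  published).
* **Region baseline BP_F levels** (3-6.5, higher in hippocampus and
  limbic/paralimbic cortex, lowest in occipital cortex and raphe) are
  order-of-magnitude plausible placeholders, not published values.
* **Error budget**: per-observation SEs are drawn lognormal
  (median 0.25, log-SD 0.3 on the log-binding scale) with observation
  noise SD equal to the drawn SE, and a subject random intercept SD of
  0.1. The measurement component deliberately dominates: weighting by
  the bootstrap (measurement) SE, as the analysis prescribes, is only
  approximately variance-correct when biological spread is the smaller
  component. With a dominant unweighted biological component the
  region-level WLS would be anti-conservative — a real limitation of
  SE-only weighting worth remembering with real data (see
  Limitations).
* **TAC noise** is Gaussian with SD $= \mathrm{noise\%} \times
  \mathrm{activity}/\sqrt{\mathrm{duration}}$ (5% default), the
  standard count-statistics approximation; frames follow a
  geometrically lengthening 20-frame, 110-minute schedule; arterial
  sampling is dense around the peak and includes it, so the noiseless
  pipeline is exactly self-consistent.
* The stress and methylation binding slopes apply to predictors
  centered at the MDD PET-subset means, so injected regional slopes do
  not shift the marginal diagnosis effect.

Every dataset is a pure function of (config, seed); regeneration is
bit-identical.

## Validation protocol and problem sizes

The test suite validates, at desk scale: the closed-form
$V_T = (K_1/k_2)(1+k_3/k_4)$ identity against numerically integrated
impulse responses (100 random parameter sets); exact noiseless
parameter and BP_F recovery and a 200-replicate 5%-noise bias check of
$V_T$; constraint exactness ($K_1/k_2 = V_{ND}$ to machine precision,
reference $\mathrm{BP_F} \equiv 0$); bootstrap-SE calibration against
the Monte-Carlo SD over 200 noise realizations; equality of the
weighted mixed fit with a direct normal-equations solve in the
zero-variance regime; type-I error of the region-by-stress F-test over
1000 simulated null cohorts and of the Spearman test over 1000 draws;
and recovery of every generator effect (sign, bias under 15%, CI
coverage for the diagnosis effect) over 200 study-size cohorts. The
end-to-end smoke test simulates, quantifies and analyses a 20-subject
PET cohort with 40 bootstrap replicates per region. These sizes are the
package's validation protocol; they balance Monte-Carlo precision
against a test run of a few minutes.

What passing does and does not show: the generator draws Gaussian
noise, missingness completely at random, and exactly the model
structure the analysis fits. Real acquisitions have non-Gaussian count
noise, dispersion and delay in arterial lines, motion, partial-volume
effects, informative missingness, and population structure in
genotype — none of which are emulated, so green tests certify the
implementation and its statistical calibration under the stated
conditions, not robustness to those real-data features.

## Known limitations

* Region-level WLS inherits mild anti-conservatism whenever the
  inverse-variance weights omit a biological variance component; with
  the default generator this is a few percent above nominal, and it
  would grow if biological spread dominated the measurement error.
* The bootstrap treats the AIF and reference fit as fixed; their
  uncertainty is not propagated into the BP_F standard errors.
* Single-pass IQR censoring is not idempotent for tiny heavy-tailed
  samples (n <= 8).
* Graphical kinetic methods (Logan, MA1), reference-tissue models and
  voxelwise maps are out of scope, as are image processing and ROI
  delineation.
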