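---
title: "Methods: positional tongue color differences with CIEDE2000"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positional tongue color differences with CIEDE2000}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonguecolor)
```

## The question and the measurement model

Tongue diagnosis in Kampo and TCM practice inspects tongue color, and
practitioners perform it with the patient either sitting or supine. If the
body position itself shifts tongue color, diagnoses made in different
positions are not comparable. This package quantifies that positional
effect: tongue color is expressed in CIE L\*a\*b\* (lightness L\*, red-green
a\*, yellow-blue b\*), the difference between a patient's sitting and supine
colors is measured with the CIEDE2000 color-difference formula
($\Delta E_{00}$), and the result is judged against the 50:50%
acceptability threshold used in dental colorimetry.

The pipeline has four stages, each a package module:

1. **Colorimetry** — sRGB $\to$ linear RGB $\to$ XYZ $\to$ L\*a\*b\*
   (D65, 2° observer by default) and the full CIEDE2000 formula.
2. **Segmentation** — tongue extraction by redness dominance and a
   ratio-based partition into edge, posterior, middle and apex regions;
   the *edge* region, least affected by tongue coating, carries the
   analysis.
3. **Position comparison** — per-patient $\Delta E_{00}$ with sitting as
   reference and supine as sample, classification against AT, and the
   cohort summary.
4. **Biometric association** — Pearson $r$ for numeric covariates and the
   correlation ratio $\eta^2$ for categorical ones, plus flagging of
   laboratory values above prompt-consultation reference criteria.

A synthetic generator stands in for the calibrated integrating-sphere
camera rig and provides ground truth for end-to-end validation.

## CIEDE2000 and its conventions

$\Delta E_{00}$ combines the lightness, chroma and hue differences
$\Delta L', \Delta C', \Delta H'$ (signed, sample minus reference) with
weighting functions $S_L, S_C, S_H$, parametric coefficients
$k_L : k_C : k_H = 1 : 1 : 1$, and the chroma-hue rotation term $R_T$:

$$\Delta E_{00} = \sqrt{\left(\tfrac{\Delta L'}{k_L S_L}\right)^2 +
\left(\tfrac{\Delta C'}{k_C S_C}\right)^2 +
\left(\tfrac{\Delta H'}{k_H S_H}\right)^2 +
R_T\,\tfrac{\Delta C'}{k_C S_C}\,\tfrac{\Delta H'}{k_H S_H}}$$

The implementation follows the standard's published implementation notes
exactly: hue angles in degrees; the $|h_1' - h_2'| > 180°$ wraparound in
both the hue difference and the mean hue; hue terms zeroed when either
primed chroma vanishes. These corner cases are exercised by the bundled
34-pair verification set (`ciede2000_reference_pairs()`), reproduced to
$10^{-4}$, and cross-checked against an independent implementation on
random pairs. Achromatic pairs reduce analytically to
$|\Delta L| / (k_L S_L)$, which the tests verify to $10^{-10}$.

Two presentation conventions matter when comparing against reported
tables: results are rounded only for display ($\Delta E_{00}$ to one
decimal, components to two), and acceptability is *strict* —
$\Delta E_{00} = \mathrm{AT}$ is unacceptable. The strict rule is forced by
the bundled cohort's own bookkeeping: the patient printed at exactly 4.1
belongs to the $\geq 4.1$ group (14, not 15, of 18 are acceptable).

## Color conversion choices

Consumer and scientific RGB cameras encode sRGB, whose native white is
D65; the conversion therefore defaults to sRGB companding with D65 and the
2° observer, with D50 (ICC Bradford-adapted matrix) as an option. No
chromatic-adaptation transform is applied. The chain is authored in the
package and validated two ways: against a frozen reference value for
neutral gray and against an independent conversion library over a random
RGB grid (agreement well under 0.05 $\Delta E_{00}$; the best available
references agree with it to ~0.01).

## The region partition

The classic ratio-based tongue partition defines edge, middle and top
regions by ratios of the tongue shape; the extended scheme used here adds
a posterior region so the four regions match 5-point practice. The ratios
are published only diagrammatically, so they are explicit configuration
with documented provisional defaults: posterior = 0.20 of the bounding-box
height from the top, apex = 0.20 from the bottom, and in each remaining
row an edge band of 0.15 of that row's tongue width *per side*. The edge
band follows each row's own tongue run rather than the bounding box, which
keeps it on the tongue outline for non-rectangular shapes. Every report
carries the ratios used. The partition is exact: the four regions tile the
mask, which is property-tested on random masks.

Region color is the arithmetic channel-wise mean over the region's pixels
(median available as an option): reported cohort tables give one Lab
triple per region, and the mean is the estimator whose standard error
($\sigma/\sqrt{N}$) the synthetic tests bound.

Tongue extraction itself is this package's design (the imaging rig's
internal algorithm is unpublished): per-pixel conversion to Lab, a
redness-dominance threshold (default $a^* > 12$, between neutral
backgrounds near 0 and tongue redness of 20-35, with $L^* > 5$ to drop
near-black pixels), largest connected component, hole filling — chosen for
determinism and testability. Precomputed masks can be supplied instead.

## The synthetic generator

The generator emulates what the integrating-sphere rig delivers: evenly
lit, gloss-free tongue images with no specular highlights. It paints a
vertically elongated superellipse mask (about 16,000 tongue pixels at the
default 180 x 140 frame; edge region ≈ 3,100 pixels) with per-region
L\*a\*b\* colors plus independent Gaussian noise per channel, converted to
sRGB. Its defaults are the study conditions the analysis targets, chosen
once:

* **Cohort size** 18, the bundled cohort's size.
* **Baseline edge color** (43, 27, 5.3), the cohort's mean sitting edge
  color; other regions are plausible light-red-tongue values.
* **Shift magnitudes** lognormal with `meanlog = log(2.34)` and
  `sdlog = 0.73`, so the median true shift equals the observed cohort
  median (2.34) and about 78% of shifts fall below AT = 4.1, matching the
  observed acceptability proportion.
* **Pixel noise** $\sigma = 2$ Lab units per channel.

Shift magnitudes are specified in $\Delta E_{00}$ units — the same scale
the analysis measures — and realized by bracketed root-finding
(`uniroot`, tolerance $10^{-8}$) on the scale factor of a random direction
drawn uniformly on the Lab unit sphere (a lightness-biased option exists,
since the largest observed positional differences are
lightness-dominated). Because the sRGB gamut is anisotropic around the
baseline, a magnitude unreachable along one direction redraws the
direction (up to 25 tries); a magnitude no direction can realize is a
per-patient error. Noise excursions outside the gamut are clipped and
counted per image; at the default conditions clipping is absent, so region
means are unbiased.

Biometric tables are drawn from an elderly-outpatient profile (age
≈ N(71, 13), blood pressure ≈ N(130/73), HbA1c ≈ N(6.1, 0.8), and so on),
and one covariate can be tied to the true shift as
`intercept + slope * dE00 + N(0, noise_sd)`; `slope_for_r()` converts a
target population correlation into the slope given the shift
distribution's analytic SD.

What the generator does **not** emulate: papillae and coating texture,
gloss, lighting gradients, pose and occlusion variation, or the true
(unknown) distribution of positional shift *directions*. Passing
end-to-end tests therefore demonstrate correctness of the measurement
chain under the stated noise model, not robustness to real photographic
variation — real deployments should validate segmentation on real frames.

## Validation studies and problem sizes

The test-suite studies, with their sizes chosen for tight statistical
bounds at interactive runtimes:

* **End-to-end recovery** — 40 replicates of render $\to$ segment $\to$
  partition $\to$ edge mean $\to$ $\Delta E_{00}$ at $\sigma = 2$;
  at least 95% must land within 0.2 of truth (observed: all within 0.1).
* **Mask recovery** — Jaccard $\geq$ 0.95 over 20 seeded replicates
  (observed: 1.0).
* **Association recovery** — 200 color-level cohorts of n = 18 with the
  slope set for population $r = 0.55$; the central 95% interval of
  recovered $r$ must cover 0.55. The *mean* recovered sample $r$ sits
  below the population value because a finite sample from the heavy-tailed
  lognormal typically under-represents its variance — an expected
  small-sample effect, not an estimator defect.
* **Null association** — with slope 0, $|r|$ stays below the two-sided 5%
  critical value at n = 18 (0.468) in about 95% of cohorts, the exact
  null sampling property of Pearson's $r$.

The statistical studies run the generator at the color level
(`render_images = FALSE`): the property under test concerns the Lab-level
pipeline, and rendering is exercised separately by the end-to-end study.

## Association analysis and reference flags

Pearson $r$ (with the two-sided $t$ p-value, $n-2$ df) serves numeric
covariates; $\eta^2$ = between-group SS / total SS (one-way ANOVA F
p-value) serves sex, smoking and — by this package's choice, since it is
categorical — cardiovascular-drug use. Missing values are deleted
pairwise, with `n_used` reported. No multiple-testing correction is
applied, matching how such exploratory cohort tables are conventionally
reported; treat the p-values accordingly. Association *magnitudes* are the
reproducible quantity; the bundled cohort's source table prints signs that
contradict its own accompanying text, and recomputation from the bundled
values yields positive correlations of the printed magnitudes.

The default reference criteria are the prompt-consultation cutoffs for
lifestyle disease: SBP $\geq$ 160 or DBP $\geq$ 100 mmHg (one item), TG
$\geq$ 500 mg/dL, FPG $\geq$ 126 mg/dL, HbA1c $\geq$ 6.5%, plus LDL-C
$\geq$ 180 mg/dL — the LDL item is required to reproduce the bundled
cohort's own flag marks, and HDL-C $\geq$ 100 is available as an optional
item. The criteria set is configurable and serialized with every run
configuration.

## A worked run

```{r}
tab <- compare_lab_table(tongue_cohort_lab())
attr(tab, "cohort_summary")
```

```{r}
assoc <- associate_covariates(tongue_cohort_lab()$dE00,
                              tongue_cohort_biometrics())
assoc[assoc$p_value < 0.05, ]
```

```{r}
split <- count_flags_by_group(tab, flag_table(tongue_cohort_biometrics()))
split
```

## Known limitations

* The partition ratios are provisional defaults, not measured against the
  original diagrammatic definition; conclusions that depend on exact
  region boundaries should sweep them.
* Segmentation is validated on synthetic renders only.
* The cohort is small (n = 18) and single-visit; association estimates
  carry wide sampling intervals, and the time course beyond ~3 minutes
  supine is outside this package's data.
* Signed component columns in the bundled table carry two transcription
  quirks (documented in the tests); $\Delta E_{00}$ itself verifies
  against independent implementations everywhere.
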