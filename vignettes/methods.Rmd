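---
title: "Automatic quantification of myocardium at risk in CE-SSFP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic quantification of myocardium at risk in CE-SSFP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marseg)
```

## The problem

Myocardium at risk (MaR) is the ischemic territory distal to an occluded
coronary artery; together with final infarct size it yields the myocardial
salvage index, the efficacy endpoint of reperfusion trials. On
contrast-enhanced SSFP (CE-SSFP) cine CMR acquired a few minutes after
gadolinium injection, MaR appears hyperintense relative to remote
myocardium, except where microvascular obstruction (MVO) suppresses
contrast arrival and leaves a hypointense core. `marseg` segments MaR
automatically from short-axis CE-SSFP stacks at end-diastole and
end-systole, given manual endocardial/epicardial contours, the culprit
artery, the right-ventricular insertion angle, and (optionally) a late
gadolinium enhancement (LGE) stack for infarct information. The output is
a MaR voxel mask per timeframe and MaR expressed as percent of
left-ventricular mass (%LVM).

## The pipeline

Four processing blocks run per timeframe:

1. **Surface-coil intensity correction.** Surface coils impose a smooth
   multiplicative gradient, roughly proportional to squared coil distance.
   We model it per slice as $\exp p(x,y)$ with $p$ a full second-order
   polynomial over normalized in-plane coordinates, fitted by least squares
   to log-intensities of two homogeneous sample classes: the blood pool
   (endocardial interior eroded one pixel) and the remote myocardium
   (outside the culprit territory). Each class's mean log-intensity is
   removed; because the classes occupy different parts of the field, the
   design additionally carries a blood-class indicator so that the
   between-class offset cannot distort the spatial coefficients — without
   it the field extrapolates badly into the culprit territory, the one
   region that has no samples. The corrected image is divided by the
   field and rescaled to preserve the remote mean. The correction is
   *conditional*: it is kept only if it reduces the remote coefficient of
   variation and leaves the culprit territory brighter than remote;
   otherwise the input passes through unchanged.
2. **EM intensity classification.** Myocardial intensities of the whole
   stack are modelled as a two-component Gaussian mixture (normal
   myocardium, MaR — CE-SSFP does not null myocardium, so a Gaussian
   rather than Rayleigh model is appropriate for both classes). The
   mixture is fitted by standard Expectation-Maximization, initialized
   from the a-priori territory (voxels inside the culprit maximal extent
   model seed the MaR class). The stack is fitted as a whole rather than
   per slice: block 1 has already removed the spatial gradient, and
   pooling maximizes sample size. We fit voxel samples directly instead of
   a binned histogram — binning is an approximation with no benefit at
   these sample sizes.
3. **A-priori regional criteria.** The myocardium is divided into 24
   circumferential sectors of 15° anchored at the anterior RV insertion.
   Within the culprit artery's maximal extent model (a per-artery,
   per-level sector table of the largest territory a proximal occlusion
   can produce), a sector is classified MaR when its mean MaR posterior
   exceeds 0.5; only the largest circumferentially contiguous run of
   flagged sectors survives on each slice, and flagged sectors are filled
   transmurally.
4. **LGE infarct fusion.** Infarct is, by definition, inside the MaR even
   when MVO makes it hypointense on CE-SSFP. The LGE stack is thresholded
   at remote mean + 1.8 SD; connected components smaller than 1 % of the
   myocardium are discarded, and enclosed hypointense regions are filled
   as MVO at 100 % infarction. Any CE-SSFP sector whose corresponding LGE
   sector (matched by slice-level third and sector index) contains infarct
   is forced into the MaR before continuity is re-enforced.

%LVM is computed per timeframe as `100 * |MaR| / |myocardium|` in voxel
counts (voxel volume and tissue density cancel) and averaged over ED and
ES; the combination rule is a package choice, as is processing the two
timeframes independently.

## Design choices where the design was open

* **Territory tables.** The expert-drawn maximal extent models used
  clinically are not published. The package ships a default derived from
  the standard AHA 17-segment coronary assignment mapped onto 24 sectors
  at three slice levels (basal/mid/apical by thirds of the delineated
  range), dilated by one 15° sector on each circumferential edge to
  represent the maximal extent of a proximal occlusion. LM is the union of
  LAD and LCx. The table is a CSV
  (`system.file("extdata", "territory_default.csv", package = "marseg")`)
  the user can replace; any result that depends on territory membership is
  configuration-sensitive in the same way the clinical implementation is.
* **Sector decision rule.** "Classification sector-wise" is implemented as
  mean posterior > 0.5 (strict), the natural sector aggregate, robust to
  single-voxel noise. Ties at exactly 0.5 are not flagged.
* **Continuity** is enforced per slice in circular sector order; ties
  between equal-length runs go to the run nearer the territory's angular
  center. Across-slice (3-D) continuity is deliberately not enforced — the
  sector-wise formulation is planar.
* **Fusion guarantee.** After fusion the labels are re-passed through
  continuity enforcement, but infarct-bearing sectors are always
  re-included afterwards: infarcted tissue is MaR by definition, and this
  also covers infarct falling outside an imperfect territory table (which
  is fused with a warning rather than dropped).
* **No-signal guard.** A two-component EM applied to a myocardium without
  MaR will happily split noise into two classes and segment ~25 %LVM of
  nothing. MaR is therefore only segmented when the culprit territory is
  measurably hyperintense: mean culprit intensity must exceed the remote
  mean by a relative margin (`min_contrast_margin`, default 0.03) on the
  flattest available image (the bias-corrected candidate, even when the
  conditional correction was declined for output). The margin sits well
  above the residual territory tilt left by an imperfect polynomial
  correction (≤ ~2 %) and well below the weakest in-scope signal (a 60°
  wedge at contrast 1.2 inside the largest territory elevates the
  territory mean by ~6 %). Patients in the validated clinical setting all
  carry MaR; this guard exists for the degenerate no-MaR input.
* **Sector binning** is half-open, `[a, a + 15°)`, counterclockwise from
  the anterior insertion; slices are ordered base to apex; voxel indices
  are 0-based in all serialized output.
* **Baselines** (2SD-from-remote, FWHM, Otsu with a 256-bin equal-width
  histogram) are computed and applied slice by slice on *uncorrected*
  intensities, as standalone competitors; masks use strict `>`.

## Numerical choices

EM runs to a relative log-likelihood change below 1e-6 or 500 iterations,
with component SDs floored at 1e-3 of the intensity range to prevent
collapse (clamping is flagged in the provenance). The equal-posterior
decision threshold is solved in closed form from the quadratic equality of
weighted log-densities, taking the smallest upward crossing. Slices whose
blood pool erodes away (apical end-systole) inherit the bias-field
coefficients of the nearest fitted slice; slices with 1–6 samples in a
class are rejected as underdetermined. Degenerate inputs error early:
all-equal intensities, empty remote regions, territories covering all 24
sectors (remote undefined), endocardium not contained in the epicardium.

## The phantom generator

Patient data from the validating trials are not public, so the package
includes a synthetic generator that encodes the pipeline's assumptions as
generative truth: an annular myocardium over 8 slices (128×128, 1.5 mm
in-plane, 8 mm slices) at ED and ES (ES radii scaled by 0.85 with
mass-preserving wall thickening, mild base-to-apex taper), a transmural
circumferentially contiguous MaR wedge clipped to the culprit territory, an
infarct sub-wedge with an optional mid-wall MVO core, a multiplicative
second-order coil field, and additive Gaussian noise. Base intensities are
arbitrary units: normal myocardium 1.0, blood 1.8, background 0.1; the MVO
attenuation 0.7 is chosen so that the core falls *below* the normal mean
(0.7 × 1.3 < 1), defeating intensity classification by construction — the
fixture that makes block 4 testable. The default coil field is an
anterior-coil ramp (~30 % swing across the ventricle); the LGE stack has
nulled viable myocardium (0.2), hyperenhanced infarct (1.0) and a
hypointense core (0.22) with SD-0.03 noise.

Cohorts sample wedge extent 60–150°, contrast ratio 1.2–1.5, noise SD
2–10 % of the normal mean, culprit from {LAD, LCx, RCA}, with an MVO core
in every second case — conditions that put truth MaR in a clinically
plausible 10–40 %LVM band and infarct/MVO sizes near reported acute-infarct
distributions. Evaluation problem sizes in the test suite use this 50-case
cohort; most unit tests use a coarser 64×64 (3 mm) phantom for speed.

What the phantom does *not* emulate matters for interpreting green tests:
there are no acquisition artifacts, no hyperintense slow-flow blood rim,
no papillary muscles, no motion, no banding, and contours are exact. EM
classification is therefore much stronger on phantoms than on trial data,
which has two consequences. First, absolute Dice values (~0.92 at cohort
level) sit above the real-data level and say nothing about clinical
accuracy. Second, the incremental value of the a-priori block is
understated: on trial images it removes out-of-territory artifacts; on the
phantom there are none to remove, while it still pays the sector
quantization cost and — in MVO cases — drops the hypointense sectors that
only block 4 can restore. The cohort-level block progression therefore
shows a characteristic dip at the a-priori stage in MVO cases (mirrored in
the bias trace, which swings negative at that stage and recovers with LGE
fusion) rather than a monotone Dice increase; the corresponding
bias pattern is the expected signature of hypoenhancement handling, not a
regression.

## Known limitations

Manual contours are inputs, not outputs; only two timeframes are
supported; the LGE infarct helper is a simplified delineation (threshold,
minimum region size, MVO fill) without partial-volume weighted summation,
sufficient for sector-level fusion but not for infarct-size reporting; LGE
and CE-SSFP are matched by slice-level thirds and sector index, not by
deformable registration; and territory tables are configurable
approximations of expert knowledge.
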