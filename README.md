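# marseg

Automatic segmentation of **myocardium at risk (MaR)** in contrast-enhanced
SSFP (CE-SSFP) cardiac MR.

After an acute coronary occlusion, the ischemic territory at risk of
infarction appears hyperintense on CE-SSFP cine images acquired a few
minutes after gadolinium injection. Quantifying MaR together with final
infarct size gives the myocardial salvage index (1 − MI/MaR), the endpoint
that lets reperfusion trials run with fewer patients. Manual delineation of
MaR is slow and subjective; `marseg` provides an automatic pipeline for
researchers working with short-axis CE-SSFP + LGE studies, along with the
standard threshold baselines, validation statistics, and a synthetic
phantom generator so every stage can be exercised without patient data.

## The algorithm

Inputs: CE-SSFP stacks at end-diastole and end-systole with manual
endocardial/epicardial contours, the culprit artery (LAD / LCx / RCA / LM),
the anterior right-ventricular insertion angle, and optionally an LGE stack.
Four blocks run per timeframe:

1. **Surface-coil intensity correction** — a second-order polynomial bias
   field `exp p(x, y)` fitted per slice to blood-pool and remote-myocardium
   log-intensities; applied only if it reduces remote variability and
   leaves the culprit territory brighter than remote.
2. **EM classification** — a two-component Gaussian mixture over myocardial
   intensities, `I ~ (1−w)·N(μ_normal, σ²_normal) + w·N(μ_MaR, σ²_MaR)`
   with `μ_MaR ≥ μ_normal`, fitted by Expectation-Maximization and
   initialized from the culprit artery's maximal-extent territory.
3. **A-priori regional criteria** — the myocardium is divided into 24
   circumferential sectors from the RV insertion; a sector inside the
   territory is MaR when its mean MaR posterior exceeds 0.5; only the
   largest contiguous run survives per slice, filled transmurally.
4. **LGE infarct fusion** — infarct from the LGE stack (remote mean +
   1.8 SD threshold, minimum region size, enclosed hypointense cores
   counted as 100 % infarction) forces its sectors into the MaR, so
   microvascular obstruction is not lost to its hypoenhancement.

MaR is reported as percent of left-ventricular mass (%LVM), averaged over
ED and ES. Baselines (2SD-from-remote, FWHM, Otsu) are applied slice by
slice for comparison, and the metrics module provides Dice, Bland-Altman
bias and limits of agreement, correlation, and Bonferroni-corrected paired
t-tests for block-ablation analyses.

## Worked example

```r
library(marseg)

case <- generate_case(phantom_spec(seed = 42, wedge_extent = 100, contrast = 1.3))
res  <- run_segment_mar(case$study)
res
#> <mar_result> MaR 25.7 %LVM (ED 26.5, ES 24.9), culprit LAD

dice(res$masks, case$truth$mar)        # regional agreement vs ground truth
#> 0.93
case$truth$percent_lvm                 # generative truth
#> 27.8
res$provenance$ED$correction$applied   # block-level audit trail
#> TRUE
```

The phantom plants a 100° transmural MaR wedge (truth 27.8 %LVM) in the
LAD territory under a coil gradient and noise; the pipeline recovers
25.7 %LVM with Dice 0.93. The provenance records each block's decisions:
here the coil correction was accepted (remote coefficient of variation
0.103 → 0.080) and the mixture fit separated normal myocardium
N(0.948, 0.080²) from MaR N(1.226, 0.095²). The same study through the
baselines gives 2SD 29.5 %LVM (Dice 0.849), FWHM 23.4 (0.914) and Otsu
24.7 (0.926).

Cohort-level evaluation, including the per-block ablation and baseline
comparison:

```r
cases <- generate_cohort(50, seed = 1)
ev <- evaluate_cohort(cases, baselines = TRUE, ablation = TRUE)
ev$report          # bias, limits of agreement, R, Dice mean/SD
```

A thin command-line wrapper is installed with the package
(`system.file("cli", "mar.R", package = "marseg")`) with subcommands
`run`, `baseline`, `phantom` and `evaluate`; studies on disk are NIfTI
volumes plus a JSON annotation sidecar (see `?write_study`).

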