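# rilfi

Radiobiological modelling of radiation-induced lung fibrosis (RILF) from
quantitative CT, for preclinical radiation oncology: researchers
characterizing late lung toxicity in mouse models and anyone who needs the
standard isoeffect / biologically-effective-dose (BED) toolkit around a
CT-derived severity score.

## What it computes

Late lung fibrosis leaves two CT signatures: mean lung density rises and
aerated lung volume shrinks. Against an age-matched reference cohort these
combine into the **fibrosis index**

    FI = sqrt(ΔHU↑ × ΔV↓)

the geometric mean of the relative density increase and relative volume
decrease (clamped to 0 with a flag when the pattern is not fibrotic).
Mean FI versus total dose D follows a probit-type sigmoid

    FI(D) = ½ A { 1 − erf( √π γ (1 − D/ED₅₀) ) }

with saturation A (maximal FI, fixed at 7.20 by default), midpoint dose
ED₅₀ and normalized gradient γ; the model inverts in closed form, giving
isoeffective doses at any FI level. From two fractionation arms the package
estimates the fractionation-sensitivity ratio **α/β** of the
linear-quadratic (LQ) model three ways — isoeffect pairing
(α/β = (D₂d₂ − D₁d₁)/(D₁ − D₂)), the Fe plot (reciprocal total isoeffect
dose vs dose per fraction; α/β = intercept/slope) and LQ regression on
−log₁₀(FI) — maps every schedule to BED = D(1 + d/(α/β)), fits the
FI-vs-BED log-logistic

    FI(BED) = A₂ + (A₁ − A₂) / (1 + (BED/k)^p)

and extracts its landmarks: the fibrosis-initiation threshold BED_Tr
(maximum curvature), the cut-off (maximum slope, closed form
k((p−1)/(p+1))^(1/p)) and BED_ED50 (half-maximal FI). An
inverse-variance meta-pooling step with forest-table output covers
literature synthesis of α/β estimates.

The imaging stage (seeded 3D region growing in the −900..−100 HU window,
volume/density metrics, smoothed-histogram peak diagnostic) and a
synthetic-data layer (two-arm cohort simulator, exact-truth voxel phantoms)
make the whole chain runnable and testable without animal data.

## Worked example

Simulate the two-arm study design (single fractions 0–20 Gy, five daily
fractions of 0–8.5 Gy, 12 mice per dose group) from known dose-response
truths, then run the full analysis:

```r
library(rilfi)

truth <- list(`1fx` = fi_model(A = 7.20, ed50 = 14.55, gamma = 1.64),
              `5fx` = fi_model(A = 7.20, ed50 = 27.7,  gamma = 1.41))
report <- run_pipeline(pipeline_config(truth = truth,
                                       noise = noise_spec(fi_sd = 0.2, seed = 1)))

print(report$fits[["1fx"]])
#> FI-model (probit-type sigmoid)
#>   A     = 7.2000 FI units (fixed)
#>   ED50  = 14.5145 ± 0.0401 Gy
#>   gamma = 1.6690 ± 0.0285
#>   adj. R2 = 0.9945 (n = 72)

cat(sprintf("alpha/beta (isoeffect profile mean): %.2f Gy\n", report$alpha_beta_gy))
#> alpha/beta (isoeffect profile mean): 4.51 Gy

print(report$bed_fit)
#> FI-vs-BED log-logistic fit
#>   A1 = 0.0000, A2 = 7.7376 FI units (fixed: A1)
#>   k  = 63.486 Gy, p = 3.457
#>   landmarks: BED_Tr = 31.07, cutoff = 53.44, BED_ED50 = 63.49 Gy
#>   adj. R2 = 0.9952 (n = 144)
```

Reading the output: the refitted ED₅₀ of 14.51 ± 0.04 Gy recovers the
generating 14.55 Gy within its standard error; the α/β of ~4.5 Gy marks
the lung as a late-responding, fraction-size-sensitive tissue; and the BED
landmarks say fibrosis initiates near BED ≈ 31 Gy, rises fastest near
53 Gy, and reaches half its maximum near 63 Gy for this simulated cohort.

The `analysis/` directory holds the same chain as numbered narrative
scripts (`01_simulate_cohort.R` … `06_phantom_imaging.R`), each writing its
tables under `results/`. The methods vignette
(`vignettes/rilf-modelling.Rmd`) documents the models, conventions and
limitations.

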