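# axoscale

Quantitative tools for studying **size scaling during axolotl limb
regeneration**. Axolotls regenerate a correctly proportioned limb from
blastemas of very different sizes, which suggests scale-invariant patterning
mechanisms. This package implements the analysis pipeline used to
characterise that invariance: allometric regression of blastema and
expression-domain sizes, a diffusion–degradation model of the SHH gradient,
the geometry of the Shh/Fgf8 signalling crosstalk region, and the
quantification of cell-density/proliferation profiles from tissue sections.
It is aimed at developmental biologists and modellers working on
morphogen-based patterning and morphometrics.

## What it computes

**Allometry.** Trait sizes follow power laws
*y* = *k·x*^α (equivalently log *y* = α·log *x* + log *k*). `fit_power_law()`
estimates (*k*, α) by nonlinear least squares on the original scale
(log–log OLS supplies starting values), and `bootstrap_exponent_sd()`
quantifies the exponent uncertainty by case-resampling. α = 1 is isometry;
α < 1 means the trait becomes relatively smaller in larger animals.
`relative_size_curve()` gives *y/x* = *k·x*^(α−1) and
`compose_allometries()` chains exponents (if *z* ∝ *y*^a and *y* ∝ *x*^b,
then *z* ∝ *x*^(ab)).

**Morphogen model.** The steady state of
∂S/∂t = D·∂²S/∂x² − γS + s₀·1[x ≤ θ] on a blastema of size *L* with
zero-flux ends, where the *Shh* source size scales as θ = 2.1·*L*^0.69 (µm).
With β = √(γ/D), the closed form is
S = (s₀/γ)(1 − A·cosh βx) inside the source and
S = (s₀/γ)·B·cosh β(L−x) outside, with
A = sinh β(L−θ)/sinh βL and B = sinh βθ/sinh βL.
`ptch1_profile()` applies the Hill readout S^h/(K^h + S^h) and
`diffusion_range_invariance()` shows the *Shh*→*Ptch1* anterior boundary
distance is nearly constant across blastema sizes because the decay length
β⁻¹ is a physical constant. A finite-difference oracle
(`numeric_steady_state()`) validates the closed form.

**Crosstalk-region geometry.** `crosstalk_region()` builds Ω_SF — the
interval from the posterior end of *Shh*(+) to the anterior end of
*Fgf8*(+) — and `proportions_from_equations()` shows that the Shh- and
Fgf8-dominant shares within Ω_SF, computed from the fitted laws
S = 2.1·L^0.69, F = 23·L^0.44 and a constant 170 µm gap, stay near 47%/53%
across blastema sizes from 500 to 3000 µm. `digit_position_stats()`
compares the variability (CV) of first-digit positions under Ω_SF- versus
blastema-size normalisation.

**Axial profiles.** `section_axial_profile()` reproduces the image
quantification chain — binarization (Otsu or manual), epithelium exclusion,
projection onto the A-P axis, normalisation by local mesenchyme width and
by the median, and a 50-sample moving average — and `fit_unimodal()` fits a
Gaussian process (squared-exponential kernel, marginal-likelihood
hyperparameters) to pooled Ω_SF-rescaled profiles, returning the mean
curve, a 95% band and the peak position.

**Synthetic data.** `generate_cohort()`, `generate_section_image()` and
`generate_digit_positions()` produce measurement tables and multi-channel
section images that obey configured scaling laws with lognormal noise, so
the whole pipeline can be exercised and validated end to end.

## Worked example

```r
library(axoscale)
cfg <- pipeline_config(cohort = cohort_config(n_specimens = 31, seed = 1),
                       n_boot = 200, seed = 8)
report <- run_pipeline(cfg, quiet = TRUE)
print(report)
```

```
Regeneration-scaling report (seed 8)
  limb_vs_animal     y = 0.392 x^0.884 (s.d. 0.0693, n = 31)
  blastema_vs_stump  y = 1.28 x^0.597 (s.d. 0.0466, n = 31)
  shh_vs_blastema    y = 2.7 x^0.666 (s.d. 0.0745, n = 31)
  fgf8_vs_blastema   y = 10.7 x^0.54 (s.d. 0.0689, n = 31)
  omega_vs_blastema  y = 28 x^0.501 (s.d. 0.0453, n = 31)
  reglimb_vs_stump   y = 1.08 x^0.446 (s.d. 0.035, n = 31)
  dominant-region shares: Shh 49% / Fgf8 51%
  morphogen-range spread across sizes: 55.2 um
  density-profile peak: 0.65 of the crosstalk region
  digit CV: 0.115 (crosstalk) vs 0.278 (blastema)
```

Reading the output: each line is a fitted allometric law with the bootstrap
s.d. of its exponent on one synthetic cohort of 31 specimens generated from
the measured laws (limb width 0.38·length^0.90, blastema 1.2·stump^0.61,
*Shh*(+) 2.1·L^0.69, *Fgf8*(+) 23·L^0.44, regenerating limb 1.1·stump^0.43)
with 15% lognormal noise — single-cohort estimates scatter around the
generative exponents by roughly their bootstrap s.d. The dominant-region
shares are close to the scale-invariant 47%/53% split; the morphogen
signalling range varies by only ~55 µm while blastema size varies 3.3-fold;
the recovered cell-density peak sits near 60% of the crosstalk region from
its posterior end; and digit positions are markedly less variable when
normalised by the crosstalk region than by blastema size.

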