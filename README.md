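# cerebromech

Quantitative analysis of cerebral artery wall remodeling: biaxial
extension–inflation mechanics, elastic-fiber "empty band" image statistics,
polarizer-stepped birefringence microscopy, and the accompanying
composition and group-comparison statistics — with seeded synthetic-data
generators providing exact ground truth for every input modality.

## The problem

Cerebral arteries stiffen and their wall microstructure degrades with
neurodegenerative disease. Quantifying that remodeling needs four distinct
measurements tied together:

1. **Wall mechanics.** A mounted artery segment held at axial stretch
   λ_z = l/L is pressurized while a myograph records transmural pressure
   *P*, outer diameter 2r_o, and axial force f_T. Assuming wall
   incompressibility, the deformed inner radius is
   r_i = √(r_o² − (R_o² − R_i²)/λ_z), the mid-wall circumferential stretch
   is λ_θ = (r_o + r_i)/(R_o + R_i), and the mean Cauchy stresses are

   σ_θ = P·r_i/(r_o − r_i),  σ_z = (f_T + P·π·r_i²)/(π(r_o − r_i)(r_i + r_o)).

   Stretch is normalized by the zero-pressure state; the stress–stretch
   curve is fitted with σ(λ) = α(e^{β(λ−1)} − 1), whose tangent stiffness
   dσ/dλ = αβe^{β(λ−1)} is reported at 80 mmHg. The in vivo axial stretch
   is the λ_z at which axial force is insensitive to pressurization.

2. **Empty-band quantification.** Binarized multiphoton projections of the
   elastic-fiber network are discretized into a 30 × 30 grid; per-column
   fiber area fractions falling two standard deviations below the media
   mean (for the reference cohort: 31.8% − 2 × 8.5% = 14.8%) define a
   fiber-depleted band at the media–adventitia interface, whose width is
   reported in micrometres.

3. **Birefringence microscopy.** Six frames acquired at polarizer angles
   0°, 30°, …, 150° follow I(θ) = a₀(1 + r·sin 2(θ − φ)) per pixel;
   discrete-Fourier inversion recovers the relative retardance r and
   optic-axis orientation φ, rendered as retardance-weighted orientation
   maps.

4. **Statistics.** Normality-gated two-group comparisons (Shapiro–Wilk
   gate: pooled t-test if both groups normal, Mann–Whitney otherwise),
   collagen composition as percent of total collagen abundance with
   Bonferroni-corrected Welch tests, and per-protein differential
   abundance with Benjamini–Hochberg FDR control.

The package is aimed at vascular biomechanics and quantitative microscopy
labs who want these analyses reproducible end to end, and testable against
simulated experiments with known ground truth.

## Worked example

```r
library(cerebromech)

# simulate one depressurization cycle (80 -> 0 mmHg) and analyze it
sim <- simulate_inflation(seed = 7)
rec <- analyze_inflation(sim$records, sim$geometry, lambda_z = sim$lambda_z)
head(rec[, c("pressure_mmHg", "outer_diameter_um",
             "lambda_theta_norm", "sigma_theta_kPa")], 4)
#>   pressure_mmHg outer_diameter_um lambda_theta_norm sigma_theta_kPa
#> 1            80             2219.              1.15            65.3
#> 2            70             2196.              1.13            55.7
#> 3            60             2175.              1.12            46.6
#> 4            50             2152.              1.11            37.8

fit <- fit_stress_stretch(rec)
glance(fit)
#>   alpha_kPa  beta residual_rms_kPa converged degenerate     n
#> 1      21.6  9.58            0.318 TRUE      FALSE          9
```

The simulated material had α = 20 kPa and β = 10; the fit recovers them
through ~0.05% diameter measurement noise. Tangent stiffness at the 80 mmHg
stretch and the in vivo axial stretch:

```r
tangent_stiffness(fit, rec$lambda_theta_norm[rec$pressure_mmHg == 80])
#> [1] 836.9  # kPa
find_in_vivo_stretch(axial_force_surface(sim$material))$lambda_z
#> [1] 1.12   # the generator's built-in value
```

Empty-band detection on a synthetic fiber scene with a known 32 µm gap
(grid columns are 14 px wide here, so recovery is exact to ±1 column):

```r
sc <- generate_fiber_image(fiber_scene_params(gap_width_um = 32), seed = 7)
roi <- c(sc$annotation$media[1], sc$annotation$adventitia[2], 1, nrow(sc$image))
measure_empty_band(sc$image, sc$annotation, roi = roi)
#>   n_columns col_start col_end width_um   tau
#> 1         2        15      16       28 0.195
```

Cohort summary formatting (mean ± SD at one decimal):

```r
donor_ages() |> summarize_by_group(age, group, mode = "sd")
#>   group            n  mean    sd  label
#> 1 control          4  71.5  9.81  71.5 ± 9.8
#> 2 early            4  69.8  8.18  69.8 ± 8.2
#> 3 intermediate     3  75    5.29  75.0 ± 5.3
#> 4 advanced         8  73   12.6   73.0 ± 12.6
```

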