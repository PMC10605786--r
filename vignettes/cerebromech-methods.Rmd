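---
title: "Models and methods in cerebromech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cerebromech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerebromech)
```

This vignette is the package's own account of its models: what each
analysis assumes, which parameters matter, how the synthetic-data
generators were designed, and where genuinely open design choices were
resolved.

## Extension–inflation mechanics

A cylindrical artery segment is treated as a thin-walled, incompressible
tube loaded by transmural pressure $P$ and an axial force $f_T$ at fixed
axial stretch $\lambda_z = l/L$. The reference state comes from ring
perimeters traced at the segment ends; we assume circular cross-sections
($R = \text{perimeter}/2\pi$) and average the two end rings
arithmetically. Incompressibility ties the deformed inner radius to the
measured outer radius,
$r_i = \sqrt{r_o^2 - (R_o^2 - R_i^2)/\lambda_z}$, which makes the identity
$\lambda_z (r_o^2 - r_i^2) = R_o^2 - R_i^2$ hold to machine precision for
every derived record — the test suite asserts a relative error below
$10^{-12}$. The mid-wall circumferential stretch is
$\lambda_\theta = (r_o + r_i)/(R_o + R_i)$ and the mean Cauchy stresses
are the thin-wall statics expressions in kPa.

**Units.** Pressures are stored in mmHg and converted once, at
133.322 Pa/mmHg; forces in mN; lengths in µm (radii) and mm (segment
length); stresses reported in kPa. A single declared conversion point
avoids silent unit errors across the mixed-unit instrument outputs.

**Normalization.** Circumferential stretch is divided by the value at the
0 mmHg record of the same cycle, so the unloaded record maps to exactly 1.
The exponential fit is performed on this normalized stretch; fitting raw
stretch simply amounts to passing a different column to
`fit_stress_stretch()`.

**Thickness.** The reported `thickness_um` is the undeformed
$R_o - R_i$. A loaded-state thickness ($r_o - r_i$ at a given pressure) is
available from the derived record table; the reference-state definition
was chosen because the ring measurement itself is unloaded.

**In vivo stretch.** The in vivo axial stretch is located by grid search
(default $\lambda_z \in [1.00, 1.30]$ in steps of 0.01) as the stretch
minimizing the variation of axial force over the 0–80 mmHg sweep.
"Variation" is not uniquely defined by the protocol description; the
standard deviation is the default and the range is selectable
(`objective = "range"`). Ties break toward the smaller stretch, and a
surface whose variation is identical across all candidates raises a
non-identifiability error rather than returning an arbitrary grid point.

## Exponential stiffness fit

The stress–stretch curve is fitted with
$\sigma(\lambda) = \alpha\,(e^{\beta(\lambda - 1)} - 1)$. The exact
functional form of "an exponential fit" is a design choice here: this form
enforces $\sigma(1) = 0$ at the normalized reference state, has positive
parameters for physically stiffening tissue, and gives the closed-form
tangent stiffness $\alpha\beta e^{\beta(\lambda-1)}$. A constant offset
term was deliberately not included, because it would break the zero-stress
anchor that the stretch normalization establishes.

Initialization uses the geometry of the curve itself: successive stress
increments of an exponential grow by $e^{\beta\,\Delta\lambda}$, so
$\beta_0$ comes from the log-ratio of the last two increments and
$\alpha_0$ from matching the final point. Refinement is
Levenberg–Marquardt (`minpack.lm::nlsLM`) with `ftol = ptol = 1e-10` and
positivity bounds. All-zero stress data return a flagged degenerate
result ($\alpha = 0$, `converged = FALSE`) instead of erroring, and any
non-convergence is carried in the result object, never silent. The fit is
equivariant to stress rescaling (multiplying $\sigma$ by $c$ multiplies
$\alpha$ and the tangent by $c$, leaves $\beta$ unchanged), which the
suite checks.

Group stiffness-versus-pressure curves are means across samples of
`stiffness_vs_pressure()` values at matched pressures, with dispersion as
SEM — the package-wide reporting default (`summarize_values()`).

## Empty-band quantification

The analysis works on a binarized projection with the wall aligned so
layers vary along image columns. Binarization defaults to Otsu's
between-class-variance threshold (via EBImage) after range-normalizing
the image, which makes the detected band invariant to uniform intensity
scaling; a manual threshold is available. Foreground means signal-bearing
(fiber) pixels — the same quantity as "black pixels" on an inverted
display convention.

The region of interest is discretized into a 30 × 30 grid. Cell edges use
integer flooring with remainder pixels merged into the last row/column:
deterministic, and documented here because no convention is prescribed by
the protocol. A column's value is the mean of its 30 cell fractions.

The detection threshold is $\tau = \mu - 2\sigma$ of the *media* column
fractions (sample SD). The protocol sentence describing the threshold
mentions media and adventitia ambiguously, but the printed cohort
threshold (14.8%) equals the printed media statistics alone
($31.8\% - 2 \times 8.5\%$), so media-only statistics are the default;
`layers = c("media", "adventitia")` is available for sensitivity
analysis, and a `pooled` mode accepts externally supplied $(\mu, \sigma)$
to reproduce a study-wide threshold. Whether per-image or pooled
statistics were used originally is not stated; both modes are provided
and neither is asserted as canonical.

A band is a *contiguous* run of sub-threshold columns overlapping the
annotated media–adventitia interface window (isolated sub-threshold
columns deep inside the media are not a band). If no column falls below
$\tau$ the width is 0 ("unnoticeable"); if several runs span the
interface the function raises an ambiguity error listing the candidates
rather than choosing silently. Layer annotation is user-supplied pixel
column ranges; automatic layer segmentation is out of scope. Per-sample
widths average the per-location measurements (four locations in the
reference protocol), with $n-1$ SD.

## Polarization-stack inversion

The forward model is $I(\theta) = a_0(1 + r \sin 2(\theta - \varphi))$
with the polarizer stepped through $\theta_k = k \cdot 30°$, $k = 0..5$.
Because $2\theta$ then samples the full circle at 60° steps, the harmonic
coefficients follow from exact discrete-Fourier orthogonality:
$a_0 = \overline{I}$, $c = \tfrac13\sum I_k \cos 2\theta_k$,
$s = \tfrac13\sum I_k \sin 2\theta_k$, giving
$r = \sqrt{c^2 + s^2}/a_0$ and
$\varphi = \tfrac12\,\mathrm{atan2}(-c, s)$ wrapped to $[0, \pi)$. The
sign and offset convention — $\varphi$ measured counterclockwise from the
horizontal image axis — is pinned by the synthetic forward model and
documented as a convention, not a claim about any particular instrument.
Retardance is reported as the normalized modulation ratio in $[0, 1]$; no
conversion to nanometres of optical path difference is attempted.

Pixels with $a_0 \le 0$ are masked invalid, and orientation is masked
where $r$ falls below a floor (default 0.02, configurable) because hues
are meaningless in effectively isotropic pixels. One documented
consequence of the normalization: adding a constant intensity offset to
all frames inflates $a_0$ and strictly deflates $r$ — unpolarized
background light biases relative retardance downward. Frames are assumed
co-registered; no alignment is performed.

Rendering maps $\varphi$ to hue on a π-periodic wheel and $r$ to
brightness, so orientations 90° apart appear as diametric hues of equal
brightness.

## Proteomics and group statistics

Collagen composition divides each type's summed abundance by the
sample's total collagen abundance (percentages sum to 100 by
construction); group comparison per type is a two-sided Welch t-test on
the percentages with Bonferroni correction over the number of quantified
types (12 in the reference profile). The original analysis tooling does
not state its test, equal-variance assumption, or whether percentages or
raw abundances were compared; Welch on percentages is the choice here,
made once and flagged as such. Samples with zero total collagen are
excluded with a warning.

Differential abundance log2-transforms intensities with zeros imputed at
half the protein's minimum positive value, excludes proteins missing in
more than half of either group (flagged, not tested), runs two-sided
Welch t-tests, and controls FDR with Benjamini–Hochberg across tested
proteins (significance at FDR < 0.05). The suite checks the BH ordering
contract — adjusted values between raw p and Bonferroni, monotone in raw
p — and that the null discovery fraction stays near nominal.

Scalar outcomes use the normality-gated comparison: Shapiro–Wilk on each
group at $\alpha = 0.05$; a pooled-variance independent t-test if both
pass, Mann–Whitney otherwise. When exactly one group is non-normal the
rank test is used — the conservative reading of the gate, since the
protocol does not state this case. Zero-variance samples are treated as
maximally non-normal (Shapiro–Wilk is undefined for them). The pooled
t-test here intentionally contrasts with the Welch choice in the
proteomics module: the former mirrors "independent t-tests" in the
group-comparison protocol, the latter is the label-free proteomics
default. Report strings round half away from zero at one decimal, the
convention of the cohort tables.

## Synthetic-data generators

The generators define the study conditions for validation; their defaults
were chosen once.

**Inflation simulator.** The circumferential law
$\sigma_\theta = c_\theta(e^{b_\theta(\lambda_\theta - 1)} - 1)$ with
defaults $c_\theta = 20$ kPa, $b_\theta = 10$ produces stresses of a few
tens of kPa at 80 mmHg for the default geometry — the physiological range
for cerebral arteries. Geometry defaults ($R_o = 1000$ µm,
$R_i = 800$ µm, $L = 10$ mm) put the vessel in the 2 mm outer-diameter
class. The axial surface
$f_T = F_0 + k_f(\lambda_z - \lambda_z^*)P$ (defaults $F_0 = 19$ mN near
the control-group force scale, $k_f = 1.5$ mN/mmHg,
$\lambda_z^* = 1.12$, a typical cerebral in vivo stretch) is
phenomenological — linear in pressure with the pressure dependence
vanishing at $\lambda_z^*$ — chosen over a full two-dimensional
constitutive law precisely so the in vivo stretch ground truth is exact
by construction. Equilibrium $P r_i/(r_o - r_i) = \sigma_\theta$ is
solved per pressure by bracketed root finding (`uniroot`, tolerance
$10^{-11}$ µm); the zero-pressure equilibrium forces
$\lambda_\theta = 1$ exactly, so raw and normalized stretch coincide on
simulator output and $(c_\theta, b_\theta)$ is exactly the ground truth
of the normalized fit. Measurement noise is additive Gaussian on diameter
(default SD 1 µm) and force (0.1 mN). No hysteresis or preconditioning is
modeled: the simulator emits a single equilibrium limb.

**Fiber scenes.** Layers (intima | media | gap | adventitia) vary along
x; straight fiber segments (length 20–60 px, width 2–3 px, uniform
orientation) are placed region by region until target area fractions are
reached — defaults 0.318 (media) and 0.478 (adventitia), the reference
cohort's printed fractions, with gap occupancy 0.02. Segment centers are
drawn from a margin extending half a fiber length beyond each region so
the clipped density stays uniform up to region borders; without this, the
clipping depletes border columns and fakes a band at the layer seam. The
scene emulates the *column statistics* of a projected fiber network, not
its biology: no curvature, tortuosity, anisotropy, or optical blur. A
passing gap-recovery test therefore shows the grid statistic and
threshold logic are correct, not that real elastin images binarize this
cleanly.

**Polarization stacks** apply the forward model exactly, plus optional
Gaussian intensity noise — no polarizer miscalibration, photon noise
statistics, or registration error.

**Abundance tables** draw per-type percentages from group-specific
Gaussian profiles (the reference composition profile's means and SDs,
truncated at a small positive floor) scaled by a log-normal total, plus
optional log-normal non-collagen proteins with known log2 effects.
Group sizes default to 5 control vs 6 case. One detail of the reference
profile: the type XII control SD prints as 0.00 at two decimals; the
generator uses 0.004 (half the rounding unit) so the type is not
degenerate.

All generators are deterministic under a fixed seed; regeneration is
byte-identical (tested).

## Problem sizes and numerical tolerances

The test suite and acceptance script use: 9-record cycles (80→0 mmHg by
10); 100 replicate fits at 1% multiplicative stress noise; a ladder of
five gap widths (0–64 µm) on ~300 × 430 px scenes; 100 × 100 px
polarization stacks ($10^4$ pixels) at noise SD 1% of $a_0$; 1000 null
replicates (n = 10 per group) for the gated procedure's type-I error; and
a 62-protein table for the FDR contracts. These sizes make every check
sharp at interactive runtimes. Root-finding and fit tolerances are stated
above; identity checks assert $10^{-12}$ relative error, round trips
machine precision.

## Known limitations

- Thin-wall, mid-wall-averaged stresses only: no radial stress
  distribution, residual stress/opening angle, viscoelasticity, or active
  smooth-muscle tone.
- Only the circumferential direction is fitted; axial stress is computed
  but not modeled.
- Layer annotation is manual; the band statistic inherits any annotation
  error.
- Relative retardance is not converted to physical retardance, and the
  orientation convention is instrument-agnostic by construction.
- Peptide-to-protein rollup, database search, and gene-set enrichment are
  consumed as pre-made tables, never computed.
- The pipeline orchestrator (`run_pipeline()`) covers the
  simulate → mechanics → stiffness chain; imaging and omics stages are
  driven directly through their functions.
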