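---
title: "Methods: blood-droplet evaporation, Marangoni trajectories and deposit topography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood-droplet evaporation, Marangoni trajectories and deposit topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemodrop)
```

## The physical picture

A sessile drop of whole blood on hydrophilic glass evaporates with a
pinned contact line: proteins adhere to the substrate and the base
diameter stays constant while volume, apex height and contact angle
shrink (constant-contact-radius, CCR, mode). Evaporative flux is
strongest at the triple line, driving an outward capillary flow that
piles red blood cells into a peripheral rim — the familiar coffee-ring
mechanism. On a heated substrate, a radial surface-temperature gradient
develops between the triple line (warm) and the apex (cooled by
evaporation). Because surface tension falls with temperature, the
gradient drives a thermocapillary (Marangoni) recirculation that
opposes the capillary flow; when it dominates, the drop's height and
contact angle *rise* mid-life and the deposit develops a central dome
rather than a cavity.

The package quantifies this competition through the thermal Marangoni
number

$$Ma(t) = -\frac{d\sigma}{dT}\,\frac{R\,\Delta T(t)}{\eta\,\alpha},
\qquad \Delta T = T_{TPCL} - T_{center},$$

evaluated per thermography frame. Three observable regimes anchor the
analysis:

* **capillary** (unheated, 23 °C): all shape descriptors decrease
  linearly; $Ma$ shows no significant two-rate structure;
* **delayed dome** (moderate heating, 37 °C): $Ma$ grows slowly
  (about 1.66 units/s) for roughly 900 s, then sharply (about
  55 units/s, a more than 33-fold rate increase), and a dome forms;
* **immediate dome** (60/90 °C): the fast growth and dome are present
  from the start, over much shorter lifetimes.

## Property models

`water_viscosity()` uses a Vogel-type form
$\eta_w = 2.414\times10^{-5}\cdot 10^{247.8/(T+133)}$ Pa·s with $T$ in
°C; at 20 °C it gives $1.005\times10^{-3}$ Pa·s, within 0.5% of
standard water tables, which is how the form was validated.
`blood_relative_viscosity()` is the empirical hematocrit-temperature
exponential $2.03\exp[(0.0332-1.08\times10^{-4}T)\,Ht+0.02T]$, used
verbatim — including the $\exp(0.02T)$ term that makes the *relative*
viscosity rise with temperature; no silent correction is applied, and
absolute blood viscosity is the product of the two models.

The default hematocrit is 35%, a typical ovine value; it is a
configurable default, not a measurement. The default surface-tension
curve $\sigma(T) = -11.5\ln T + 88$ mN/m is likewise an invented but
plausible logarithmic decline for blood over 24–90 °C; real campaigns
should fit their own tensiometer data with `fit_surface_tension()`.

Thermal diffusivity $\alpha = \lambda/(\rho C_p)$ is exposed in two
unit conventions. With the blood constants
($\lambda = 0.52$ W/(m·°C), $\rho = 1.04873$ g/ml,
$C_p = 3617$ J/(kg·°C)), plugging the density in as its g/ml numeral
gives $1.3708\times10^{-4}$ — the conventionally quoted value for this
system, kept as the `paper_numeric` regression anchor — while the
`si` mode converts to kg/m³ and yields the dimensionally honest
$1.3708\times10^{-7}$ m²/s. The pipeline computes $Ma$ with `si`
diffusivity and blood viscosity at the film-mean temperature
$(T_{TPCL}+T_{center})/2$ by default; both choices are configurable
because the underlying convention is genuinely open.

## Image reduction conventions

Thermography frames are reduced with a fixed sampling convention:
$T_{center}$ is the mean over a disc of radius 2 px at the drop centre
and $T_{TPCL}$ the mean over a 2 px-wide annulus just inside the drop
radius. Region means rather than single pixels buy robustness to pixel
noise; the price is a noise floor set by the disc's ~12 pixels
(0.006 °C at the default 0.02 °C pixel noise). `locate_tpcl()` finds
the drop radius as the maximum absolute radial gradient of the
azimuthally averaged profile, falling back to a supplied mask radius on
featureless frames.

Contact angles are extracted by a local circle fit (Kasa algebraic fit
to the contour points within 0.6 of the profile height of each contact
point); the angle follows from the circle's centre height via
$\cos\theta = -b/r$. A circle fit is the standard drop-shape-analysis
choice and is exact for spherical caps; nearly collinear contours fall
back to a straight-line tangent.

The volume-shrinkage slope is OLS over a window that starts at the
first 20% of samples and grows while the fit keeps $r^2 \ge 0.98$ —
the package's operational definition of the "initial linear segment".
At the default threshold the window leaks slightly past a sharp kink
(about 10% slope bias on an extreme line-then-plateau input); a
stricter `r2_min` trades robustness for sharpness, and the tests pin
both behaviours.

## Marangoni rate analysis

`detect_breakpoint()` fits a continuous two-segment piecewise-linear
model at every candidate sample time and takes the SSE minimiser; an
exact straight line, or a best gain below 1%, is flagged as having no
breakpoint. `two_segment_rates()` reports the mean growth rate from
$t_0$ to the break and over a 100 s window after it — the construction
behind the quoted units-per-second rates. Regime classification is
dome-first: no dome means capillary unless a breakpoint with a
late/early ratio of at least 3 contradicts it. The ratio guard exists
because a best-of-$n$ two-segment fit on a noisy but linear trajectory
always gains a few percent SSE, and without the guard unheated drops
would occasionally be misclassified.

## The texture engine

Height maps are leveled (least-squares plane, then mean removal)
before any parameter. The Abbott-Firestone curve is the quantile
function of the height distribution on a 0.1% material-ratio grid; Smc
is its inverse at 10%. The functional family uses the standard
construction: the 40%-wide window of minimum secant slope defines the
equivalent line, extended to 0% and 100% to give Sk, with Spk/Svk from
the triangle-equivalence rule on the residual areas. Volume parameters
integrate the same curve (p = 10%, q = 80%). Feature parameters come
from watershed segmentation (EBImage) with tolerance-based merging of
features whose relief is below 5% of Sz — the Wolf-pruning convention —
then S5p/S5v are means of the five highest peaks / deepest pits, with
fewer-than-five flagged. Pattern segmentation thresholds the leveled
surface (Otsu by default), labels 8-connected components (implemented
in-package; the convenient library labelling is 4-connected, which
splits diagonally-touching wedges), and discards components under
20 px. Circularity is area over the disc of the maximum (Feret)
diameter, compactness the equivalent-to-maximum diameter ratio, and
coplanarity the maximum peak-height difference to neighbouring
patterns, neighbourhood meaning boundary proximity within 5 px (an
isolated pattern is paired with its nearest). Masked pixels (no-data
regions in cracked real scans) are excluded from every statistic.

## Statistics

Group comparisons follow the classical recipe: one-way ANOVA per
texture parameter across temperature groups, then Tukey-Kramer
all-pairs comparison using the studentized range distribution (R's
numerical `ptukey`/`qtukey`, so any group count and degrees of freedom
are supported) with Kramer's unequal-$n$ correction. Per-group
comparison intervals use halfwidth
$(q/2)\sqrt{(MSE/2)(1/n_i + 1/n_h)}$ with $n_h$ the harmonic-mean
group size, so in balanced designs "intervals disjoint" is exactly
equivalent to pairwise significance — the graphical rule — and the
rule is conservative otherwise. No correction is applied across the 16
parameters, matching the analysis this package reproduces. A
degenerate input (zero variance everywhere) returns p = 1 by flagged
convention.

## The synthetic study generator

The generator exists so the full pipeline can be exercised, seeded and
tested without instrument data. Its defaults *are* the study
conditions: four substrate temperatures (23/37/60/90 °C), 18 replicates
each, nominal 11 µl drops (5% volume jitter), 50° initial contact
angle, 1200 s lifetime at 23 °C scaling with volume and shrinking with
temperature, dome onset at 900 s in the 37 °C regime. The 37 °C
Marangoni schedule is deliberately the two-segment line with slopes
1.66 and 55 units/s breaking at 900 s, so the full IR-to-Ma pipeline
reproduces those rates as a round trip — a calibration choice, not an
empirical result. Edge-centre temperature differences are obtained by
inverting the Ma formula pointwise (fixed-point iteration to
$10^{-6}$ °C, since $d\sigma/dT$ and $\eta$ depend on
$T_{TPCL} = T_{center} + \Delta T$); the resulting $\Delta T$ sits at
physically plausible 0.5–5 °C through most of each lifetime.

Rendered frames use a radial profile $\propto (r/R)^\gamma$ with
$\gamma = 2$ inside the drop and the substrate temperature outside,
plus 0.02 °C Gaussian pixel noise. The radial shape is affinely
normalized on the actual pixel grid so that the analyzer's
annulus-minus-disc convention returns exactly the prescribed
$\Delta T$: without this calibration the area-weighted annulus mean of
$(r/R)^2$ is about 0.95, and the generator-analyzer round trip would
carry a built-in 5% bias that has nothing to do with either component.

Deposits are phenomenological height maps, not crack mechanics: a
peripheral rim, a raised coronal band cut by radial and ortho-radial
crack grooves, a central cavity (cold) or dome (hot), inner-annulus
elliptical aggregates, and fine blurred texture. Relief amplitude,
crack count, ring count and dome height scale monotonically with
substrate temperature, and aggregate elongation decreases with it
(radially stretched by capillary outflow when cold, compacted by
recirculation when hot), so that *all sixteen* texture parameters —
including the shape-based circularity and compactness — carry a
programmed temperature effect with 5% replicate dispersion.
Consequently, a significant ANOVA on synthetic data demonstrates that
the pipeline detects effects the generator programmed; it says nothing
about effect sizes in real blood deposits, and the generator does not
emulate focus-variation artefacts, stitching seams, no-data crack
interiors, or biological variability between animals.

## Problem sizes and numerical choices

The study-scale defaults are 64×64 thermal frames (48 per drop) and
128×128 deposit maps, sizes at which the edge-centre reduction and
watershed remain well resolved while a 72-drop study completes in well
under a minute; the single-drop round trip uses the full 128×128 grid
with a 40 px drop radius and 10 s frame spacing. The Abbott grid step
is 0.1% material ratio; breakpoint candidates are the interior sample
times; the ANOVA null calibration in the tests uses 2000 replicates of
the 4×18 design. All randomness flows from one master seed through
per-drop child seeds, so study bundles are bit-reproducible and every
drop can be regenerated in isolation.

## Known limitations

* No fluid-dynamics simulation: Marangoni circulation is inferred from
  the dimensionless number, never solved.
* No radiometric calibration or emissivity correction; the pipeline
  starts at temperature grids.
* No video segmentation; geometry starts at contour polylines and time
  series.
* The viscosity, surface-tension and diffusivity conventions inside
  $Ma$ are documented defaults, not settled physics; sensitivity to
  those choices rescales $Ma$ trajectories but not the regime
  classification, which depends on shape.
* Real-deposit p-values and regression coefficients are not
  reproducible without the original scans; the statistical layer is
  validated on calibration properties (null uniformity, t-test
  reductions, normal-equation equivalence) and on programmed effects.
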