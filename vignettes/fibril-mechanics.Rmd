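---
title: "Single-fibril mechanics and hydration: models, parameters, design"
author: "fibrilmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-fibril mechanics and hydration: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilmech)
```

`fibrilmech` turns raw AFM observables — force–displacement curves and
height images of individual collagen fibrils — into mechanical and
hydration phenotypes, and compares fibril cohorts on the log-modulus
scale. This vignette is the package's account of the models it
implements, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic-data tests do and
do not establish about real data.

## 1. The contact-mechanics model

A cantilever of spring constant $k$ (N/m) presses a sharp pyramidal tip
into the fibril. The instrument records piezo displacement $z$ and
deflection $d$; force is $F = k\,d$ and the indentation (tip–sample
separation past contact) is

$$\delta = (z - z_0) - (d - d_{\text{baseline}}),$$

the piezo travel corrected for cantilever bending. For a rigid cone of
half-angle $\theta$ on an elastic half-space (Sneddon),

$$F \;=\; \frac{2}{\pi}\tan\theta\,\frac{E}{1-\nu^2}\,\delta^2 .$$

The analysis chain inverts this through the standard depth-sensing
(Oliver–Pharr) quantities: contact stiffness $S_c = dF/d\delta$ at
maximum load; contact depth $h_c = h_{\max} - \varepsilon P_{\max}/S_c$;
projected area $A_c(h_c)$; reduced modulus

$$E_r = \frac{\sqrt{\pi}}{2\beta}\,\frac{S_c}{\sqrt{A_c}};$$

and sample modulus. Two elastic bodies combine as
$1/E_r = (1-\nu_s^2)/E_s + (1-\nu_i^2)/E_i$; with a silicon tip
($E_i = 169$ GPa, $\nu_i = 0.27$) against collagen at MPa–GPa, the
indenter term is negligible and the default inversion is the simplified
$E_s = (1-\nu_s^2) E_r$. The exact two-body inversion is available
(`sample_modulus(mode = "two_body")`); below 100 MPa the two differ by
under 0.1%, and even at 13 GPa by only ~10%.

The result is reported as the **indentation modulus**: a fibril is
transversely isotropic (molecules aligned axially), so indentation mixes
transverse compression with longitudinal tension and the scalar modulus
should not be read as either pure component.

### Key parameters, defaults and why

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| $\varepsilon$ | $2(\pi-2)/\pi \approx 0.727$ | — | conical indenter value; makes the chain exactly self-consistent with the Sneddon cone law (the 0.75 paraboloid value is selectable) |
| $\beta$ | 1 | — | the convention adopted for sharp pyramidal tips; values in (1.0226, 1.085) are accepted |
| $\nu_{\text{sample}}$ | 0.5 | — | incompressible limit, the common assumption for hydrated collagen; an explicit config field echoed in every output because the study value is not otherwise constrained |
| $\theta$ | 35 | degrees | half-angle of the ideal pyramidal tip geometry; a calibrated area polynomial can replace the ideal form |
| $\chi$ (thermal) | 0.971 | — | first flexural mode of a rectangular lever in the equipartition calibration $k = \chi k_B T / \langle d^2\rangle$ |

### Contact-point detection

No single algorithm is canonical, and curves vary enormously in how the
recorded travel divides between free travel and contact: a 0.24 N/m
lever indenting a GPa-scale sample spends almost all of its piezo range
on deflection, leaving a few percent of samples before contact. A
baseline fitted to a fixed leading fraction of the approach therefore
fails in exactly the regimes this package must handle. Instead the
detector fits the full two-regime model: a baseline line in $z$ (offset
plus drift, with the slope bounded at $0.05k$ so the line cannot absorb
a contact branch that is nearly linear in $z$) plus a parabola
$C(s-s_0)^2$ in tip position $s = z - d$ with its vertex at the contact
point. The split $s_0$ is found by a coarse grid over the tip-position
range followed by golden-section refinement of the best few separated
candidates (the objective can be multi-modal when contact is much
stiffer than the lever). A curve whose baseline-corrected force never
sustains `threshold_sd` (default 5) baseline residual SDs above zero is
flagged contact-free and excluded from batch statistics rather than
fitted.

### Stiffness estimation and noise geometry

Deflection noise $\epsilon$ enters the indentation as $-\epsilon/k$,
perfectly anticorrelated with the force noise $+\epsilon$. Regressing
$F$ on that noisy $\delta$ attenuates the slope (errors-in-variables),
and the attenuation is amplified by the series-spring factor $1 + S_c/k$
— a factor of 5–25 in the soft-lever configurations used on hydrated
fibrils. The package therefore estimates stiffness on the noise-free
piezo axis: force is smoothed against $z$, a self-consistent indentation
is rebuilt by solving the fitted force law against the lever equation
(closed form for a quadratic law), and the polynomial force–indentation
fit runs on that rebuilt axis. By default the analyzer additionally
re-fits the exact cone-lever model jointly in $(C, s_0)$
(`contact_config(refine = TRUE)`): for the Sneddon law this estimator is
unbiased and uses every contact sample. On noiseless synthetic curves
the full chain recovers the generating modulus to better than $10^{-5}$
relative; at 2% force noise, single-curve errors are a few percent.

Two related defaults deviate from the more common textbook settings and
deserve a note. The quadratic stiffness fit uses the **whole** contact
range by default (`fit_fraction = 1`): the sharp-cone law is globally
quadratic, so restricting to the top 30% of the depth range (the usual
choice for unloading curves of materials with non-power-law response,
and still available) only discards information and inflates variance.
And the loading branch, not an unloading branch, is analyzed, matching
an elastic-indentation protocol.

## 2. Topography: heights, banding, swelling

Height images are flattened with a robust plane fit on below-median
pixels before ridge detection, so substrate tilt or offset never masks a
fibril. The fibril axis is the height-weighted principal axis of the
above-threshold pixels, refined station-by-station to the sub-pixel
crest; stations whose crest is clipped by the image boundary are
dropped. Cross-section profiles are taken perpendicular to the local
axis, averaged over `avg_window` (default 5) adjacent sections, and
baseline-corrected with a least-absolute-deviations line fitted only to
flanking substrate at least one apparent fibril width from the crest —
this makes the extracted height exactly invariant to substrate tilt.
The default station is the crest maximum along the axis, so dry/wet
height ratios compare like phases of the D-band modulation.

The D-period comes from the crest profile, linearly detrended, via the
zero-padded FFT power spectrum with parabolic sub-bin peak interpolation
(default) or the first autocorrelation maximum. Confidence is the
fraction of in-band power inside the spectral peak's main lobe; a flat
or roughness-dominated crest is flagged low-confidence rather than
yielding a spurious period.

**Swelling and density.** Swelling is the height fold-change
$S = h_{\text{wet}}/h_{\text{dry}}$. Converting $S$ to water content
requires a volume convention. The package's default takes fibril volume
proportional to height — length does not change on hydration, and the
apparent width is tip-convolved and unreliable — giving
$\phi_w = 1 - 1/S$ and $\rho_{\text{norm}} = 1/S$. At the wild-type fold
of 2.6 this yields $\phi_w \approx 0.62$, i.e. roughly two-thirds of the
hydrated fibril volume is water, which is the physically expected scale;
an isotropic-cross-section alternative ($V \propto S^2$, selectable as
`convention = "isotropic"`) would give 0.85, which is not. The
convention is a config switch precisely because it is a modelling
choice, not a measurement.

## 3. Microfibril arithmetic

Collagen microfibrils pack in a triclinic unit cell (for the in-situ
type I structure: $a \approx 40.0$, $b \approx 27.0$, $c \approx 678$ Å,
$\alpha \approx 89.2^\circ$, $\beta \approx 94.6^\circ$,
$\gamma \approx 105.6^\circ$). The volume uses the standard
crystallographic formula and is tested to $10^{-9}$ relative against a
lattice-vector triple-product oracle over randomized cells — a guard
against angle-convention mistakes. Trimer masses are plain
stoichiometry: the heterotrimer is $2 M_{\alpha 1} + M_{\alpha 2} =
405.621$ kDa, the homotrimer $3 M_{\alpha 1} = 414.096$ kDa (a 2%
difference). Density comparisons divide mass by cell volume; at equal
assumed mass a 14% volume excess is a 12.3% density deficit, and using
the true trimer masses instead shrinks it to ~10.4% — the package
reports either so the effect of the equal-mass approximation is visible.
Tangent moduli of polynomial stress–strain laws are evaluated by
bisection on the monotone fitted interval (robustness over Newton for
low-degree polynomials); a stress level outside the fitted range is an
error with the range reported, never an extrapolation.

## 4. Cohort statistics

Group comparison follows the unbalanced-groups recipe: ordinary least
squares on $\ln(\text{modulus})$ with categorical factors. The log
transform corrects the unequal group variances that modulus cohorts
always show (SD roughly proportional to mean). Group summaries are
least-square means — marginal means over the factor grid with equal
weights, the classic definition — whose back-transforms are
geometric-mean-type group values; in a balanced one-factor design the
back-transformed lsmean *is* the geometric mean, exactly, and the test
suite asserts this. All pairwise contrasts are Tukey-adjusted through
the studentized range distribution; at two groups this reduces exactly
to the pooled t-test ($q = \sqrt{2}\,|t|$), and a 2000-replicate
simulated null puts the empirical type-I rate at $0.05 \pm 0.01$. The
lsmean computation is hand-built from the model matrix and is verified
against `emmeans` to $10^{-8}$ in the test suite; `emmeans` is an
oracle there, not a dependency. Whether sex enters the model is a
config choice (`factors`), supporting designs that include it as a
covariate.

## 5. The synthetic-data generator

The generator exists so that every downstream stage has ground truth:

* **Curves** follow the same Sneddon cone law the analyzer assumes, with
  the deflection channel solved self-consistently against the lever
  ($k d = F(\delta)$, $\delta = (z-z_0) - d$), additive white Gaussian
  force noise, and optional linear baseline drift. The geometric
  constant $2/\pi \tan\theta$ is shared with the analyzer's ideal area
  function, which is what makes the noiseless round trip an exact
  identity and therefore a usable oracle.
* **Images** render one straight fibril as a circular-segment cross
  section with sinusoidal axial height modulation (the D-banding
  surrogate), Gaussian substrate roughness, optional in-plane rotation,
  and optional grayscale dilation with a spherical-cap structuring
  element as the tip-convolution surrogate.
* **Cohorts** draw per-fibril moduli from a lognormal matched to the
  stated arithmetic mean and SD — lognormal because the statistics are
  done on logs and moduli are positive and right-skewed — with a
  truncated-normal alternative.

The default study conditions are: air-dried 7.9 ± 2.8 GPa (WT) vs
5.3 ± 2.2 GPa (oim); hydrated 3.3 ± 0.5 MPa (WT, n = 10) vs
16.2 ± 3.0 MPa (oim, n = 8); an ethanol-series hydrated trial at
1.2 ± 0.4 vs 10.8 ± 3.7 MPa (n = 6); swelling folds 2.6 (WT) vs 1.5
(oim); 26 nm dry height, 67 nm banding, 2 nm pixels, 0.2 nm substrate
roughness. Group sizes for the air-dried and ethanol cohorts are not
constrained by the emulated study design, so the defaults (n = 20 and
n = 6) were chosen once as typical survey sizes for those protocols —
n = 20 also being large enough that the air-dried group contrast is
reliably significant at the group separation above, as it should be for
a faithful emulation. Indentation depths (20–50 nm by medium) and the
150 nm free-travel contact point are likewise documented assumptions,
not measured values. The 2% force noise default exercises
contact-point detection without overwhelming n = 8 cohorts.

**What passing tests show — and don't.** The generator shares its
contact law with the analyzer, so the round trip certifies the
*inversion chain*, not the physics: real fibrils add adhesion,
viscoelasticity, substrate stiffening at large depth, tip blunting and
piezo nonlinearity, all outside scope (and declared so). Similarly, the
image model has no instrument line noise, scars or drift bowing, so
pixel-accurate D-period recovery on synthetic images is a statement
about the estimator, not about any microscope.

## 6. Numerical choices and degenerate inputs

* Unit system: nm, nN, N/m internally (1 N/m = 1 nN/nm); moduli in Pa.
  The conversion in $E_r$ is a single factor of $10^9$, asserted against
  an all-SI hand computation in the tests.
* Contact-point golden-section refinement stops at $10^{-6}$ relative;
  the exact-model refinement profiles $C$ over a 100-fold bracket.
* Negative contact depths (possible under extreme noise) invalidate the
  curve rather than producing a negative area; zero-variance thermal
  series, contact-free curves, blank images, singular designs and
  out-of-range stress levels are all explicit errors or flagged
  results, never silent numbers.
* All simulation-scale defaults (256-sample curves, 128 x 320 px
  images, 2000-replicate null) were sized so the full suite runs in
  well under a minute on a laptop while keeping Monte-Carlo standard
  errors below the asserted tolerances.

## 7. Known limitations

Adhesive (JKR/DMT) and viscoelastic contact, finite-thickness substrate
corrections, anisotropic contact solutions, tip-shape deconvolution,
multi-fibril segmentation and mixed-effects models are out of scope.
The Poisson ratio and the exact swelling-to-density conversion are
assumptions surfaced as config switches, not estimated quantities; any
downstream comparison should carry them along explicitly.
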