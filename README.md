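# fibrilmech

Mechanical and hydration phenotyping of individual collagen fibrils from
atomic force microscopy (AFM) data.

Type I collagen fibrils — the ~100 nm-wide, D-banded cables that carry
load in tendon and bone — can be probed one at a time by AFM: cantilever
nanoindentation yields an *indentation modulus*, and height imaging before
and after hydration yields the *swelling* of the same fibril. Comparing
wild-type fibrils (heterotrimeric collagen, two α1(I) + one α2(I) chain)
with fibrils from the osteogenesis imperfecta murine model (*oim*;
homotrimeric, three α1(I) chains) connects a single-gene defect to a
single-fibril mechanical phenotype. `fibrilmech` implements the complete
computational chain for such a study, plus a synthetic-data module so
every stage can be tested against known ground truth.

## The analysis chain

**Force spectroscopy.** A force–displacement curve records cantilever
deflection `d` against piezo displacement `z`. With spring constant `k`
(thermal calibration, `k = χ k_B T / ⟨d²⟩`), force is `F = k d` and
indentation is `δ = (z − z₀) − d`. The contact point `z₀` is located by a
two-regime model fit (baseline line + Sneddon parabola in tip position).
The Oliver–Pharr/Sneddon chain then gives

- contact stiffness `S_c = dF/dδ` at maximum load,
- contact depth `h_c = h_max − ε P_max / S_c` (conical ε = 2(π−2)/π),
- projected area `A_c(h_c)` (ideal sharp cone: `π tan²θ h_c²`),
- reduced modulus `E_r = (√π / 2β) · S_c / √A_c` (β = 1),
- sample modulus `E_sample = (1 − ν²) E_r` (rigid-indenter limit for a
  silicon tip at 169 GPa against MPa–GPa collagen).

**Topography.** Fibril axis tracing on height images, baseline-corrected
cross-section heights, D-band periodicity (FFT or autocorrelation of the
crest profile), hydration swelling `S = h_wet / h_dry`, water volume
fraction `φ_w = 1 − 1/S` and normalized density `ρ_norm = 1/S` under the
height-proportional volume convention.

**Microfibril arithmetic.** Triclinic unit-cell volumes
(`V = abc√(1 − cos²α − cos²β − cos²γ + 2cosα cosβ cosγ)`), trimer masses,
density ratios between the wild-type and homotrimer packings, and tangent
moduli `dσ/dε` of polynomial stress–strain laws at a stress level.

**Cohort statistics.** Gaussian linear model on `ln(modulus)`,
least-square means, Tukey-adjusted pairwise contrasts (studentized range),
and fold ratios on the back-transformed (geometric-mean) scale.

## Worked example

```r
library(fibrilmech)

# a hydrated oim-like fibril: 16.2 MPa ground truth, 2% force noise
spec <- curve_sim_spec(modulus_true = 16.2e6, spring_constant = 0.24,
                       noise_sd = 0.02, seed = 1)
analyze_curve(generate_force_curve(spec))
#> <contact_analysis> E_sample = 1.618e+07 Pa (E_r = 2.157e+07 Pa)
#>   S_c = 0.9623 N/m, h_c = 31.85 nm, A_c = 1562 nm^2, R^2 = 1.0000

# full synthetic study at the default group parameters
res <- run_pipeline(default_config(seed = 1))
res
#> <study_summary>
#> ...
#> PBS oim/WT lsmean ratio: 5.07 (5-fold)
#> swelling deficit: 42.1%
#> D-period: 67.07 nm
```

The pipeline's defaults emulate the study conditions: air-dried moduli of
7.9 ± 2.8 GPa (WT) vs 5.3 ± 2.2 GPa (oim), hydrated moduli of
3.3 ± 0.5 MPa (WT, n = 10) vs 16.2 ± 3.0 MPa (oim, n = 8), and swelling
folds of 2.6 vs 1.5. The summary above says: in the hydrated state the
homotrimer fibrils are about fivefold stiffer on the lsmean scale, they
swell about 42% less than wild type, and the banding period of the
generated topography is recovered at 67 nm.

A thin CLI wraps the same pipeline:

```sh
Rscript inst/scripts/fibrilmech run --seed 1 --out results/
```

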