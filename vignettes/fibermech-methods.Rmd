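---
title: "Models and methods behind fibermech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibermech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibermech)
```

# The measurement problem

Passive (non-contractile) stiffness of skeletal muscle is usually
characterised at the level of single skinned fibers and small fiber
bundles. A specimen is mounted between a force transducer and a length
controller, stretched in cumulative increments of 10% strain at 10%
strain per second, and allowed to stress-relax for 4 minutes after each
increment. The force at the end of each hold, divided by the slack-state
cross-sectional area (CSA), is the equilibrium engineering stress; the
sarcomere length measured by laser diffraction before the first stretch
and at the end of each hold gives the strain. The *elastic modulus* of a
specimen is the tangent to the resulting stress-strain curve at 30%
sarcomere strain.

Two systematic problems affect this measurement, and `fibermech`
implements the analysis machinery for both:

1. **Size dependence.** Larger fibers and larger bundles are
   systematically more compliant. `fibermech` provides the two
   mechanistic models that explain this: a thin stiff basement membrane
   of constant thickness around each fiber (its cross-section scales
   with diameter, the contractile core with diameter squared), and a
   size-dependent extracellular-matrix (ECM) fraction combined through
   the rule of mixtures.
2. **Non-circularity.** Specimen cross-sections are elliptical, not
   circular. Protocols that measure one diameter and assume a circle
   misestimate CSA, and hence the modulus, by the major/minor axis
   ratio.

# Geometry

Top and side diameters are each read at three points along the specimen
and averaged. The cross-section is modeled as an ellipse with those two
axes:

$$\mathrm{CSA} = \frac{\pi}{4}\, \bar d_{top}\, \bar d_{side}.$$

The axis ratio is $\max(\bar d_{top}, \bar d_{side}) / \min(\bar
d_{top}, \bar d_{side}) \ge 1$. Whether the original analyses used the
ellipse formula or some other combination of the two diameters is not
documented; the ellipse is the natural model once two orthogonal axes
are measured, and it is what this package uses throughout (the choice is
visible in `ellipse_csa()` and flagged here deliberately). The
major/minor assignment is made per specimen from the two mean diameters,
not per reading point, because one shape summary is reported per
specimen.

If only the major axis were measured and a circular section assumed, the
assumed CSA would exceed the elliptical CSA by exactly the axis ratio;
`single_axis_error_factor()` returns that factor, which is how
under-estimation factors of 1.15-1.44 arise for typical fiber and bundle
shapes.

Diameter readings may optionally be rounded to the 1 µm instrument
resolution before averaging (`resolution_mm = 0.001`); this is off by
default so that synthetic data round-trip exactly.

# From raw trace to tangent modulus

`detect_slack()` locates the first force sample above the transducer
noise floor (about 5 µN for fibers, 50 µN for bundles); the sarcomere
length at that point is the slack length $SL_0$, and strain is
$(SL - SL_0)/SL_0$. Negative strains (readings below slack) are flagged
with a warning rather than rejected, but they never enter the curve fit.

The end-of-hold force of increment $k$ is the last sample in its hold
window. The 4-minute hold matters: the simulated relaxation (below)
leaves end-of-hold force within about 0.1% of equilibrium, which is why
the end-of-hold value is treated as the elastic response.

With only four to eight (strain, stress) points, a tangent at exactly
30% strain needs a smooth model. The package fits the standard passive
muscle toe-region form

$$\sigma(\varepsilon) = A\left(e^{B\varepsilon} - 1\right)$$

by nonlinear least squares (Levenberg-Marquardt, initialized at
$A = \sigma_{max}/(e^2 - 1)$, $B = 2$) and reports the analytic tangent
$A B e^{B \varepsilon}$ at $\varepsilon = 0.30$. The exponential form
has a well-defined tangent whether or not an increment lands exactly on
0.30, handles the linear case as its $B \to 0$ limit (recovering the
constant slope to within about 1%), and uses all increments rather than
the two nearest ones. If the fit fails to converge, a central finite
difference on the piecewise-linear interpolant is used and the result is
flagged (`fallback_used`); in practice the fallback is never needed on
curves of the simulated kind. Whether the original tangent was taken on
a fitted curve or by finite differences is not documented; both are
available and the fitted form is the default.

Units are fixed: forces in µN, areas in mm², stresses in kPa (1 µN/mm²
= 1 Pa), sarcomere lengths in µm.

# Composite models of the size effect

**Rule of mixtures.** A bundle is a parallel composite of ECM and
fibers:

$$E_{Bundle} = f_{ECM} E_{ECM} + (1 - f_{ECM}) E_{Fiber}.$$

With the reference values $E_{ECM} = 1$ MPa and $E_{Fiber} = 20$ kPa, an
ECM fraction of 5% gives 69 kPa; 6% and 4% give 78.8 and 59.2 kPa
(printed as 79 and 59). The algebraic inverse
`invert_rule_of_mixtures()` recovers $f_{ECM}$ from a measured bundle
modulus.

**Basement-membrane shell.** Each fiber is modeled as a circular
contractile core of modulus $E_{core}$ wrapped in a membrane of constant
thickness $t$ and modulus $E_{bm}$. The exact annulus area fraction

$$\varphi(d) = 1 - \left(\frac{d - 2t}{d}\right)^2$$

decreases with diameter, so small fibers are stiffer. The thin-shell
approximation $\varphi \approx 4t/d$ is available for comparison
(`thin_shell = TRUE`) but the exact form is the default — at $d = 50$
µm, $t = 0.5$ µm the two differ by about 2% of $\varphi$. Defaults
$E_{core} = 15$ kPa and $t = 0.5$ µm are package choices (no measured
values exist for them); they place fiber moduli near the 20 kPa
reference at mid-range diameters of 50-80 µm.

**ECM fraction vs. bundle size.** ECM bound to the bundle boundary
scales with the perimeter while bundle area scales with fiber count $n$,
suggesting

$$f_{ECM}(n) = f_\infty + \frac{c}{\sqrt{n}}.$$

The packaged default calibrates $(f_\infty, c)$ to the two extreme
measured bundles — collagen-I fractions of 5.3% at $n = 8$ and 3.4% at
$n = 25$ — giving $c = 0.1237$ and $f_\infty = 0.00926$. The
interpolated prediction at $n = 16$ is 4.02% against a measured 3.8%, an
adequacy check rather than a fit. The functional form itself is a
package choice: only three measured points exist, and any decreasing
one-parameter-per-observation family would pass through them; the
$1/\sqrt{n}$ law is the one with a geometric argument behind it.

`predict_bundle_modulus()` composes the three pieces and reproduces the
printed predictions 72/57/53 kPa from the measured fractions
0.053/0.038/0.034 after nearest-integer rounding (raw values
71.94/57.24/53.32 are always retained).

# Cohort statistics

Within each pool (group × muscle × specimen type):

* **Outlier filtering** removes, in a single pass, moduli above
  $Q_3 + 1.5\,\mathrm{IQR}$. Quartiles use linear interpolation between
  order statistics (`stats::quantile` type 7) — stated explicitly
  because outlier membership depends on the convention; other types are
  selectable. Only the upper tail is removed. Whether the original
  filtering was per pool or per study group is ambiguous; per pool is
  the default, per group (`outlier_scope = "group"`) an option.
* **Regression** of modulus (dependent) on CSA (independent) is
  unweighted OLS with a two-sided $t$-test on the slope ($n - 2$ df).
  Specimens are treated as independent, matching the pooling of
  spinal levels within a study group.
* **Shape testing** reports median and IQR of the axis ratios and a
  one-sample Wilcoxon signed-rank test against the theoretical median
  of 1 for a circular section. The test is implemented in the package:
  differences equal to 1 are dropped, tied absolute differences receive
  average ranks, and for $n \le 25$ the two-sided p-value comes from
  the exact null distribution of the positive-rank sum, computed by the
  rank generating function (polynomial convolution over doubled ranks,
  so tied average ranks stay exact); above 25 a normal approximation
  with continuity correction and tie-corrected variance is used. The
  exact branch is verified in the test suite against full enumeration
  of all $2^n$ sign assignments.
* **Control regression** of slack sarcomere length on CSA guards
  against the slack-detection artifact: a fixed force threshold could
  make large specimens appear to have short slack lengths, shifting
  where 30% strain falls. When slack length is generated independent of
  size, this regression rejects at the nominal 5% rate.

No multiple-testing correction is applied, and no between-group tests
are run; pools are reported separately.

# Collagen imaging

The collagen-I area fraction of a bundle in an immunostained section is
the ratio of collagen-positive pixels to all pixels inside the bundle
outline. Because the true bundle border is ambiguous in a section, two
segmentations are drawn — type A internal to the boundary fibers' edges,
type B external to them — and their fractions averaged. The A and B
fractions bracket the average by construction; on real sections the two
can rank either way depending on how much collagen sits in the boundary
annulus.

Pixel membership uses the even-odd rule on pixel centers, stated
explicitly because fractions of small bundles are sensitive to the
inclusion rule. Fibers are counted by pixel majority: a fiber whose
labeled pixels fall mostly inside the polygon belongs to the bundle (the
assignment rule for straddling fibers is otherwise undefined).
Thresholding raw fluorescence into the binary collagen mask is out of
scope; masks and label rasters are inputs (PNG/TIFF).

# The synthetic cohort generator

No raw data from the original cohorts are deposited, so the generator is
the package's testbed. It emulates:

* per-pool specimen counts (default 60), groups G1-G3, multifidus and
  longissimus, fibers and bundles;
* fiber minor-axis diameters log-normal with median 0.090 mm and
  `sdlog` 0.20, spanning roughly 0.06-0.14 mm as reported for rat
  multifidus fibers;
* bundles of approximately 7, 14 or 21 fibers (small/medium/large,
  jittered by ±2), with bundle CSA equal to the summed fiber area
  grossed up by the ECM fraction;
* true moduli from the composite models above, with log-normal
  biological scatter (CV 25%) on the core modulus and ECM fraction —
  this scatter, not measurement noise, is what keeps cohort-level
  $R^2$ in the 0.05-0.35 range seen in real pools;
* axis ratios $1 + (\tilde r - 1)\,\mathrm{lognormal}(0, 0.6)$ with
  medians 1.20 (fibers) and 1.35 (bundles), inside the reported
  1.15-1.29 and 1.27-1.44 spans, and IQRs of the reported order;
* slack sarcomere lengths normal (2.2 ± 0.1 µm), independent of size by
  construction, so the control regression has a true null;
* measurement noise: Gaussian force noise (1 µN fibers / 10 µN
  bundles), 2 µm per diameter reading, ~10 nm sarcomere quantization.

`simulate_test()` produces the full force/time recording: each
increment ramps to 1.5× the equilibrium force and relaxes as
$F(t) = F_{eq} + (F_{peak} - F_{eq})(0.5 e^{-t/2} + 0.5 e^{-t/40})$
(time constants in seconds). No within-hold force data exist for the
original tests; this double exponential is a synthetic stand-in chosen
so that end-of-hold force is ≥ 99.9% equilibrated at 240 s, consistent
with treating the end-of-hold value as elastic. All randomness flows
from one integer seed through per-specimen sub-seeds, so cohorts are
bit-reproducible and extensible.

The `sl_resolution_um` argument controls the sarcomere readout
quantization (default 0.01 µm). Setting it to 0 defines the noise-free
round-trip condition used in validation: with quantization active, the
rounding of $SL_0$ itself induces a small coherent strain bias whose
effect on the recovered tangent grows with the curve exponent $B$ and
can reach ~2% in the upper tail of the $B$ distribution — a measurement
limit of the instrument resolution, not of the extraction algorithm,
which recovers the generating modulus to ~0.06% (the residual of the
relaxation double exponential) once quantization is disabled.

## What the generator does not emulate

Real specimens have history-dependent viscoelasticity, titin isoform
variation, potential digestion/permeabilization artifacts, and
non-elliptical, longitudinally varying cross-sections. Passing
parameter-recovery tests on synthetic cohorts therefore validates the
analysis chain — not the biological models themselves, whose only
empirical anchors are the printed worked examples and the three measured
collagen fractions.

# Problem sizes and numerical choices

The validation suite runs, among others: 1000 noise-free curves for the
tangent oracle; 50 replicate noisy cohorts of $n = 60$ bundles for
size-effect recovery; 5000 null cohorts of $n = 30$ for the Wilcoxon
size check; 1000 cohorts of $n = 30$ for the slack-control null; and a
60-sample randomized battery against full sign enumeration for the exact
Wilcoxon branch. These sizes give comfortable Monte-Carlo margins for
the properties asserted (e.g. binomial SE ≈ 0.3% at 5000 replicates)
while keeping the default test run around two minutes.

Degenerate inputs are handled explicitly: constant response in the
regression returns slope 0, $R^2 = 0$, $p = 1$; constant predictor is an
error; all-zero stress curves and fewer than three positive-strain
points are errors; values all equal to the Wilcoxon null are a
no-information error; pools below $n = 5$ are reported as skipped with a
reason, never silently dropped.

# Known limitations

* The ellipse CSA and the $1/\sqrt{n}$ ECM law are modeling choices on
  top of sparse reported data (two orthogonal diameters; three collagen
  fractions).
* The Wilcoxon normal-approximation branch is slightly conservative
  near $n = 26$-40; the `exact_max` argument extends the exact branch
  if needed.
* The mixture model is applied at the single 30% tangent point; no
  strain-dependent mixture theory is attempted.
* Mapping between the mechanical size classes (~7/14/21 fibers) and the
  imaged bundles (8/16/25 fibers) is configurable rather than fixed;
  the defaults keep the two worlds separate.
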