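---
title: "Methods: small-field output factors and detector correction factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-field output factors and detector correction factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallfieldOF)
```

# Scope and model

This package determines field output factors $\Omega$ for small static
megavoltage photon fields from two reference detectors — planar dose
maps (radiochromic film surrogate) and a two-channel plastic
scintillator — and, from the fitted $\Omega(S_\mathrm{clin})$ curve,
detector-specific output correction factors $k$ for solid-state
detectors. Both reference detectors are treated as perturbation-free
except for volume averaging; that assumption is the physical basis of
the whole chain and is inherited from their near water equivalence and
weak energy dependence.

All internal lengths are millimetres; field sizes cross the API in
centimetres. Grid coordinates refer to pixel centers, and the map
origin defaults to the geometric center of the grid.

## Field sizing

Field widths are the FWHM of dose profiles through the field center,
with the half-maximum defined relative to the profile **maximum** (the
conventional FWHM definition; the center-ROI mean would differ for
occluded small fields). Crossings are located by linear interpolation
between bracketing samples. The center itself is the fixed point of an
iteration — extract profiles through the current center, move to the
midpoint of the half-maximum crossings — converged below 0.01 mm or
capped at 20 iterations. Profiles through non-grid-aligned centers use
bilinear interpolation. Profiles are not smoothed before the FWHM is
taken; with the noise levels considered here smoothing changes the
crossing position by far less than a pixel, and leaving the data
untouched keeps the measurement definition simple (a smoothing toggle
would otherwise become part of the field-size definition).

The equivalent square small field size is
$S_\mathrm{clin} = \sqrt{A \cdot B}$ with $A$, $B$ the in-line and
cross-line FWHM in cm.

## Volume averaging

The central $3\,\mathrm{mm} \times 3\,\mathrm{mm}$ region of each dose
map is fitted to the bivariate Gaussian
$f(x,y) = a\,e^{-\frac12[(x/b)^2 + (y/c)^2]}$. For a detector footprint
of equivalent square side $d$ (with $\pi r^2 = d^2$ for circular
detectors), averaging $f$ over the axis-aligned centered $d \times d$
square gives the closed form

$$k_\mathrm{vol} = \frac{d^2}
  {2\pi b c\,\operatorname{erf}\!\big(\tfrac{d}{2\sqrt2\,b}\big)
   \operatorname{erf}\!\big(\tfrac{d}{2\sqrt2\,c}\big)},$$

which the package cross-checks against explicit 2D Gauss–Legendre
quadrature to $10^{-6}$ relative. The peak amplitude $a$ cancels. The
erf argument $d/(2\sqrt2 b)$ is the unique reading consistent with the
one-axis integral $\int_{-d/2}^{d/2} e^{-x^2/2b^2}dx =
b\sqrt{2\pi}\operatorname{erf}(d/(2\sqrt2 b))$.

Numerical choices: fitted scales are reported as absolute values (the
Gaussian is even in $b$, $c$); fits are initialized from the region's
crude FWHM$/2.355$ floored at 0.3 mm, with three perturbed restarts. At
field sizes $\gtrsim 2$ cm the central region is flat to machine
precision (the erf-saturated core), so no finite Gaussian scale is
identifiable; a fitted scale beyond 100 mm over a 3 mm window is
therefore returned as the *flat* solution $b = c = \infty$, for which
$k_\mathrm{vol} = 1$ exactly. A fully uniform map is rejected as
degenerate instead. Corrections are applied in the pipeline only when
$k_\mathrm{vol} - 1 > 10^{-3}$ (configurable), matching how such
corrections are used in practice; $k_\mathrm{vol}$ is rounded to three
decimals only for reporting.

## Scintillator corrections

The Cerenkov light ratio is
$\mathrm{CLR} = (M^{Ch1}_{max} - M^{Ch1}_{min}) /
(M^{Ch2}_{max} - M^{Ch2}_{min})$ from max/min fiber-length readings in
the reference field, averaged over repeated triplets, and the corrected
signal is $M = M^{Ch1} - \mathrm{CLR}\,M^{Ch2}$. Channel response is
assumed linear. A denominator within $10^{-12}$ of the larger channel-2
reading raises an ill-conditioned-calibration error. Negative corrected
signals are flagged with a warning, not rejected — they can occur
legitimately in noisy data. Corrected scintillator signals are put on
the film scale by $\bar\epsilon$, the mean over the nine fields of the
ratio of volume-averaging-corrected scintillator to film signals.

## Output-factor fitting

Both reference series are pooled without preference and fitted by the
Sauer–Wilbert function
$\Omega(S) = P_\infty S^n/(l^n + S^n) + S_\infty(1 - e^{-bS})$.
"Maximum likelihood" is implemented as SD-weighted least squares —
the MLE under independent Gaussian errors with known SDs, the standard
reading for metrology data. The five-parameter *unnormalized* form is
fitted first and then divided by its value at $S = 10$, so the
normalized curve passes through 1 exactly for any parameter set.
Levenberg–Marquardt with five seeded starts and bounds
$P_\infty, n, l, b > 0$, $S_\infty > -1$ (scaled) is used; the wide
upper bound on $S_\infty$ admits the near-degenerate solutions in which
$S_\infty$ and $b$ trade off ($S_\infty \approx 1.4$, $b \approx 0.02$
occurs among the published sets).

Uncertainties of discrete $\Omega$ values come from a seeded parametric
bootstrap (default 500 resamples around the fitted curve, refit each):
the published tables state 1-SD uncertainties of the fits without a
method, and a parametric bootstrap is the least-assumption choice
consistent with the weighting model.

**Weighting.** Per-point sample SDs from three repeats have a ~50%
coefficient of variation; weighting by them lets chance-small SDs
dominate the fit and makes the bootstrap overconfident (we observed
actual curve errors about twice the bootstrap SD). The pipeline
therefore pools the relative SD across fields within each detector
series (root mean square) before weighting. With pooling, the fraction
of errors within one SD is 0.69–0.71 on simulated campaigns, matching
the nominal 0.68.

## Correction factors

$k(S_\mathrm{clin}) = \Omega(S_\mathrm{clin})/(M_\mathrm{clin}/M_\mathrm{ref})$,
with the reference reading averaged over bracketing pre- and
post-session measurements. The SD combines the relative SDs of
$\Omega$ and the ratio in quadrature, assuming independence (different
detectors and sessions). Discrete $k$ values are fitted by the TRS-483
sigmoid-plus-linear form for fields $\ge 0.8$ cm; smaller fields are
excluded from the residuals but reported flagged, because the sigmoid
cannot represent the 0.5 cm behaviour. The source text names three
fitting coefficients while the formula carries four; both modes are
implemented (`fix_d` fits or freezes the sigmoid amplitude $d$), and
neither is asserted as canonical. The multi-start grid covers both
signs of $d$ (under- and over-responding detectors); if no sigmoid
start converges on a near-flat noisy series, the fit falls back to the
degenerate linear member of the same family ($d = 0$).

## Summary-statistics t-tests

Output-factor tables are compared with two-sample t-tests computed
from means, SDs and $n$ (default $n = 3$, the number of film pieces or
readings per field; the published comparisons do not state their
degrees of freedom). Welch–Satterthwaite degrees of freedom are the
default; pooled variance is available for sensitivity analysis. The
published p-value tables are not reproducible from the printed
summary statistics under any standard two-sample construction we
tried, so the package reports its own p-values and makes no attempt to
match those tables.

# The synthetic campaign generator

The generator exists so that every stage is testable without external
data. One master seed drives all randomness through derived child
seeds; regeneration is bit-identical.

* **Dose maps.** Separable model
  $D(x,y) \propto g(x)g(y)$ with
  $g(u) = \frac12[\operatorname{erf}(\frac{w/2-u}{\sigma\sqrt2}) +
  \operatorname{erf}(\frac{w/2+u}{\sigma\sqrt2})]$: a collimated rect
  convolved with a Gaussian penumbra. For $w \gg \sigma$ the core is
  flat; for $w \lesssim 2\sigma$ the center is rounded, a surrogate for
  source occlusion. The map is scaled so the *central-axis* dose equals
  the planted output factor times the reference dose — the occlusion
  dip is the distribution's shape, already accounted for inside the
  planted curve. Default pitch 0.1693 mm (150 dpi); default penumbra
  $\sigma = 1.8$ mm, chosen so the nominal 0.5 cm field sizes to
  $S_\mathrm{clin} \approx 0.58$ cm, central in the measured
  0.54–0.62 cm spread; default reference dose 5 Gy (central doses stay
  above ~2 Gy at all fields).
* **Truth curves.** The eight published Sauer–Wilbert parameter sets
  (`beam_catalog()`), so campaigns are anchored to the published
  conditions.
* **Readings.** Scintillator channel pairs are constructed so that
  Cerenkov correction with the planted CLR (default 0.92) recovers the
  intended signal; the scintillator's true volume averaging is computed
  by exact quadrature of the model field over the fiber footprint, so
  the pipeline's Gaussian-fit route is tested *including* its model
  error. Solid-state detectors plant a *total* correction curve (the
  published discrete $k$ are total corrections), so pipeline recovery
  compares directly to the planted curve. Reference readings are
  emitted twice (pre/post session).
* **Noise defaults** (chosen once to be consistent with the published
  1-SD levels: tabulated $\Omega$ SDs of 0.005–0.011 and fit
  uncertainties of 1.0–2.5% at 0.5 cm): film per-piece scale 1.0%,
  film per-pixel 0.3%, scintillator per reading 0.5%, diode per
  reading 0.3%, Cerenkov-calibration readings 0.2% (long
  integrations). Three film pieces and three repeats per field.

What the generator does **not** emulate: film granularity and scanner
artifacts (lateral response, inter-scan drift), collimator-exchange
asymmetries ($A \ne B$), beam spectral changes with field size, or any
radiation transport. Passing recovery tests therefore demonstrates the
correctness and statistical calibration of the *analysis*, not the
absence of such experimental systematics in real data.

# Validation design and problem sizes

The test suite runs entirely on generated data at desk scale: campaigns
of nine fields with three film pieces (maps up to ~730² pixels at the
default pitch), 200-resample bootstraps in examples and 100–150 in
tests. Noiseless campaigns must return the planted normalized curve to
better than 0.1% at all nine fields and planted $k$ curves to 0.1% at
fields $\ge 0.8$ cm; campaigns at the default noise must recover
planted $k$ within one combined SD. For the latter, the criterion is
applied to the *mean over ten seeded campaigns* at each field: with
well-calibrated SDs, individual recoveries fall outside one SD about a
third of the time by construction, so a per-seed requirement would
reject a correct implementation; averaging ten seeds tests central
accuracy at the same tolerance.

Known limitations: the Sauer–Wilbert and TRS-483 forms are smooth
interpolants, so fitted values below 0.8 cm extrapolate the sigmoid
shape and are reported but not fitted; the $S_\infty$/$b$ trade-off can
leave individual parameters poorly determined even when the normalized
curve is tight (only the curve, never the raw parameters, should be
interpreted); and bootstrap SDs inherit the pooled-weighting model, so
they describe repeat-level noise, not systematic film-lot or
positioning effects.
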