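---
title: "Characterizing globular-protein adsorption on macroion layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing globular-protein adsorption on macroion layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adsorbkin)
```

## The problem

Small therapeutic proteins such as fibroblast growth factor 21 (FGF 21, a
~19.4 kDa endocrine hormone) are expensive, short-lived in vivo, and
difficult to characterize by classical bulk methods. A practical alternative
is to combine a handful of desk-scale physical models with flow-cell
(OWLS), gravimetric (QCM-D) and electrokinetic (streaming-potential)
measurements: from these one can extract the molecule's size, its charge as
a function of pH, and the coverage of the layers it forms on
polyelectrolyte-coated (e.g. PDADMAC) silica. `adsorbkin` implements that
workflow end to end, together with seeded synthetic-data generators that
stand in for instrument traces, and an independent hard-disk packing
simulator for the jamming coverage the packing limit relies on.

## Geometry and packing

From the molar mass $M_w$ and an effective globular-protein density
$\rho_p$ (default 1.35 g cm$^{-3}$), the molecular volume is
$v_1 = M_w / (N_{Av} \rho_p)$ and the equivalent-sphere diameter
$d_1 = (6 v_1/\pi)^{1/3}$. The hydrodynamic diameter of a doublet of two
touching equal spheres is 1.39 times the monomer value, giving a dimer-size
estimate. The maximum (jamming-limited) mass coverage of a monolayer is

$$\Gamma_{mx} = \frac{M_w\,\theta_{mx}}{N_{Av}\,S_g},$$

with $S_g$ the average molecular cross-section area (an input, typically
from molecular modeling) and $\theta_{mx} = 0.547$ the jamming coverage of
random sequential adsorption (RSA) of equal hard disks.

```{r geometry}
fgf21 <- protein_spec("FGF 21", molar_mass = 19400, density = 1.35,
                      cross_section_area = 17)
geometry_report(fgf21)
```

All interfaces use bench units (g mol$^{-1}$, g cm$^{-3}$, nm, nm$^2$,
mg m$^{-2}$, elementary charges, mV); SI conversions happen inside the
functions. Rounding is left to the reporting layer: the computed values
(e.g. 23.86 nm$^3$, 4.96 nm, 1.04 mg m$^{-2}$) are returned at full
precision.

## Charge versus pH and the isoelectric point

The nominal charge curve is modeled by the quadratic
$Q_p(\mathrm{pH}) = C_0 - C_1\,\mathrm{pH} + \mathrm{pH}^2$ with the leading
coefficient fixed at exactly 1; [fit_charge_polynomial()] therefore
estimates only $(C_0, C_1)$, by regressing $Q - \mathrm{pH}^2$ on pH. The
quadratic is a *local* fit (default validity pH 4--8); evaluation outside
that window warns rather than errors, because structure-based titration
curves diverge from the quadratic there. The isoelectric point is defined as
the smaller root of $\mathrm{pH}^2 - C_1\,\mathrm{pH} + C_0 = 0$ --- the
zero crossing on the descending, physical branch; the larger root lies on
the ascending branch outside the validity range. The quadratic is
dimensionally informal (a pH$^2$ term added to a charge); it is implemented
literally as the empirical fit it is. Note the raw polynomial value and its
integer rounding are both exposed (e.g. a charge of 8.3 e at pH 4 reported
as 8 e): the model and a rounded reading of it are different things and we
do not guess which a downstream consumer wants.

```{r charge}
poly <- charge_polynomial(55.9, 15.9)
isoelectric_point(poly)
nominal_charge(poly, c(4, 6, 8))
```

A sequence-based Henderson--Hasselbalch titration model
([titration_charge()]) is included as a *null model*: intrinsic pKa values
only (D 3.65, E 4.25, C 8.5, Y 10.0, H 6.0, K 10.5, R 12.5, N-terminus 9.0,
C-terminus 3.1; user-overridable), no structural shifts. It is monotone
non-increasing in pH and is meant for sanity checks and for proteins where
no computed charge curve is available, not as a replacement for
structure-aware pKa prediction.

## Hydrodynamic sizing

The Stokes--Einstein relation $d_H = kT/(3\pi\eta D)$ converts diffusion
coefficients (e.g. from multi-angle DLS) to hydrodynamic diameters and back.
When no viscosity is given, water viscosity at the stated temperature is
interpolated log-linearly between anchors at 273.15, 298.15 and 373.15 K
(8.90e-4 Pa s at 298.15 K); a user-supplied viscosity always overrides.
Ionic strength and pH ride along as metadata only.

## Flow-cell kinetics and the slope method

Under transport-limited (convective-diffusion) conditions the early-time
coverage in a flow cell grows linearly,
$\Gamma = k_{c0}\, D^{2/3} Q^{1/3} c_b\, t$, where $Q$ is the volumetric
flow rate, $c_b$ the bulk concentration and $k_{c0}$ a cell-geometry
mass-transfer constant. [fit_initial_slope()] extracts the slope $s_l$ by
ordinary least squares after subtracting the coverage at the adsorption
start (baselines drift; the model has no intercept). The default window is
0--450 s after the adsorption start --- the linear range seen for small
globular proteins at these flows --- additionally truncated where coverage
first exceeds 50% of the trace maximum so that short-plateau scans do not
contaminate the fit. A fit with $R^2 < 0.98$ warns.

Two inversions to the hydrodynamic diameter are offered:

* **direct** ([dh_from_slope()]): requires $k_{c0}$, which is
  instrument-specific and rarely known; the function refuses to guess and
  points to the calibration route;
* **calibration** ([dh_calibrated()], the default in
  [analyze_owls_trace()]): the ratio form
  $d_H = d_{H0}\left[\frac{s_{l0} Q^{1/3} c_b}{s_l Q_0^{1/3} c_{b0}}\right]^{3/2}$
  against a reference protein of known size measured in the same cell,
  which cancels $k_{c0}$ and is invariant under any common rescaling of
  slope, flow or concentration units. [hsa_reference()] provides the serum
  albumin tuple ($d_{H0}$ = 7.5 nm, $s_{l0}$ = 5.5e-3 mg m$^{-2}$ s$^{-1}$ at
  2.5e-3 cm$^3$ s$^{-1}$ and 5 mg L$^{-1}$).

```{r owls}
dh_calibrated(2.2e-3, flow_rate = 1.1e-3, concentration = 2,
              ref = hsa_reference())
```

Plateau and irreversible (post-rinse) coverages are tail-window means over
the final 20% of the phase, with a 3-standard-error drift check that flags
still-rising tails.

## QCM-D analysis

The Sauerbrey relation $\Gamma_Q = -C_Q \Delta f / n_o$ converts per-overtone
frequency shifts to acoustic (wet) coverage;
$C_Q = \sqrt{\rho_q \mu_q}/(2 f_0^2)$ evaluates to 0.177 mg m$^{-2}$
Hz$^{-1}$ for a 5 MHz AT-cut sensor. Because the oscillating sensor drags
coupled solvent, the wet coverage overestimates the dry protein mass; the
hydration correction $\Gamma = \Gamma_Q (1 - H)$ with default $H = 0.5$
(established for compact globular proteins such as serum albumin) yields the
dry coverage. $H$ is deliberately a parameter, not a constant: its
transferability between proteins is an open question. The default averaging
subset is the extreme overtones {3, 11}; full-set averaging is one argument
away. Dissipation data are not modeled --- no viscoelastic (Voigt) fitting
is attempted, because the workflow applies only Sauerbrey + hydration.

## Streaming-potential electrokinetics

The zeta potential of the channel walls follows from the slope of streaming
potential versus driving pressure via the Smoluchowski relation
$\zeta = \eta \lambda\,(\mathrm{d}U_s/\mathrm{d}\Delta p)/(\varepsilon_r \varepsilon_0)$,
with $\lambda$ the bulk electrolyte conductivity (supplied by the user; no
conductivity-from-ionic-strength model is invented) and $\varepsilon_r$
defaulting to 78.5 at 298 K. No surface-conductance or cell-geometry
corrections are applied, so the result is the plain Smoluchowski estimate.

## The RSA simulator

[rsa_fill()] performs random sequential adsorption of unit-diameter hard
disks on an $L \times L$ periodic square: uniform random placement attempts,
accepted only when no minimum-image overlap exists. A cell list (cell edge
$\geq$ 1 diameter) makes each attempt O(1); a brute-force path consuming the
identical random stream exists purely as a correctness oracle, and every
test run re-validates configurations with an $O(N^2)$ overlap check.
Attempt time is the dimensionless $\tau = \mathrm{attempts}/(L/d)^2$, making
the kinetics box-size independent. [estimate_jamming_coverage()] fits the
known hard-disk asymptotic law $\theta(\tau) = \theta_J - a\,\tau^{-1/2}$
over the final decade of $\tau$ in each replicate and averages the
intercepts; replicate $i$ uses seed $\mathrm{seed} + i - 1$. With the
default study conditions ($L = 50$ diameters, $\tau = 10^5$, 5 replicates)
the estimate lands within $\pm 0.005$ of the accepted jamming coverage
0.547, at a few minutes of CPU; asymptotic extrapolation was chosen over
exhaustive insertion-region tracking as simpler and adequate for that
target. Electrostatic swelling of the effective molecule size at low ionic
strength can be explored through the `disk_diameter` multiplier, but no
screened-interaction model is invented.

## Synthetic data: what it does and does not emulate

Every analyzer has a matching seeded generator that is its exact functional
inverse at zero noise:

* [generate_owls_trace()]: rise to a plateau, then a rinse-triggered
  exponential decay toward the irreversible coverage, plus iid Gaussian
  noise. The default rise shape is **linear-rise-then-plateau**
  ($\Gamma = \min(s_l t, \Gamma_{plateau})$) --- the shape transport-limited
  adsorption traces actually show and the one consistent with extracting the
  slope by ordinary least squares; a smooth saturating-exponential shape
  with the same initial slope and plateau is available via `shape =
  "exponential"` (note its curvature biases a straight-line fit low, which
  is visible in the fit's $R^2$ warning). Defaults (slope 2.2e-3
  mg m$^{-2}$ s$^{-1}$, plateau 1.0, irreversible 0.8, desorption rate
  0.01 s$^{-1}$, 1 s sampling over 3600 s, rinse at 1800 s) mirror the
  adsorption/rinse experiments on polyelectrolyte-coated silica.
* [generate_qcm_trace()]: per overtone,
  $\Delta f_n = -n \Gamma/( (1-H) C_Q ) + \mathrm{drift}\cdot t +$ noise,
  independent across overtones.
* [generate_dls_series()]: stationary per-population diameter draws
  (defaults 3.7 and 5.4 nm, the monomer/dimer pair).
* [generate_streaming_potential()]: linear $U_s(\Delta p)$ from a
  prescribed zeta (default 20 mV, a cationic-layer scale).

The generators emulate the *statistical structure* the analyzers assume ---
linear regimes, plateaus, additive Gaussian noise, overtone scaling. They do
not emulate instrument artifacts (temperature drifts, viscoelastic overtone
spread, bubbles, aggregation transients), so a passing recovery test
demonstrates the correctness of the inversion chain, not robustness to every
failure mode of real data.

## Numerical choices and degenerate inputs

* Least squares everywhere is `stats::lm`; $R^2$ is computed against the
  full model.
* Slope/plateau extraction requires $\geq 5$ / $\geq 2$ samples and errors
  otherwise; the charge fit requires two distinct pH values.
* The charge quadratic with negative discriminant raises a "no isoelectric
  point in model" error rather than returning a complex root.
* A torus of edge $L < 2$ diameters cannot hold two disks (maximum
  minimum-image separation $L/\sqrt 2$), so the $L = 1$ box jams at exactly
  one disk, $\theta = \pi/4$ --- a closed-form regression case.
* RSA attempt budgets below three decades of $\tau$ warn that the
  $\tau^{-1/2}$ extrapolation may be unstable.

## Problem sizes used in the test suite

Unit and property tests run at deliberately small scale (boxes of 5--25
diameters, $\tau \leq 10^4$, traces of a few thousand samples), which keeps
the full suite fast while exercising every code path; the one full-scale
computation is the jamming-coverage check at $L = 50$, $\tau = 10^5$,
5 replicates, reflecting the study conditions. Recovery tolerances in tests
(5% for kinetic parameters at 1% noise, 2% for QCM dry coverage at 0.2 Hz
noise, 3% for zeta at 2% noise) state the accuracy the synthetic conditions
support, not instrument accuracy.

## Known limitations

* No optical theory for the waveguide readout: traces enter already in
  mass-coverage units.
* No surface-blocking (RSA-kinetic) correction to the initial slope; only
  the linear regime is analyzed.
* The hydration factor $H$ and the reference-protein diameter are inputs;
  errors in them propagate multiplicatively into dry coverage and $d_H$.
* The titration model is intrinsic-pKa only.
* Electrostatic reduction of the jamming coverage at low ionic strength is
  exposed only as an effective-diameter multiplier, never computed from an
  interaction model.
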