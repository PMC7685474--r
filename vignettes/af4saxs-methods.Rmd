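---
title: "Methods: AF4-MALS and SAXS analysis in af4saxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AF4-MALS and SAXS analysis in af4saxs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(af4saxs)
```

This vignette is the package's own account of the science it implements: the
models, their assumptions, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical choices made where the
design was genuinely open. Nothing here states an empirical result that the
test suite or the acceptance script does not itself compute.

## The separation model: AF4 retention theory

In asymmetrical flow field-flow fractionation a cross-flow `Vc` presses
analytes against a semi-permeable wall of a ribbon-like channel while a
laminar channel flow carries them to the detector. Diffusion balances the
field, producing an exponential concentration layer of relative thickness
`lambda = D * V0 / (Vc * w^2)`, and the classical retention equation

$$R = \frac{t_0}{t_r} = 6\lambda\left[\coth\frac{1}{2\lambda} - 2\lambda\right]$$

links the observed retention time to the diffusion coefficient and, through
Stokes–Einstein, to the hydrodynamic radius. Assumptions: normal-mode
operation (no steric inversion — safe below ~10 nm radii), constant
cross-flow, a parabolic channel-flow profile, and no particle–wall or
particle–particle interactions.

**Geometry and void time.** The channel is trapezoidal (defaults: 26.5 cm
tip-to-tip, 2.2/0.6 cm inlet/outlet widths, 350 µm spacer). The void volume
is plan area × effective height; the void time uses only the volume
downstream of the focusing position (default 2 cm from the inlet), because
sample physically starts its elution there. The focusing default is a design
choice: it is rarely reported, its effect on `t0` is a few percent, and the
calibration described next absorbs residual error.

**Calibration.** The effective channel height is not the spacer thickness —
membranes swell and compress — so all absolute radii depend on a
`thickness_scale` fitted with `calibrate_thickness()` from one reference
species (radius, retention time) by root finding over [0.2, 2]. With the
albumin monomer reference (3.2 nm at 4.5 min) the fitted scale is ~0.49,
i.e. an effective height of ~173 µm; the model then maps the dimer peak at
6.5 min to 4.69 nm, within 0.3% of the 4.7 nm the same theory reported for
those data. Uncalibrated geometries work but warn.

**Solvent defaults.** 298.15 K and 8.9e-4 Pa·s (water at room temperature);
the experiments the package emulates were run at ambient temperature without
a reported thermostat value.

**Numerics.** The retention equation switches to the series
`R = 1 - 1/(60 lambda^2) + 1/(2520 lambda^4)` above `lambda = 10` to avoid
cancellation; inversion solves `R(lambda) = t0/tr` on a log grid with
`uniroot` at 1e-12 tolerance, making `time_from_radius()` and
`radius_from_retention_time()` mutual inverses to better than 1e-6. A
quadrature oracle (velocity-weighted average of the exponential layer against
the parabolic profile) confirms the closed form to 1e-6 in the tests.

## Molar mass from light scattering: the Berry formalism

For each elution slice the excess Rayleigh ratio at the detector angles is
converted to `sqrt(K* c / R_theta)` and regressed (degree 1 or 2, weighted)
on `sin^2(theta/2)`; `MW = 1/intercept^2`, and the radius of gyration comes
from the slope. For particles with `Rg <= 5 nm` at 658 nm the form factor
varies by under 1% across 32–147°, so molar masses are robust but light-
scattering radii of gyration are near the resolution limit (they are
reported as `NA` when the slope is non-positive).

Design choices: a 14-angle HELEOS-like detector set spanning 32–147° with
the low/high split at 81°/90° (six + eight detectors) — the split used for
the co-elution diagnostic; inverse-variance weights propagated from
per-detector baseline noise estimated on the quieter of the first/last 10%
of the run; concentrations from the dRI trace (`c = dRI / (dn/dc)`), with
slices below five baseline standard deviations excluded and reported as
"n.d."; the second virial coefficient is fixed at zero (dilute regime).

A genuine physical point documented rather than hidden: a low-angle/high-
angle molar-mass split of roughly two-fold, as fast-exchanging monomer–dimer
systems show in practice, cannot arise from ideal Rayleigh–Gans scattering of
3 nm particles. The tests reproduce it only through angle-correlated noise;
the package implements the diagnostic, not a physical mechanism for it.

## Binding stoichiometry from deconvoluted fractograms

Mixture UV fractograms are fitted as a linear baseline plus one to three
Gaussians ("Gaussian equation of first or second order" generalised to the
three-component titration case). Initialisation windows default to the
pure-component elution ranges (free ligand 3–5 min, albumin monomer
3.8–5.6 min, dimer 5.8–7.5 min); `analyze_binding_titration()` widens them
(3.0–4.2 / 4.2–6.2 / 6.2–8.6 min) because complex bands shift to later times
as occupancy grows — the simulated monomer complex reaches ~5.6 min and the
dimer complex ~7.6 min at saturation, exactly the shifts the measured
hydrodynamic radii imply. Centres are bounded inside their windows,
amplitudes at zero, and widths between two sampling intervals (nothing
narrower is resolvable) and the window width. The optimiser is
`minpack.lm::nls.lm` on the residual directly; components whose fitted
amplitude stays below three baseline standard deviations are treated as not
detected (zero area), which is how sub-detection free ligand is reported.

The bookkeeping defines, with `f` the albumin monomer mass fraction (which
equals its monomer-equivalent molar fraction) and `Konv` from a pure ligand
injection at the same instrument settings and injection volume:

* dimer-bound ligand: `(AUC_dimer(mix) - AUC_dimer(pure)) * Konv`, divided by
  the **dimer-particle** concentration `(1-f) * C_tot / 2` — "per dimer"
  counts ligands per dimer particle, which is why the dimer curve can sit at
  twice the monomer curve;
* free ligand: `AUC_free(mix) * Konv / C_tot` (the free-ligand window is the
  only region that can define it);
* monomer-bound ligand: the remainder of the mass balance, which therefore
  holds exactly at every titration point;
* negative subtraction results within twice the propagated area noise are
  clipped to zero silently, larger ones with a data-inconsistency warning.

Assumptions inherited from the experimental design: binding does not shift
the albumin monomer–dimer ratio; UV response is linear, and all extinction
and gain factors cancel through `Konv` (the tests assert invariance under a
uniform UV gain); pure references are injected at the same load as their
contribution to the mixtures.

The nominal molar masses (11.5 and 66.5 kDa) give an equal-stock mixing
ratio of 5.78, whereas titration series of this design are usually printed
with 5.66; `mixing_molar_ratio()` uses the nominal masses and the
discrepancy is left visible rather than reconciled.

## SAXS primary analysis

**Frame handling.** Repeated exposures are compared pairwise by reduced
chi-squared with the combined error `sqrt(s1^2 + s2^2)` — so two pure-noise
realisations score ~1 — against the most central frame; frames above the
threshold (default 1.5) are dropped and the rest averaged with
inverse-variance weights.

**Guinier.** Weighted fit of `ln I` vs `q^2`, starting at the third usable
point (beamstop edge) and growing self-consistently to the largest window
with `q_max * Rg <= 1.3` (the community default). A Wald–Wolfowitz runs test
on the residuals at 5% flags systematic curvature, the signature of
aggregation. One quantified caveat: on an ideal solid sphere the form
factor's negative fourth-order term biases the fitted `Rg` about 1.7% high
at the 1.3 limit; the sphere-oracle tests therefore fit within the sphere's
strict linear regime (`q_max * Rg <= 0.6`, residual bias ~0.4%). Real
globular proteins sit between these cases.

**p(r) inversion.** `I(q) = 4 pi int p(r) sinc(qr) dr` is discretised on a
regular grid (default 101 points) with hard endpoint zeros and solved by
Tikhonov-regularised weighted least squares with a second-difference
penalty; `alpha = "auto"` takes the maximum-curvature corner of the L-curve
over 25 log-spaced candidates. Non-negativity (default on) is imposed by
box-constrained L-BFGS-B on the same quadratic objective; it should be
disabled for particles where oscillating correlation functions are expected.
Real-space `Rg` and `I(0)` come from the moments of `p(r)`.

**Maximum dimension.** `pddf_dmax_scan()` selects the smallest trial `Dmax`
whose reconstruction chi-squared is within 5% of the plateau minimum:
underestimating `Dmax` leaves unfittable structure, overestimating merely
wastes grid. This works decisively for particles whose distance distribution
is well populated near `Dmax` (a two-lobed particle recovers a 12 nm maximum
dimension exactly across seeds in the tests); for smooth elongated particles
(prolate axial ratio ~4) under 1% of the pair distances lie in the outer
sixth of the range and any criterion — this one included — reads 1–2 nm
short. That softness is a property of the data, not of the solver.

**Porod pipeline.** The invariant integrates `q^2 I` over the data with a
Guinier extrapolation below the first measured point and a `K/q^4` tail
above the last (Porod constant from the mean of `q^4 I` over the last decade
of `q`); `Vp = 2 pi^2 I(0)/Q`. Molecular weights: `Vp/1.6` (kDa per nm^3,
the standard hydrated-protein rule), rounded half away from zero for
reporting — the rounding rule is needed so that 100 nm^3 prints as 63 kDa —
with the unrounded value also returned; ab initio excluded volumes divide by
2; the standard-based estimate scales a reference protein's `I(0)/c`. Shape
factors `Rg/Rh` are reported to two significant figures.

## What the synthetic generator emulates — and what it does not

`simulate_fractogram()` produces Gaussian bands centred at the retention
model's times with width `tr/sqrt(plate_number)` (default plate number 2500,
chosen to give the sharp, nearly baseline-resolved peaks of a
well-optimised channel) and linear detector responses: UV from mass
extinction, dRI from `dn/dc`, Rayleigh ratios `K* c MW P(theta)`. Noise is
additive Gaussian per detector at 0.5% of that detector's peak signal by
default. `simulate_fast_exchange_peak()` co-elutes an interconverting pair
as one skew-normal band carrying the weight-average molar mass, so the
apparent mass is flat across the peak — the co-elution fingerprint.

`simulate_titration_series()` solves a single-site equilibrium per point.
The binding entities are ligand monomers and Z–Z-interface ligand dimers; a
dimer occupies one albumin site via one of its two free binding domains and
contributes two ligand masses. Bound entities spread over albumin monomer
and dimer pools in proportion to sites (one per monomer, two per dimer
particle). Complex radii follow volume additivity over constituent radii
(`Rh^3` additive) — with the defaults this reproduces the measured complex
radii (3.9 nm monomer complex, 5.4–5.5 nm dimer complex) without further
tuning. Defaults are the experimental design itself: 2 mg/mL albumin stock
mixed 1:1 with ligand stocks 0.01–2 mg/mL, 93:7 monomer content, Kd 1 nM
(mid-range of the reported nanomolar affinities), and a ligand dimer
fraction of 6/13, the value at which the saturation plateau of the overall
bound ratio is exactly 1.3 ligands per albumin. The ligand monomer radius
(2.5 nm) is a modelling choice consistent with the 2.8 nm fast-exchange peak.

`simulate_saxs_curve()` uses analytic form factors (sphere; orientation-
averaged ellipsoid by 64-point Gauss–Legendre quadrature, 48×48 for triaxial
shapes; two-sphere dumbbell with the coherent `sinc(qd)` cross term;
weighted mixtures), normalised to `I(0)`, with noise
`sigma = 0.01 I + 1e-4 I(0)` by default and an optional `q^-3` low-q
contaminant for exercising the aggregation flag.

Not emulated: detector dead time and saturation, inter-detector delay
volumes, band asymmetry from overloading, programmed cross-flow gradients,
buffer-subtraction drift, radiation-damage kinetics, and concentration-
dependent structure. Passing the closed-loop tests therefore shows the
analysis chain is self-consistent and correctly implements its models — not
that it is robust to every artefact of real instruments.

## Problem sizes and runtime choices

The shipped tests run fractograms of ~3000 time points × 14 angles, SAXS
curves of 500–2000 points, 50-seed noise ensembles for the recovery checks,
20-seed ensembles for the IFT consistency check, and 7-point titrations —
sizes chosen to mirror realistic data densities while keeping the whole
suite around twenty seconds on a single core. The d_max scan covers 8–18 nm
in 1 nm steps at 101 p(r) grid points.

## Known limitations

* Retention theory here is classical; instrument software may apply
  non-equilibrium or focus-position corrections that are not public, so
  absolute agreement beyond the calibrated reference is only expected at the
  few-percent level.
* The Guinier sphere bias and the soft `Dmax` of smooth elongated particles,
  both quantified above.
* `Konv`-based bookkeeping assumes equal injection volumes between the pure
  ligand reference and the mixtures; scale `Konv` by the volume ratio
  otherwise.
* No Kd estimation: the titration analysis reports bound ratios, not an
  affinity — with nanomolar binding and micromolar albumin every
  sub-stoichiometric point is fully bound, so the data contain almost no Kd
  information anyway.
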