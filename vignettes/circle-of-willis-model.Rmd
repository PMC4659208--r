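---
title: "A lumped-parameter model of collateral flow in the circle of Willis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of collateral flow in the circle of Willis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(willisflow)
```

## What the model computes

The circle of Willis (CoW) is the anastomotic ring connecting the two
internal carotid arteries (ICAs) and the vertebrobasilar system to the six
efferent cerebral territories (paired anterior, middle and posterior
cerebral arteries). When one ICA narrows, the communicating arteries — the
single anterior communicating artery (ACoA) and the paired posterior
communicating arteries (PCoAs) — reroute flow to the starved side; when a
proximal segment (A1, PCoA) is congenitally absent, that rerouting capacity
changes qualitatively.

`willisflow` represents the circle as a graph of cylindrical resistive
segments between pressure nodes and solves the steady nonlinear network:
for each segment, fully developed Poiseuille flow

$$Q = \frac{\Delta P}{R}, \qquad R = \frac{128\,\mu_{\mathrm{eff}}\,L}{\pi d^4},$$

with mass conservation at every junction and fixed pressures at the
boundary nodes. It deliberately does **not** solve the 3D Navier–Stokes
equations: the target quantities are territory flow distributions,
collateral flow directions and reversal points, which a 0D reduction
resolves at negligible cost. Velocity profiles, wall shear stress and any
geometry-specific secondary flow are outside the model's reach by
construction.

## Rheology

Blood is shear-thinning, which matters at the low shear rates of
communicating arteries carrying little flow. Viscosity follows the Carreau
law

$$\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
 \left[ 1 + (\lambda\dot\gamma)^2 \right]^{(n-1)/2},$$

with the standard whole-blood constants $\lambda = 3.313$ s, $n = 0.3568$,
$\mu_0 = 0.056$ Pa·s, $\mu_\infty = 0.00345$ Pa·s
(`carreau_parameters()`). A lumped segment has no shear-rate field, so a
representative scalar is needed; we use the Poiseuille wall shear rate

$$\dot\gamma_w = \frac{32\,|Q|}{\pi d^3},$$

the standard reduced-order choice. It is exact for a Newtonian fluid in a
straight tube and errs on the high side for a shear-thinning profile, i.e.
it slightly underestimates the effective viscosity of slow segments. At
$Q = 0$ the viscosity is exactly $\mu_0$; no expression divides by the
flow, so zero-flow segments are handled without special cases.

## Boundary conditions

The inlet pressure at all three supply roots (both ICAs and the common
vertebral root) is the cerebral perfusion pressure,

$$\mathrm{CPP} = \mathrm{MAP} - \mathrm{ICP}, \qquad
 \mathrm{MAP} \approx DP + 0.01\,e^{4.14 - 40.74/HR}\,(SP - DP),$$

with defaults $DP/SP = 80/120$ mmHg, $HR = 80$ bpm, $\mathrm{ICP} = 3$
mmHg, giving MAP 95 mmHg and CPP 92 mmHg after integer rounding
(`tidy(build_boundary_set())` prints the full chain).

Each efferent territory ends at a constant outlet pressure: 46 mmHg (ACA),
56 mmHg (MCA), 43.5 mmHg (PCA). The lumped cerebrovascular resistances
follow from $\mathrm{CBF} = \mathrm{CPP}/\mathrm{CVR}$ at a total cerebral
blood flow of 12.5 ml/s split 22/45/33 % over ACA/MCA/PCA: 0.56 and 0.27
mmHg/(ml/min) for the ACA and MCA territories at two decimals. For the PCA
territory the chain gives $92/(0.33 \times 12.5 \times 60) \approx 0.372$
mmHg/(ml/min); a value of 0.375 is sometimes quoted alongside these
constants, but it is not reproducible from them, and the package always
reports the computed value. More generally the printed outlet pressures
and the CVRs are not mutually consistent under any single steady-state
derivation; we treat the **pressures** as the operative boundary condition
(they are what the solver consumes) and the CVRs as descriptive. Both are
configurable.

Cerebral autoregulation is deliberately absent: CVR does not respond to
perfusion changes, so perfusion deficits under severe stenosis are
upper-bound estimates.

## Geometry, variants, stenosis

The patient geometries behind published CoW studies are generally
unpublished, so the package ships a synthetic nominal dimension table
(`nominal_geometry()`, persisted as
`inst/extdata/nominal_geometry_synthetic.csv`) taken from the dimension
classes of the 1D arterial-network modelling literature: ICA ≈ 4 mm
diameter, communicating arteries ≈ 1.5 mm, A1/P1 ≈ 2.1–2.3 mm. It is
left-right symmetric by construction so that the complete circle carries no
ACoA flow — the physiological baseline. `synthetic_geometry(seed, jitter)`
multiplies every length and diameter by independent uniform factors in
$[1 \pm \text{jitter}]$ (jitter < 0.3) for sensitivity studies;
identical seeds give identical tables.

Five anatomical variants besides the complete circle remove exactly one
segment: ACoA, right/left A1, right/left PCoA (`apply_variant()`). Removal
never alters other dimensions. If a removal strands an efferent from every
inlet, the network is flagged and the solver reports zero flow there rather
than failing.

Stenosis uses the NASCET grade $S = (1 - d_s/d_n) \times 100\,\%$.
`apply_stenosis()` splits the target vessel into a healthy remainder and a
stenotic sub-segment of diameter $d_n (1 - S/100)$; $S = 100\,\%$ removes
the vessel entirely, avoiding the ill-conditioned systems that
huge-resistance stand-ins produce. The axial extent of the stenotic
sub-segment defaults to 10 mm and is configurable; its influence is
discussed below, because it is the single most consequential free parameter
of the stenosis model.

## Solver and calibration

`solve_flows()` uses Picard (successive substitution) iteration: assemble
the nodal conductance matrix at the current viscosities, solve the linear
system for internal node pressures with boundary pressures imposed, recover
segment flows, under-relax (factor 0.5 by default), repeat until the
relative change of all flows drops below $10^{-8}$ (at most 200
iterations). Picard with under-relaxation is robust for monotone
shear-thinning laws, where Newton iterations can overshoot near zero flow.
Non-convergence is always reported (flag plus warning), never silent. Each
converged solution carries a mass-conservation certificate
(`max_mass_residual`), and junction minor losses are neglected — a known
fidelity gap shared by essentially all 0D network models.

The circle segments are far less resistive than the arteriolar beds they
feed, so the raw network over-perfuses by a factor of ~4. `calibrate()`
therefore appends distal resistive elements — implemented as one resistance
scale factor per territory on the efferent segments — and finds the three
factors by monotone bisection (territory flow is strictly decreasing in its
scale factor), cycling over territories until the complete, unstenosed
network carries the target CBF and split to within 0.1 % per territory.
This is comfortably inside the acceptance bands used in the tests (0.5 % on
the total, 1 % absolute on the split). The factors persist in the
`r_scale` column of the segment table and survive CSV round-trips.

## Reporting conventions

Flows and percentage changes are reported at two decimals, rounding half
away from zero (`round_half_away()`), the convention of clinical tables;
internal computation keeps full precision. Percentage change is always
against the complete/unstenosed reference cell. Communicating-artery signs
follow the usual convention: ACoA flow positive towards the right
hemisphere, PCoA flow positive towards the anterior circulation. Reversal
("turning") points are located by linear interpolation between the last
same-sign and first opposite-sign samples of a degree sweep — the simplest
defensible rule; an exactly zero sample is itself the turning point.

## What the synthetic conditions do and do not show

The test-suite conditions are: nominal symmetric geometry, calibrated to
12.5 ml/s at 22/45/33, default boundary chain, 10 mm stenotic length,
stenosis grid 0/25/50/75/90/100 % in the right ICA. Under these conditions
the solved network reproduces the qualitative collateral physiology:

* no ACoA cross-flow in the symmetric complete circle, and left-to-right
  ACoA flow growing with right-ICA stenosis;
* reversed (right-to-left) ACoA flow when the left A1 is absent, shrinking
  as the stenosis grows;
* total flow monotonically non-increasing with stenosis degree in every
  configuration, with the left-A1-absent configuration worst at occlusion;
* a right-PCoA reversal from posterior-directed to anterior-feeding flow at
  high stenosis degrees.

These are sign and ordering statements. The absolute flow values of any
particular patient, and 3D-CFD results on unpublished patient geometries,
are **not** reproduced — the packaged reference flow table exists precisely
so the derived-table arithmetic (percentage changes) can be checked exactly
without re-running 3D CFD.

One quantitative behaviour deserves emphasis. At the reversal point a PCoA
carries no flow, so its turning degree is set by the ratio of the baseline
anterior–posterior junction pressure gap to the stenotic resistance growth
$(1 - S/100)^{-4}$ integrated over the stenotic length. With the 10 mm
default the left-A1-absent turning point on the nominal geometry sits near
47 % (the fine-sweep test computes it); shorter stenotic segments move it
to substantially higher degrees, longer ones lower. 3D focal stenoses
produce pressure losses concentrated over a few millimetres, which is why
in-vivo and 3D-CFD turning points are typically reported at substantially
higher degrees. Users studying turning points should treat
`stenotic_length` as a first-order sensitivity:

```{r sensitivity, eval = FALSE}
net <- build_complete_cow() |> calibrate()
for (len in c(2, 5, 10, 20)) {
  fine <- run_sweep(net, variants = "LA1_ABSENT", degrees = 0:100,
                    stenotic_length = len)
  print(reversal_points(fine))
}
```

## Numerical choices and degenerate inputs

* Units are mmHg, ml/s and mm throughout, with the SI conversion constants
  (1 mmHg = 133.322 Pa) centralized in one place.
* Zero shear rate, zero flow and absent segments are exact cases, not
  limits: no division by flow occurs anywhere.
* Occlusion is edge removal; components without an inlet are excluded from
  the linear solve and reported with zero flow and their boundary pressure.
* Ties in configuration rankings break alphabetically by variant name, so
  orderings are deterministic.
* The Reynolds diagnostic uses $\mu_\infty$ (the most pessimistic
  viscosity) and blood density 1050 kg/m³; it is a laminar-assumption check
  only and feeds nothing back into the solve.

## Known limitations

Steady flow only (no pulsatility or wave propagation), rigid walls, no
junction losses, no autoregulation, no wall shear stress. The efferent
"territory" is a single lumped resistance, so intra-territory heterogeneity
is invisible. The synthetic geometry emulates dimension classes and
left-right symmetry of real circles, not any patient's anatomy: passing
tests demonstrate the solver and the collateral logic, not patient-specific
prediction.

## Test problem sizes

The suite solves the full 6 × 6 variant-by-degree grid once, a 1 %-step
fine sweep of one variant, and twenty randomized ≤ 6-segment networks
cross-checked against an independent brute-force root-finder; the whole
suite runs in well under a minute on one core. These sizes were chosen as
the smallest that exercise every code path and invariant.
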