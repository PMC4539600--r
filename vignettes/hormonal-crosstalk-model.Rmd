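---
title: "A spatiotemporal hormonal-crosstalk model of the Arabidopsis root"
author: "RootCrosstalk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatiotemporal hormonal-crosstalk model of the Arabidopsis root}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RootCrosstalk)
```

## The model

RootCrosstalk simulates the coupled dynamics of three hormones (auxin,
ethylene, cytokinin), the POLARIS (PLS) peptide, the ethylene
receptor--CTR1 signalling cascade, and the auxin carriers PIN (efflux) and
AUX1 (influx) on a two-dimensional multicellular map of the *Arabidopsis
thaliana* root tip.  Sixteen point species live on a regular grid of 2 um
x 2 um finite volumes labelled cytosol or wall (the cell wall and plasma
membrane are merged, one grid point thick); two additional membrane-bound
pools (PIN and AUX1 protein) live on the membrane faces of each cell.

### Geometry

The root map mirrors four cell files about the central axis -- epidermis,
an outer ground-tissue file, pericycle/border, vascular -- with a columella
cap and a quiescent-centre (QC) tier at the distal tip, a meristematic zone
(MZ) of short cells, and an elongation zone (EZ) whose cell lengths ramp up
shootwards.  Exact cell counts and file widths are not prescribed by
published root maps at this resolution, so the defaults are a stated
assumption, exposed in the configuration: 968 um x 224 um overall,
epidermis/outer/pericycle/vascular file widths 20/32/20/40 um per side, MZ
cells 8 um, EZ ramp 12--40 um, columella 2 x 16 um plus an 8-um QC tier.
All lengths are multiples of 4 um so the same layout discretises exactly at
both 2 um (the reference resolution) and 4 um spacing.  Row 1 is the distal
tip; tier 1 is the most distal cell tier, so "five to 25 tiers from the
tip" selects `tiers = 5:25`.

### Reactions

Reaction terms run in the cytosol and follow single-cell hormonal-crosstalk
conventions: mass-action receptor steps, Michaelis--Menten activation
factors `c/(K + c)` and saturating repression factors `1/(1 + c/K)`:

* **Auxin** -- synthesis (basal plus an ethylene-signalling-activated term
  through X) divided by a saturating cytokinin factor with a residual
  floor, minus first-order turnover.  A configuration switch
  (`ck_activates_auxin`) replaces cytokinin inhibition with activation,
  reflecting the two experimental accounts of this regulation; the shipped
  default is inhibition.
* **Cytokinin** -- synthesis restricted to the pericycle/border, vascular
  and columella cell types, inhibited by auxin; turnover everywhere.
* **Ethylene** -- basal plus a synergistic term increasing in both auxin
  and cytokinin.  Both synergy factors operate near saturation at the
  wild-type operating point, which is what makes steady-state ethylene
  nearly insensitive to the *pls* mutation while remaining strictly
  increasing in both hormones.
* **Receptor cascade** -- auxin activates its receptor (Ra to Ra*);
  ethylene binding deactivates the ethylene receptor ETR1 (Re* to Re)
  while PLS protein promotes the active pool; active receptor activates
  CTR1; downstream ethylene signalling X is produced under CTR1*
  repression and decays first order.  Each pair conserves its total.
* **PLS** -- transcription induced through Ra* and repressed by X;
  translation and decay.  The *pls* genotype zeroes functional PLS
  production; PLSox adds a constitutive term; an ablation switch replaces
  the Ra* factor by a constant to remove the auxin dependence.
* **PIN** -- transcription = basal x (auxin-increasing factor) x
  (X-increasing factor) x (cytokinin repression); translation into a
  cytosolic pool that exchanges with the membrane pool by recycling.
* **AUX1** -- transcription increasing in X above a basal floor.

X is modelled as a concentration-like species with first-order decay;
"high ethylene signalling" thresholds are smooth saturating functions, not
steps.  PLS promotion acts on the Re to Re* reactivation step, the
direction established in single-cell models of this network (Liu et al.
2010).

### Transport

Hormones diffuse in the cytosol and the wall network; ethylene and
cytokinin additionally cross membrane faces freely (plain diffusion).  All
other species diffuse only between cytosol points of one cell (mRNAs and
receptor species are solved pointwise, i.e. at zero diffusivity, by
default).  Auxin crosses membranes only through carriers: influx
`P_AUX1 * g(sigma_AUX1) * auxin_wall` and efflux
`P_PIN * h(sigma_PIN) * auxin_cyt`, where sigma is the local membrane
carrier density (concentration x spacing, in uM um) and g, h are linear
below a saturation cap and normalised so the reference density gives the
nominal permeability.  The cap prevents runaway positive feedback through
the auxin -> PIN -> efflux loop; densities are expressed per unit membrane
length so the scaling is grid-independent.

PIN polarity is prescribed per cell type, forming the familiar reflux
loop: vascular and pericycle cells carry PIN on rootward faces, epidermis
and the outer file on shootward faces, columella and QC on
lateral-outward faces.  The outer ground-tissue file is given shootward
polarity (like the epidermis) so that the outer layers return auxin
shootwards; without it the outer file becomes a diffusive auxin trap and
the tip maximum degrades.  The *amount* of PIN on those faces is dynamic:
exocytosis delivers the cytosolic pool uniformly to the allowed faces and
endocytosis (inhibited by auxin for PIN, unregulated for AUX1) returns it,
conserving total carrier protein.  AUX1 is distributed over all membrane
faces.

At the shoot boundary (the proximal wall row), auxin flows in over the
pericycle and vascular files at a rate repressed by local downstream
ethylene signalling, `I0/(1 + X/K_X)`; auxin leaves over the epidermal
files in proportion to the local shootward membrane PIN; ethylene and
cytokinin exchange diffusively against fixed shoot-side reference
concentrations.  The shoot itself is not modelled.

## Numerics

Each grid point is a finite volume; fluxes are integrated over the faces
between points.  Steady states are found by implicit pseudo-time stepping
to stationarity (robust for stiff positive systems), with the nonlinear
reaction and carrier terms re-linearised by Picard sweeps within each
backward-Euler step.  The linear systems for ethylene, cytokinin and the
cytosolic PLS protein are symmetric positive definite and are solved by
preconditioned conjugate gradients (Cholesky preconditioner by default,
Jacobi available) to a relative residual of 1e-10; the auxin system (whose
carrier terms make it structurally asymmetric, since influx and efflux act
on different sides of each membrane face) and the PIN/AUX1
recycling-coupled systems use a sparse direct factorisation instead.  The
Picard tolerance is 1e-5.  Halving both tolerances changes steady
concentrations by well under 0.1%, the standard robustness check, which
the test suite reproduces.

The pseudo-time step grows geometrically from 0.5 s to its cap; because
every implicit loss term is diagonal and every source non-negative, each
species' system is an M-matrix and the iteration preserves non-negativity
at any step size.  Stationarity is declared when the maximum relative rate
of change of every species falls below `steadyTol` (1e-7 per second) and
the last Picard update is below 1e-5.  Receptor pairs are updated by exact
pointwise 2x2 backward-Euler solves, which conserve each pair total to
machine precision.

A time-dependent mode (`integrateModel`) provides plain explicit-Euler
integration of the same semi-discretisation and serves as the
cross-method oracle: on a small fixture the Picard steady state and a long
explicit integration agree to better than 0.1% per species.  The test
suite runs this oracle with a slow-diffusion parameter variant so the
explicit stability limit stays affordable.

Problem sizes: the reference grid is 2 um (485 x 113 points); the test
suite and the acceptance script solve the same layout at 4 um (243 x 57
points, half the reference resolution) and miniature fixture maps, sizes
chosen so a full genotype batch completes in minutes on one CPU.  Grid
refinement on the miniature map (4 um vs 2 um) moves region-averaged
steady concentrations by a bounded amount (tested under 50%; typically a
few percent for the hormones).

## Parameters and calibration

Literature values are used where available: auxin diffusion 220 um^2/s,
PIN efflux permeability 2.5 um/s (within the experimentally reported 0.5--5 um/s range),
AUX1 influx permeability 1.5 um/s, and the influx at least as strong as
the efflux at reference densities so cells are not depleted of auxin.  The
*aux1* mutant halves the influx permeability (other influx carriers
remain); *etr1* reduces the ethylene-binding (receptor-deactivation) rate
to 6.5% so the receptor keeps signalling, i.e. dominant ethylene
insensitivity; PLSox switches on a constitutive PLS transcription term.
The *etr1* reduction and the PLSox term are free fitting knobs, set once so
the mutant trend suite holds.

All remaining constants were calibrated once, following the fitting
model-fitting criteria below, not any numerical target: a wild-type
auxin maximum at or close to the QC; carriers predominantly at the
membrane; cytokinin higher in the vascular and pericycle files than the
epidermis; ethylene increasing shootwards; and the wild-type/mutant trend
suite (auxin *pls* < *pls etr1* <= wild type; ethylene unchanged in *pls*;
cytokinin and PIN raised in *pls*; shoot-to-root auxin flux *pls* < wild
type <= *pls etr1*).  `parameterTable()` lists every constant with units
and provenance.  Two calibration choices deserve note:

* The shoot-side ethylene reference is above the interior production
  level, so ethylene rises shootwards (the observed response pattern);
  because the ethylene synergy factors are near saturation, this gradient
  is insensitive to genotype.
* Cytokinin's auxin-inhibition constant is small (0.03 uM) so that the
  roughly two-fold auxin drop in *pls* converts into a near two-fold
  cytokinin rise; cytokinin diffusion is moderate (60 um^2/s) so the
  lateral contrast between the synthesising central files and the
  epidermis survives.

## What the trend comparisons do and do not show

Profiles can be extracted per grid row or per cell tier; tier averaging
(all points of a tier, membrane pools included for carrier totals) smooths
the strong membrane/cytosol contrast of PIN, which is why PIN patterns are
compared on tier profiles.  A profile "has a distal maximum" when its
maximum lies in the distal third of the axis *and* the distal-third mean
exceeds the proximal-third mean by at least 1.2-fold; the prominence
requirement is what distinguishes the wild-type PLS pattern from the
near-flat profile produced when auxin regulation of PLS transcription is
ablated (a weak residual gradient through X repression remains, and a bare
argmax test would count it as a maximum).

Pattern checks against imaged profiles are evaluated over the root-tip
region the imaging covers (the columella/QC, meristematic zone and the EZ
ramp; tiers 1--45 of the default layout).  The last few tiers sit in the
boundary layer of the shoot-side influx -- an artefact of cutting the
domain at the shoot boundary -- and are excluded from pattern judgements,
exactly as a cropped micrograph of the tip would exclude them.

Comparisons against experimental images are trend-level only: image
intensities are unitless responses, so profiles are normalised to their own
maximum when set against image-derived data, and agreement is judged on
monotonicity, extremum location and rank correlation (`trendCompare`),
never on absolute values.

## Known limitations

The map has no lateral root cap, no growth or cell division, and no third
dimension; cytokinin patterning along the axis follows the model's
auxin-inhibition logic (rising shootwards), which is the opposite of some
response-reporter images -- a known open discrepancy between this class
of model and reporter imaging.  PIN isoforms are lumped (PIN3/PIN7 cytokinin effects assumed to
cancel); the *pls etr1* double mutant's PIN pattern is reproduced only in
part, a known limitation of the network.  The
synthetic fields the generator produces are smooth steady states: they do
not emulate image noise, reporter nonlinearity or biological variability,
so passing trend tests shows the network logic reproduces the observed
orderings, not that the model fits any particular image quantitatively.

## A worked example

```{r example, eval = FALSE}
map <- buildRootMap(defaultGridSpec(spacing = 4))
wt  <- picardSteadyState(map, defaultParameters(), "wt")
pls <- picardSteadyState(map, defaultParameters(), "pls")

foldChange(pls, wt, "CK")          # whole-root cytokinin fold change
longitudinalProfile(wt, "auxin")   # row profile; maximum near the QC
totalRootwardFlux(wt)              # shoot-to-root auxin flux ledger
exportColormap(wt, "auxin", "auxin_wt.png")
```
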