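---
title: "Models and methods behind psbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind psbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psbind)
```

psbind analyses protein binding by phosphorothioate (PS) antisense
oligonucleotides from two directions: solution affinities measured by
fluorescence-anisotropy titration, and per-linkage Rp/Sp stereochemistry
read from atomic models together with sulfur anomalous difference maps.
This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-data generators do and do not
emulate. Units are micromolar for concentrations and Angstrom for
coordinates throughout.

## The binding model

A labelled oligonucleotide probe at total concentration
$\mathrm{RNA_{tot}}$ is titrated with protein at total concentration
$\mathrm{Prot_{tot}}$. Binding is 1:1, with an additional *noncompetitive
nonspecific* interaction that sequesters a fixed fraction $\mathrm{NS}$
of the total protein into a complex that changes the anisotropy like the
specific one but does not deplete the probe:

$$A = A_0 + \Delta A \cdot
  \frac{\mathrm{Prot_{RNA}} + \mathrm{NS}\cdot\mathrm{Prot_{tot}}}
       {\mathrm{RNA_{tot}}}$$

subject to mass conservation
$\mathrm{RNA_{tot}} = \mathrm{RNA_{free}} + \mathrm{Prot_{RNA}}$,
$\mathrm{Prot_{tot}}(1-\mathrm{NS}) = \mathrm{Prot_{free}} +
\mathrm{Prot_{RNA}}$ and mass action
$\mathrm{Prot_{free}}\cdot\mathrm{RNA_{free}} =
K_D\,\mathrm{Prot_{RNA}}$. Eliminating the free species gives a
quadratic in the specific complex $x = \mathrm{Prot_{RNA}}$ whose
physical root is

$$x = \frac{b - \sqrt{b^2 - 4 P' R}}{2}, \qquad
  P' = \mathrm{Prot_{tot}}(1-\mathrm{NS}),\;
  R = \mathrm{RNA_{tot}},\; b = P' + R + K_D .$$

The "minus" root is the physical one — the other root exceeds
$\min(P', R)$, violating conservation. `bound_complex()` evaluates it in
the cancellation-free form $2P'R/(b + \sqrt{b^2-4P'R})$, which matters
in the tight-binding regime where $b^2 \approx 4P'R$.

Two properties of the model deserve emphasis:

* **The nonspecific term does not saturate.** Its signal contribution
  $\Delta A \cdot \mathrm{NS}\cdot\mathrm{Prot_{tot}}/\mathrm{RNA_{tot}}$
  grows linearly in protein without bound. With a 50 nM probe and
  protein up to 120 uM, even $\mathrm{NS} = 10^{-3}$ contributes more
  than a full $\Delta A$ at the top of the titration. The model is
  implemented exactly as formulated — the linear tail is a feature the
  AIC test is meant to detect, not a defect to correct — but users
  should read fitted NS values with the probe/protein ratio in mind.
* **Weak binders sit near an identifiability boundary.** When the true
  $K_D$ approaches the highest protein concentration, the specific
  isotherm never saturates and becomes nearly collinear with the linear
  NS term and with $\Delta A$. Estimates there carry large and
  correlated uncertainties; `fit_global()` reports standard errors from
  the local quadratic approximation so this shows up honestly, and the
  flat-data guard refuses to report a tight $K_D$ when $\Delta A$ is
  indistinguishable from zero.

### Fitting, model selection, outliers

Replicate series of one oligo/condition system are fitted *globally*:
one shared $(K_D, A_0, \Delta A, \mathrm{NS})$ across all points, by
bounded Levenberg-Marquardt least squares (`minpack.lm`), equal weights.
Starting values are data-driven ($A_0$ = minimum anisotropy, $\Delta A$
= observed range, $K_D$ = concentration at half-range, NS = 0.01) with a
small deterministic geometric multistart on $K_D$ (factors 1, 0.2, 5,
0.05, 20) because the optimiser can stall in the wrong basin when the
half-range heuristic lands far from the truth. NS is shared across
replicates of one condition but never across conditions.

The nonspecific hypothesis $\mathrm{NS} > 0$ is always tested against
$\mathrm{NS} = 0$ with the least-squares Akaike Information Criterion,
$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2k$, where $k$ counts the free
model parameters plus one for the noise scale. Lower AIC wins; exact
ties keep the simpler model.

Outlier handling is a **single screening pass**: internally studentized
residuals at the selected fit (residual over
$s\sqrt{1-h_{ii}}$, leverages from the numerical Jacobian), flag
$|r| > 3$, refit both models once on the reduced set, reselect. No
iteration to exhaustion — repeated screening on re-fitted models can
chase its own tail. If more than 20% of points would be flagged the
function refuses: that is model misfit, not outliers. The choice of the
3-sigma studentized rule is a declared convention; the published
analyses this package re-implements removed outliers without stating
their criterion, so determinism and transparency were the selection
criteria here. (With the 3-sigma cutoff and equal displacement the
flagged fraction is mathematically bounded near 13%, so the 20% guard
fires only for pathological leverage patterns; it is kept as a
defensive contract and is configurable.)

### The simulator and its defaults

`simulate_titration()` adds homoscedastic Gaussian noise to the exact
model curve — the published fits weight all points equally, which
implies that assumption. Defaults mirror the standard plate design:
probe 50 nM, 12 log-spaced protein concentrations over 0.1–120 uM,
triplicate. The default generating parameters used across the analysis
scripts are $A_0 = 0.10$ and $\Delta A = 0.15$ (typical Cy3 anisotropy
scales), noise SD 2% of $\Delta A$ (0.003, a realistic plate-reader
precision), and $\mathrm{NS} = 2\times10^{-4}$, chosen once so that the
unsaturating nonspecific term contributes a modest fraction (~half of
$\Delta A$) at the top of the titration — larger values make the linear
tail dominate the curve, smaller ones make it undetectable. What the
simulator does *not* emulate: pipetting-series correlation, intensity
changes upon binding (only anisotropy is modelled), inner-filter
effects, and probe depletion errors; recovery results on synthetic data
therefore bound what the pipeline can do on ideal data, not on every
real plate.

## Stereochemistry calling

A phosphorothioate replaces one non-bridging phosphate oxygen with
sulfur, making phosphorus a stereocentre with Rp and Sp configurations.
`extract_linkages()` walks each chain 5'→3' and builds one linkage per
internucleotide phosphate from P, the 3'-residue O5', the 5'-residue
O3' and the non-bridging atoms (OP1/OP2 and sulfur substitutions,
all altlocs); incomplete backbones are skipped with a warning, never
fatally.

**Configuration from coordinates.** CIP priorities at phosphorus are
S > O3' > O5' > O(non-bridging); O3' outranks O5' on the
next-sphere substituents. `assign_chirality()` evaluates the signed
volume of the priority-ordered substituent vectors,
$(v_1-v_4)\cdot((v_2-v_4)\times(v_3-v_4))$; negative volume means Rp.
That sign→label constant was calibrated once against an independent
CIP construction (project the top three substituents onto the plane
normal to the P→lowest-priority direction, read the 1→2→3 sense from
the opposite side; clockwise = R) and then frozen; the test suite keeps
both implementations and checks them against each other on randomly
programmed strands. Near-coplanar geometry (normalised volume below
0.05) is refused rather than guessed.

**Peaks and the four-way call.** The two candidate non-bridging sites
come from the model's dual-altloc atoms when present, otherwise they
are constructed at ideal tetrahedral positions (P–S 1.95 A).
`peak_height()` reports the maximum trilinearly interpolated map value
over the query position and all grid nodes within 1.0 A, in sigma
units. A maximum (not an integral) is used because anomalous peak
inspection is conventionally done against a contour level.
`classify_linkage()` then applies, in order:

1. *Reliability*: mean B-factor of the phosphate group above 60 A^2
   → `indeterminate`, `reliable = FALSE`. Disordered phosphates do not
   produce interpretable anomalous density; ~60 A^2 is where clearly
   defined sulfur densities stop being observed at ~2 A anomalous
   resolution.
2. *Contour*: neither site ≥ 3.5 sigma (the conventional display
   contour for such maps) → `indeterminate`.
3. *Dominance*: one site ≥ 3.5 sigma and ≥ 1.5× the other → that
   configuration; both above threshold within the 1.5 margin →
   `mixed`, i.e. the dual 0.5-occupancy modelling convention. The
   published criterion distinguishes "clearly indicated" from "evenly
   distributed" density qualitatively; the 1.5-fold margin is this
   package's declared quantitative substitute, exposed as an argument.

All three thresholds (`threshold_sigma`, `b_max`, `ratio_margin`) are
arguments with the defaults above.

### Synthetic strands and maps

`build_ps_strand()` places phosphate groups on idealized B-form helical
parameters (twist 36°, rise 3.38 A, phosphate radius 8.9 A) with
metrically correct local geometry: bridging P–O 1.59 A, non-bridging
P–O 1.48 A, P–S 1.95 A, tetrahedral angles. Sugars and bases are not
built — sugar pucker, base stacking, duplex mismatch geometry and
crystal packing are explicit non-goals; only the phosphate-group
geometry that the chirality and peak machinery consumes is faithful.
Programmed `"mixed"` linkages become two 0.5-occupancy altloc
conformers (A = Rp sulfur, B = Sp sulfur).

`render_anomalous_map()` deposits an isotropic Gaussian of width 0.9 A
(the peak width regime of ~2 A anomalous data) at every sulfur,
occupancy-weighted, plus optional Gaussian voxel noise, on a 0.5 A
grid; the result is sigma-normalised by construction. The default full
occupancy blob height of 8 sigma emulates a well-measured sulfur
anomalous peak — chosen so that a half-occupancy site (4 sigma) still
clears the 3.5 sigma contour, as mixed-population sulfur sites do in
good experimental maps. Real anomalous maps differ in ways the
generator deliberately ignores: anisotropic and series-termination
ripple, peak-height dependence on B-factor and data completeness, and
solvent noise structure. Passing the round-trip tests therefore shows
the calling logic is correct, not that every real map at these nominal
levels would be called this cleanly.

## Contacts and superposition

`find_contacts()` declares a contact when the interatomic distance is
at most the sum of Bondi van der Waals radii (C 1.70, N 1.55, O 1.52,
S 1.80, P 1.80 A) plus a 0.5 A tolerance; a contact is *polar* when
both partners are N/O (or S paired with N/O) within 3.5 A, otherwise
*hydrophobic* when either partner is carbon or sulfur. Published
figures draw such contacts without printing cutoffs, so the radii set
and both cutoffs are exposed arguments with these documented defaults.
Altloc ambiguity is resolved to the highest-occupancy conformer unless
`all_altlocs = TRUE`. `find_water_bridges()` reports waters polar-bonded
to both selections simultaneously (the backbone-carbonyl water bridge
pattern); it requires water atoms to be present in the model.
`summarize_pocket()` ranks residues by hydrophobic contacts to PS
sulfur atoms specifically, because that is the interaction the analysis
is about.

`match_calpha()` pairs C-alpha atoms through global sequence alignment
(identity scoring +2/−1, gap open 10, extension 0.5 — conservative for
near-identical chains) and keeps only aligned identical residues;
fewer than 30 pairs is treated as insufficient overlap.
`superpose()` computes the closed-form Kabsch rotation (SVD with
reflection correction, determinant forced to +1) and then runs at most
5 rejection cycles, dropping pairs deviating more than 2.0× the current
RMSD and refitting. This emulates the common behaviour of structure-
alignment tools whose exact settings are rarely printed; published
"RMSD over N atoms" figures are therefore reproduced by protocol shape,
within tolerance, not bit-exactly. The RMSD sequence is non-increasing
by construction and is reported as `rmsd_history`.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and restores the
caller's RNG state. The test suite and the acceptance script use
problem sizes chosen to make Monte-Carlo conclusions stable while
staying quick: 50-seed recovery studies for $K_D$ and AIC behaviour,
50 random strand specifications for the stereo round trip, $10^4$
random draws for the quadratic-root/bisection equivalence, 100
simulated experiments for the bias/coverage property, ~300-residue
chains for superposition. These sizes are the package's own
reproducibility choices; all headline numbers quoted anywhere in the
documentation are computed by those scripts at run time, never stored.

## Known limitations

* The nonspecific binding term is phenomenological and unsaturating;
  fitted NS values are design-dependent and not transferable between
  probe concentrations.
* Chirality assignment requires the two non-bridging positions to be
  resolved or constructible; grossly distorted phosphates (volume
  threshold) are refused rather than called.
* The map reader supports orthogonal cells (mode 2), which covers the
  synthetic maps and orthorhombic/cubic experimental maps; maps in
  non-orthogonal cells must be resampled upstream.
* Contact classification is geometric only — no energies, no
  solvent-accessibility screening, no angular criteria for hydrogen
  bonds.
* The sequence-alignment pairing assumes numbering-independent but
  sequence-identical residues; homologous (non-identical) positions
  are never paired, which is the desired behaviour for comparing
  refinements of the same protein but too strict for remote homologs.
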