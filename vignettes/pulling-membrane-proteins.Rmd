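---
title: "Simulating force spectroscopy of helical membrane proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating force spectroscopy of helical membrane proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mempull)
```

## The problem

Single-molecule force spectroscopy unfolds membrane proteins one structural
element at a time: an AFM cantilever pulls a terminus vertically out of the
bilayer, or magnetic tweezers stretch the chain laterally within the membrane
plane. The measured force-extension curve (FEC) shows a sawtooth of rupture
events, and the open question is which interactions set the height of each
force peak: backbone hydrogen bonds, packing between helices, or the
protein-membrane interaction.

`mempull` provides a coarse-grained model in which each of those interaction
groups carries its own strength scale factor (`lambda_hb`, `lambda_pp`,
`lambda_memb`), so their contribution to rupture forces can be dialled
independently, together with the full analysis pipeline for the resulting
trajectories (rupture detection, replica alignment, NH-vector rotation
analysis, contact and H-bond fractions, Bell-Evans and worm-like-chain fits).

## The model

**Resolution.** Three backbone sites per residue (N, C-alpha, C). The amide
H, carbonyl O and a side-chain bead C-beta are pure functions of the
backbone: H and O are placed on the bisector construction at the N and C
atoms, C-beta by the standard ideal-geometry reconstruction from N/CA/C.
This is the minimum resolution at which backbone hydrogen bonds are
*directional* and the NH bond vector used by the rotation analysis is a
literal geometric object.

**Units and frame.** Energies are in kBT at the simulation temperature,
lengths in Angstrom, the bilayer midplane is z = 0 and the membrane normal
is +z. The reduced temperature is 0.85, mapped to 300 K only when forces are
reported in pN (1 kBT/A = 41.42 pN at 300 K; the default spring constant
0.05 kBT/A^2 is about 21 pN/nm). Residue indices are 1-based and helix
ranges closed intervals, the native R convention.

**Energy terms.**

* *Bonded*: bond and angle springs about ideal backbone geometry plus a
  torsion bias toward the helical basin (phi = -60, psi = -47) and trans
  omega. The phi/psi bias (3 kBT) carries much of the helical propensity, as
  in other three-bead backbone models.
* *H-bonds* (`hb`): every donor-acceptor pair with H...O distance below 3 A
  and N-H...O angle above 120 degrees contributes
  `-lambda_hb * eps_hb * s(geometry)`, with `s` a C1 switching function that
  saturates at 1 well inside the cutoffs (an ideal helix scores exactly 1
  per i -> i-4 bond). Detection is not restricted to native pairs; non-native
  bonds formed during unfolding count, but with a Go-type reduced well depth
  (`nonnative_hb_scale = 0.45`). Without that bias the helical register
  random-walks through i -> i-3 / i -> i-5 slips at this temperature.
* *Side-chain contacts* (`sc_sc`): native inter-helix C-beta pairs (within
  8 A in the built structure) sit in smooth wells centred at their native
  distance; all pairs additionally feel a soft excluded-volume repulsion
  that no lambda ever scales, so `lambda = 0` systems remain physical
  chains.
* *Burial* (`cb_burial`, `bb_burial`): a smooth, saturating function of the
  neighbour count within 6.5-9.5 A, favourable for hydrophobic residues --
  a multibody desolvation term.
* *Membrane* (`cb_membrane`, `hb_membrane`): each residue's transfer free
  energy `dG_transfer` weighted by the depth profile
  `f(z) = 1/(1 + exp((|z| - T/2)/w))` (interface width `w` = 3 A) and
  attenuated by a shielding factor proportional to the burial saturation,
  capped at `shield_max = 0.6` -- a residue in a small bundle never loses
  all lipid contact. Backbone polar groups inside the slab pay `eps_unsat`
  when their H-bond is unsatisfied and gain a bonus when satisfied, which is
  what makes helices the stable secondary structure inside the core.

All switching functions are polynomial smoothsteps, so every term is C1 and
the analytic forces match finite differences to a relative error below
1e-4 (this is asserted by the test suite).

**Default hydrophobicities.** Hydrophobic residues -4 kBT, polar +0.5 kBT,
charged +4 kBT, editable per builder call. An early calibration with -2 kBT
for the hydrophobic class left the membrane unable to hold the folded bundle
against the cantilever (the whole protein slid out bodily at forces below
the first rupture), so the class value was deepened once and frozen; only
the relative ordering of conditions enters the trend analyses.

**Synthetic systems.** `build_tm_bundle()` places ideal helices on a
serpentine lateral grid with alternating up/down orientation (the C-terminal,
pulled helix always points up so the pulled terminus is on the +z side),
joins them with surface linkers, and relaxes the assembly to a local
minimum; native contacts and H-bonds are measured on the relaxed structure.
Each helix carries two charged (lysine) cap residues at both ends. The caps
matter: an idealized all-hydrophobic helix has no reason to stand
perpendicular to the membrane and prefers to lie flat in the midplane;
the polar caps anchor its ends at the two interfaces, as the charged flanks
of natural TM helices do. `build_single_helix_probe()` builds the one-helix
test systems with neutral `(Gly)5` or +3e `(Arg)3(Gly)2` tails.
`load_pdb()` ingests a pre-oriented single-chain PDB structure (helices
annotated from the i -> i-4 H-bond pattern); this path is provided for
completeness and is exercised only on synthetic files in the tests.

## Dynamics

The integrator is single-timestep overdamped Langevin (Euler-Maruyama):
`dr = (dt/gamma) F + sqrt(2 kBT dt/gamma) eta`, with `dt = 0.01` and
`gamma = 1` in reduced units, chosen so that the stiffest modes (bond
springs, H-bond switching regions) stay well inside the stability limit and
the equipartition test passes to a few percent. Rare near-singular
geometries (collinear torsions, degenerate bisectors) are handled by
skipping the ill-defined torsion and clipping per-site gradients at
35 kBT/A, far above any physical force scale in the model; a site moving
more than 2 A in one step still aborts the run with an error naming the
step. Noise comes from mt19937_64 with a built-in ziggurat sampler, so a
trajectory is a bit-reproducible pure function of (system, parameters,
protocol, seed) on any platform.

An important consequence of overdamped dynamics with per-site friction is
that collective motion is slow: dragging an n-site segment at speed `v`
costs a force of about `v * n * gamma / dt`. The pulling velocity therefore
sets a viscous force floor under the FEC, and clean force *relaxation* after
a rupture requires pulling much slower than the freed chain can pay out
slack. The packaged demonstration scales (below) choose the fastest
velocities at which the rupture phenomenology of interest survives; at
those speeds FECs carry a drag baseline that a true quasi-static experiment
would not have. Absolute forces are therefore not comparable to experiment
-- only differences and orderings between conditions, which share the same
baseline by seed pairing, are interpreted.

## Pulling protocols

* **Vertical, stiff spring** (AFM-like): spring on the C-terminal C-alpha,
  retracted along +z at `velocity` Angstrom per step (default 0.001, the
  protocol value used for the headline simulations in the source study).
* **Lateral** : tension along +x with the N-terminal residue held by a
  second, fixed spring; extension subtracts the anchored end's displacement.
* **Soft spring / force clamp** (magnetic-tweezers-like): a near-zero
  spring constant (0.002 kBT/A^2) keeps the force nearly constant after a
  rupture; `force_clamp` applies a constant force exactly.
* **Helix restraints**: harmonic restraints on the native helical
  donor-acceptor distances (10 kBT/A^2), the "helices stay helical"
  perturbation.

## Analysis pipeline

`extract_fec()` subsamples every 5th frame and smooths force with a
50-point moving average (both configurable and recorded as metadata);
sharper event work uses 25-point windows and the turning analysis smooths
spring energy with a Gaussian filter whose width of 25 points is
interpreted as sigma = width/5. `detect_ruptures()` finds local maxima by
prominence (default 20 percent of the series range) with a minimum peak
separation; a terminal monotone rise -- the contour-length limit -- never
produces a local maximum and is never reported. `detect_turning()` finds
the first crossing of the second helix's NH projection through -0.5 toward
zero, reads the Gaussian-smoothed spring energy there, divides by the
window maximum, and calls the turning part of the rupture when that
fraction reaches 0.8. `align_average_responses()` shifts each replica so
its maximum spring energy sits at offset zero and averages negated
interaction energies pointwise with an SD band. `bell_evans_fit()` is a
least-squares line in log-velocity; `wlc_fit()` fits the worm-like-chain
interpolation formula with `minpack.lm`, rejecting points beyond the
contour estimate and constraining the fitted contour length above the
largest retained extension.

Per-frame metrics count an H-bond as formed when its switching value `s`
reaches 0.25 -- deliberately lenient, because at this resolution thermal
wobble takes individual bonds through the switching region constantly, and
a 0.5 threshold would read an intact, breathing helix as half-melted.

## Demonstration scales

The packaged tests and the acceptance script run scaled-down study systems
chosen once: a 4-helix bundle of 14-residue helices (21 A membrane) for
vertical pulling, a 6-helix bundle of the same helices for lateral pulling,
and 14-residue single-helix probes. Replica counts follow the study design
(10-20 seeds per condition, seed-paired across conditions so that
direction-of-effect comparisons cancel the shared baseline). Velocities of
1e-4 to 2e-4 Angstrom per step are used, and the perturbation runs are
pre-tensioned (`initial_offset`) so that the fixed measurement window
covers the rupture region rather than the quiescent loading phase; the
"first-event force" at this scale is the peak of the smoothed force over
that seed-paired window.

What these scaled-down reproductions show -- and what they do not.
Reproduced cleanly: helix restraints raise rupture forces strongly;
doubling the membrane potential raises the extraction force of an isolated
(lipid-exposed) helix relatively more than the first bundle event; charged
versus neutral tails and moderate membrane-thickness changes are null
effects; sawtooth rupture events appear at the slower velocities. Known
departures at this scale, measured and reported honestly by the test suite
rather than hidden: the first vertical rupture is membrane- and
packing-dominated because the small helices can exit largely intact, so
its force is nearly insensitive to the H-bond scale factor (in the
underlying study, where helices must unfold to thread out, H-bonding
dominates); helix pairs do not reliably exit as tight pairs because
overdamped per-site friction broadens exit timing; and the lateral
contact-versus-H-bond loss ordering is confounded by the coarse helix's
register wobble, which erodes the native H-bond count before the helices
have fully separated. The model also does not reproduce absolute rupture
forces of any real protein, real time scales, or sequence-specific
behaviour: the synthetic bundles are idealized poly-leucine architectures,
the membrane is an implicit smooth slab, and the pulling is orders of
magnitude faster than experiment.

## Numerical choices and degenerate inputs

* Smoothing uses reflected boundaries and is length-preserving and
  idempotent on constants; windows larger than the series are an error.
* Rupture detection on ties (plateaus) reports the plateau centre.
* `wlc_fit()` rejects extensions at or beyond the contour estimate before
  fitting (the formula diverges there) and reports how many points were
  dropped.
* `rupture_statistics()` excludes replicas lacking the requested event and
  reports how many contributed; fewer than two is an error.
* Zero-length runs, non-positive time steps, windows below one point and
  negative spring constants are rejected with "invalid argument" errors.
* The chirality of the backbone means a bare z-reflection is not an energy
  symmetry (it would produce the mirror-image protein); the symmetric-slab
  invariance is expressed as the proper rotation that flips the protein
  upside-down, and that is what the tests assert.

## Known limitations

* The membrane is implicit and rigid: no lipid rearrangement, no water
  penetration, no lateral pressure profile.
* Overdamped per-site friction makes collective drag scale with segment
  size (see *Dynamics*); post-rupture relaxation is slower than in an
  inertial simulation, and pair-extraction timing statistics are broadened
  by it.
* The coarse helix has a soft H-bond register; equilibrium helicity of an
  unrestrained bundle fluctuates around 0.6-0.8 by the lenient counting
  criterion rather than 1.0.
* PDB input is untested against real membrane-protein structures; helix
  annotation on experimental coordinates may differ from other assignment
  tools.
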