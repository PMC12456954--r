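---
title: "Mesoscale simulation of multiphase PSD condensates: models and methods"
author: "psdmeso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale simulation of multiphase PSD condensates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdmeso)
```

## The model

`psdmeso` simulates liquid–liquid phase separation of the four core
components of the postsynaptic density (PSD) upper layer at domain
resolution: the AMPA receptor in complex with four TARP auxiliary subunits,
the NMDA receptor with two GluN2B C-terminal tails (GluN2Bc), the scaffold
PSD-95, and the dodecameric kinase CaMKII.  Every globular domain or
segment is one spherical particle; the four complexes are 5, 3, 6 and 13
particles respectively.  CaMKII is a central hub particle flanked by two
hexagonal rings of six kinase particles, held by hub–kinase, ring-neighbor
and inter-ring harmonic bonds so each ring defines a stable plane — the
plane the orientation analysis measures.

A particle representing a domain of $N$ residues has radius
$R_n = 0.224\,N^{0.392}$ nm, hydrodynamic radius $R_h = 1.45\,R_n$, and
Einstein–Stokes diffusion coefficient $D = k_B T / (6\pi\eta R_h)$ with
cytoplasmic viscosity $\eta = 0.89$ mPa·s at 300 K.  In membrane mode,
membrane-embedded domains use ten times the cytoplasmic viscosity.  In the
soluble (3D) system the receptor cores are the fluorescent proteins used in
the corresponding reconstitution experiments (DsRed2, $N = 936$; eqFP670,
$N = 482$); in the membrane (2D) system they are the transmembrane
assemblies.  Residue counts the source structures do not pin down (tails,
scaffold domains, linker lengths, 2D receptor cores) are reconstructions at
UniProt scale, shipped as an editable table in
`inst/extdata/domain_params.tsv`; `domain_params()` loads it.

The total potential decomposes as
$$V_{total} = V_{bond} + V_{angle} + V_{dihedral} + V_{spe} + V_{nonspe} + V_{system}.$$

* **$V_{bond}$** — intra-complex harmonic bonds with
  $k = 10$ kJ/mol/nm² (receptor–tail, hub–kinase, CaMKII cage bonds), plus
  PSD-95 inter-domain linkers modeled as ideal-chain entropic springs with
  $k_{link} = 3 k_B T / (n\,b^2)$, $b = 0.38$ nm per residue.  The linker
  constant is the standard Gaussian-chain result; only the statement that
  the constant is set by the linker length is inherited, the functional
  form is this package's choice.
* **$V_{angle}, V_{dihedral}$** — zero.  The CaMKII shape is maintained
  entirely by its bond network, so no angle/dihedral table is exposed; the
  two slots remain in the decomposition for completeness.
* **$V_{spe}$** — harmonic restraints of currently formed specific bonds
  (below), rest length at domain contact, $k = 10$ kJ/mol/nm².
* **$V_{nonspe}$** — soft excluded volume,
  $\tfrac12 k_{rep}(d - r_i - r_j)^2$ for $d < r_i + r_j$ and zero beyond
  contact, $k_{rep} = 10$ kJ/mol/nm², applied to every particle pair not
  joined by a structural bond.  Soft-sphere repulsion of this magnitude is
  the convention of interacting-particle reaction-dynamics engines.
* **$V_{system}$** — in membrane mode, the implicit membrane:
  membrane-compartment domains feel a flat-bottomed well
  ($0$ for $|z| < D_{mem2}$, harmonic walls outside, $k_{mem} = 10$
  kJ/mol/nm², $D_{mem2} = 2.5$ nm), cytoplasmic domains are excluded from
  $z \ge -D_{mem2}$.  Slab runs add a temporary harmonic z-confinement
  that is removed at a configured release step.

**A note on the periodic cytosol.**  All modes use minimum-image periodic
boundaries in three axes.  In membrane mode the flat cytosolic region
would otherwise touch the periodic $z$ boundary: a particle diffusing to
the bottom of the box would reappear above the membrane inside the penalty
region and be driven violently back through it.  The package therefore
closes the cytosol with a soft harmonic floor at $z = -L_z/2 + D_{mem2}$
(same $k_{mem}$), which makes both sides of the boundary repulsive.  Near
the membrane — where all observables of interest live — the potential is
unchanged; the floor only replaces an unphysical wrap-through with a
reflecting wall, and the Boltzmann-distribution test in the suite covers
the full resulting density.

## Dynamics

The overdamped Langevin equation is integrated with the Euler–Maruyama
scheme: per particle and step
$\Delta x = (D_i / k_B T) F_i \,\Delta t + \sqrt{2 D_i \Delta t}\,\xi$,
$\xi \sim \mathcal N(0,1)$ per axis, $\Delta t = 0.25$ ns, $T = 300$ K.
Gaussian draws come from a single explicit xoshiro256++/ziggurat stream in
fixed particle order, so single-threaded runs are bitwise reproducible for
a given seed, and checkpoint/resume continues the identical trajectory.
Pair interactions use a linked-cell neighbor list rebuilt every step with
cell edge at least the maximum interaction distance.

At the default timestep the stationary distribution of a harmonic degree
of freedom carries an $O(\theta\,\Delta t)$ Euler–Maruyama bias
($\theta = kD/k_BT \approx 1$/ns for the membrane walls), inflating the
wall-tail variance by a few percent.  The equilibration tests therefore
thin their samples and test at the resolution where the sampler, not the
discretization, is under scrutiny; production observables (cluster
composition, profiles, tension) are insensitive at this level.

## Specific binding as a virtual reaction

One-to-one domain–domain binding is a stochastic reaction that rigorously
maintains valency.  Each binding site carries a type (three PDZ sites on
PSD-95; one PBM on each TARPc; a PBM and a CaMKII-binding segment on each
GluN2Bc, which may engage simultaneously; twelve kinase sites on CaMKII,
active only in the active state and only for the configured valency
$V \in \{12, 6, 3\}$).  Per step, every unbound complementary site pair
within the reaction radius becomes a candidate; candidates are processed
in random order with probability $1 - e^{-\lambda_{on}\Delta t}$ each, and
a site claimed earlier in the sweep is unavailable later.  Each live bond
breaks with probability $1 - e^{-\lambda_{off}\Delta t}$.  Because a PDZ
site is a single slot, the mutual exclusion of TARP and GluN2B PBMs is
structural rather than rule-based.

The reaction radius is the contact distance plus a 0.5 nm capture margin;
bond restraints rest at contact.  The valency-reduction patterns are
symmetric: $V = 6$ alternates active/inactive around each hexagonal ring,
$V = 3$ activates every fourth kinase; this avoids artificial dipoles
where no placement is prescribed by the biology.

### Calibration to experimental dissociation constants

Interaction strengths are calibrated against in vitro dissociation
constants: TARPc with full-length PSD-95, 2.66 μM; GluN2Bc with
full-length PSD-95, 1.19 μM; GluN2Bc with the active CaMKII kinase
domain, 0.10 μM.  `calibrate_rates()` simulates the minimal pair system —
one ligand peptide and one full-length partner with all competing sites,
in a closed 80 nm periodic box — measures the apparent constant
$K_d = P_u^2 / (P_b N_A V)$ from the bound-fraction trace
(`apparent_kd()`, circular block bootstrap for the CI), and iterates
$\lambda_{on}$ multiplicatively until the target is met.  $\lambda_{off}$
is held fixed: equilibrium depends on the ratio, and fast exchange keeps
the calibration affordable.

Two empirical properties shaped the kinetic defaults.  First, with
binding-on-contact geometry the achievable association constant has a
ceiling at $p_{on} \to 1$; reaching sub-micromolar targets requires
off-rates slow enough that this ceiling sits well above the target, which
sets the per-rule defaults $\lambda_{off} = 5\times10^{-4}$,
$5\times10^{-4}$ and $5\times10^{-5}$ /ns.  These are still orders of
magnitude faster than the physical complexes, a deliberate choice that
accelerates equilibration without moving the equilibria.  Second, because
of diffusion-influenced rebinding the measured $K_d$ responds to
$\lambda_{on}$ with a local exponent between roughly $-1$ and $-2$, so the
calibration uses damped multiplicative updates.  The shipped
`default_rules()` on-rates are the output of this calibration; the
acceptance script re-runs the calibration from scratch.

## Scenarios

* `scenario_3d()` — the soluble system: 135 AMPAR(TARP)₄, 90
  NMDAR(GluN2Bc)₂, 240 PSD-95 and 60 CaMKII in a 155.362 nm periodic cube,
  8×10⁷ steps, three replicas differing only in the random stream.  PSD-95
  copy number satisfies the stoichiometry identity — total PDZ domains
  equal total PBM clients ($3P = 4A + 2N$) — and scaled-down systems
  preserve it by construction (counts scale with the cubed linear factor,
  with a minimal AMPAR increment to restore divisibility).
* `scenario_2d()` — the same composition with receptors and the PSD-95
  palmitoyl particle embedded in the membrane plane of a 500 nm box;
  anchorless CaMKII starts in the cytosol within 40 nm of the membrane (a
  choice; the source states only that it is beneath the membrane).  The
  weak-membrane ($k_{mem}/1000$) and thick-membrane ($D_{mem2} = 25$ nm)
  variants are `variant_spec()` switches.  On scale-down the box edge
  scales with the 3/2 power of the linear factor: counts shrink with the
  cube, so this keeps the membrane surface density — the intensive state
  of a 2D system — fixed, exactly as the cubic scaling keeps volume
  density fixed in 3D.
* `scenario_slab()` — tension measurement: molecules are confined to a
  central 100 nm slab of a 50×50×500 nm box for 4×10⁶ steps, then released
  into a 50×50×1500 nm box for 2×10⁷ production steps.  Phase compositions
  follow the cubic-box stoichiometry; the composition table the original
  protocol tabulates is not available, so the A phase holds AMPAR with
  proportional PSD-95, the N phase NMDAR with proportional PSD-95 plus the
  dense-phase share of CaMKII (default 37/60 of the total, the share the
  cubic-box run reports), and the combined slab is their union.  The
  tension difference construction
  $\gamma_{AN} = \gamma_{total} - \gamma_A - \gamma_N$ is a documented
  reconstruction.

The default desk scale for exploratory work is 1/3 linear (≈1/27 of the
molecule counts, ≥10⁶ steps); the full-scale protocols are constructed
exactly and run when the budget allows.  The test suite exercises 1/3-scale
systems with 10⁶-step trajectories and states its window sizes in the
test code; these sizes are the package's validation choices.

## Analyses

Cluster detection builds a molecule graph (edges: any specific bond, or
any inter-molecule particle pair within contact + 0.5 nm, minimum image)
and takes connected components; the suite checks it against a brute-force
union-find oracle.  The 0.5 nm contact margin is also the criterion for
counting non-specific interactions — the original figures plot such counts
without printing the criterion, so the margin is a documented
reconstruction, configurable everywhere it enters.  Radial distributions
support normalization by the cluster radius of gyration for pooling
differently sized clusters.  Where an observable asks "where is the
receptor", the package uses the receptor-core particle — the position the
fluorescence experiments localize — rather than the molecule's center of
mass, whose position carries an arm-count bias (four TARP arms versus two
GluN2Bc arms pull the two receptor types differently toward their binding
partners, which matters in small clusters).  Effective valency counts
distinct NMDAR molecules per CaMKII (both arms of one NMDAR count once).  Ring
orientation fits the least-squares plane of each kinase hexagon (SVD) and
folds the membrane-plane angle to [0°, 90°], since plane orientation is
sign-free; degenerate (collinear) rings are skipped.

Interfacial tension uses the Kirkwood–Buff anisotropy of the virial
pressure tensor in the slab geometry,
$\gamma = \tfrac12 L_z \{ P_{zz} - \tfrac12 (P_{xx} + P_{yy}) \}$,
with the ideal term $N k_B T/V$ on the diagonal and pair/bonded forces in
the virial; external membrane and confinement forces are excluded from the
virial (slab runs are soluble, so nothing is lost).  Uncertainty comes
from ten equal block averages of the production leg — a standard choice
for slowly decorrelating stress signals.  `classify_morphology()` applies
the tension inequalities: segregated droplets when
$\gamma_{AN} > \gamma_A + \gamma_N$, an A-core (or N-core) core–shell
droplet when one single-phase tension exceeds the sum of the other two,
and the Janus (partial-engulfing) morphology otherwise.

Phase assignment labels cluster members by the local majority of receptor
type among neighbor molecules within twice the contact margin, breaking
ties toward the molecule's own bound partners; singletons are dilute.
The bar-chart rule of the original analysis is unstated, so this is a
documented reconstruction with a conservation test (every molecule gets
exactly one label).

## What the synthetic systems do and do not show

All validation inputs are generated in code: analytic fixtures (ideal gas,
bonded dimer, two-slab, toy cluster) with closed-form observables, and
reduced-scale versions of the study systems.  Passing tests demonstrate
that the propagator samples Boltzmann distributions, that valency and
exclusion are never violated, that the calibrated rules reproduce the
experimental dissociation constants in pair titration, and that at 1/3
scale the qualitative morphology trends (activation-induced demixing and
its reversal by CaMKII volume or valency reduction) emerge.  They do not
demonstrate quantitative phase diagrams at experimental scale: desk-scale
clusters hold tens of molecules, so interface widths are comparable to
cluster radii and dilute-phase concentrations are strongly
finite-size-affected.  Full-scale runs use the exact printed protocol
parameters and are the appropriate setting for quantitative comparison.

## Numerical choices and limitations

* Timestep 0.25 ns, temperature 300 K throughout; positions are stored
  wrapped into the box and separations use branch-based minimum image.
* Placement rejects any inter-particle overlap (center distance below the
  radius sum) with bounded retries, then fails naming the species — at the
  study densities this is generous headroom.
* The trajectory format is line-oriented text with explicit truncation
  recovery; checkpoints are RDS archives of state plus the packed RNG
  stream.  Extended-XYZ export serves visualization tools.
* Hydrodynamic interactions, inertia, explicit lipids, autophosphorylation
  kinetics and Ca²⁺/calmodulin activation are out of scope; CaMKII is
  always dodecameric; activation is a static variant flag.
* The kinetic rates are calibration devices, not measurements: only the
  equilibrium constants are constrained by experiment, so dynamical
  quantities (cluster growth times, exchange rates) are meaningful in
  relative comparisons between variants, not as absolute times.
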