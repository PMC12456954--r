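# psdmeso

Particle-based reaction–diffusion simulation of multiphase liquid–liquid
phase separation in the postsynaptic density (PSD), for computational
biophysicists studying biomolecular condensates and synaptic organization.

The PSD's upper layer is a protein condensate built from four components:
the AMPA receptor with four TARP auxiliary subunits, the NMDA receptor
with two GluN2B C-terminal tails, the scaffold PSD-95, and the dodecameric
kinase CaMKII. `psdmeso` implements a mesoscale model of this mixture at
domain resolution — every globular domain is one spherical particle
(complexes of 5, 3, 6 and 13 particles) — and the analysis toolkit for its
multiphase morphologies:

- domain radii from the scaling law *R*ₙ = 0.224 *N*^0.392 nm, friction
  from Einstein–Stokes *D* = *k*₈*T*/6πη*R*ₕ with *R*ₕ = 1.45 *R*ₙ;
- overdamped Langevin dynamics (Δ*t* = 0.25 ns, 300 K) with soft
  excluded-volume repulsion and an implicit membrane potential for
  membrane-anchored (2D) systems;
- specific domain–domain binding as a stochastic **virtual reaction** that
  rigorously enforces valency: each PDZ domain holds at most one
  PDZ-binding motif (TARP and GluN2B motifs are mutually exclusive), each
  active kinase domain holds at most one GluN2B tail, and a GluN2B tail
  can engage PSD-95 and CaMKII simultaneously;
- on-rates calibrated against experimental dissociation constants (TARPc /
  PSD-95 2.66 μM, GluN2Bc / PSD-95 1.19 μM, GluN2Bc / active kinase
  0.10 μM) by pair-titration simulation,
  *K*_d = *P*ᵤ²/(*P*_b *N*_A *V*);
- cluster detection, compositions, radial/axial density profiles,
  specific/non-specific interaction counts, effective valency, CaMKII
  ring orientation;
- interfacial tension of slab systems via the Kirkwood–Buff relation
  γ = ½ *L*_z {*P*_zz − ½(*P*_xx + *P*_yy)} and morphology classification
  from the tension inequalities (segregated / core–shell / Janus).

CaMKII variants — inactive state, reduced radius (*r* = 2/3, 1/2), reduced
valency (*V* = 6, 3) — and the weak/thick-membrane variants are switches
on `variant_spec()`.

## Worked example

Build a 1/3-linear-scale version of the soluble four-component system
(counts scale with the cubed factor while preserving the PDZ = TARPc +
GluN2Bc stoichiometry), run Brownian dynamics, and look at the largest
cluster:

```r
library(psdmeso)

sc <- scenario_3d(variant_spec("active"), scale = 1/3, n_steps = 2e5)
st <- build_system(sc$composition, seed = 1)
print(st)
#> psd_state: 125 particles, 21 molecules, mode solution_3d
#>   box [nm]: 51.7873 x 51.7873 x 51.7873
#>
#>    AMPAR_TARP4         CaMKII NMDAR_GluN2Bc2          PSD95
#>              6              2              3             10
#>   specific bonds: 0  step: 0

run <- bd_run(st, 2e5, seed = 2, traj_stride = 2e4, sample_stride = 2e3)
round(largest_cluster_composition(run$trajectory, run$state, window = 3), 1)
#>    AMPAR_TARP4 NMDAR_GluN2Bc2          PSD95         CaMKII   cluster_size
#>            2.3            3.0            5.0            1.0           11.3
```

After 2×10⁵ steps (50 μs) the largest cluster already holds about eleven
of the twenty-one molecules — an early-stage condensate containing all
four components, with the two CaMKII still exchanging between cluster and
dilute phase.

Measuring an apparent dissociation constant with the calibrated
TARPc–PDZ rule (one TARPc peptide and one full-length PSD-95 in a closed
80 nm box; three independent titrations pooled):

```r
rules <- default_rules()
trace <- unlist(lapply(1:3, function(k)
  attr(pair_titration("TARPc", "PSD95", rules, n_steps = 2e7, seed = k),
       "trace")))
apparent_kd(trace, 80^3, discard = 0.05)
#> apparent Kd: 2.32 uM (CI 1.74 - 3.09), P_bound 0.440, n 570000
```

which recovers the 2.66 μM experimental constant the rule was calibrated
to, within the confidence interval of a titration this long. Tension analysis and morphology classification follow the same
pattern: `run_scenario(scenario_slab("A_phase"), ...)`, then
`interfacial_tension()` on the production pressure samples and
`classify_morphology(gamma_a, gamma_n, gamma_an)`.

A thin command-line wrapper is installed at `exec/psdmeso`
(`psdmeso build|run|calibrate-kd ...`).

## Scope

The model resolves domains, not residues: no atomistic structure,
hydrodynamic interactions, explicit lipids, autophosphorylation kinetics
or Ca²⁺/calmodulin activation dynamics. Kinetic rates are calibration
devices — only equilibrium constants are experimentally constrained. See
`vignettes/psdmeso-methods.Rmd` for the full model description, parameter
choices and limitations.
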