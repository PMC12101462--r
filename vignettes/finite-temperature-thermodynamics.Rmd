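---
title: "Finite-temperature thermodynamics of molecular crystals with xtaltherm"
author: "xtaltherm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-temperature thermodynamics of molecular crystals with xtaltherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtaltherm)
```

## The problem

The sublimation enthalpy of a molecular crystal,

$$\Delta H_\mathrm{sub}(T, p) = H_\mathrm{gas} - H_\mathrm{sol},$$

measures how strongly molecules are bound in the solid and controls
stability and solubility of crystalline compounds, including
pharmaceuticals.  About 80% of it is the zero-temperature electronic
binding (the negative of the lattice energy $E_\mathrm{latt}$); the
remainder comes from vibrations, nuclear quantum effects, and the
ideal-gas terms of the vapour.  All enthalpies and volumes of the solid
are per molecule throughout the package.

`xtaltherm` computes $\Delta H_\mathrm{sub}$ at three nested levels of
statistical mechanics over one pluggable potential interface
(`evaluate(potential, config)` returning energy, forces and a virial):

1. **QHA** - quasi-harmonic phonons.  Small-displacement force constants
   (0.01 Å central differences, acoustic sum rule enforced blockwise),
   dynamical-matrix diagonalisation on a uniform $q$-grid including
   $\Gamma$, and the quantum-harmonic internal energy per mode,
   $\hbar\omega/2 + \hbar\omega/(e^{\hbar\omega/k_BT}-1)$.  The gas
   molecule contributes its $3N-6$ (non-linear) or $3N-5$ (linear)
   vibrations plus $\tfrac{3}{2}RT$ translation, $\tfrac{3}{2}RT$ (or
   $RT$ if linear) rotation and $RT$ of ideal-gas $pV$, so the assembly
   with zero vibrational terms is $E + 4RT$ (non-linear) or
   $E + \tfrac{7}{2}RT$ (linear).  The solid $pV$ term at ambient
   pressure (< 0.05 kJ/mol) is neglected.
2. **MD** - classical anharmonic sampling.  Langevin dynamics (BAOAB
   splitting, per-atom white noise, friction 1 ps$^{-1}$ by default,
   1 fs timestep) in NVT for the gas (centre-of-mass momentum removed
   every step, its $\tfrac32 RT$ restored analytically) and NPT for the
   solid, giving
   $\langle H\rangle_\mathrm{sol} = \langle K + U\rangle + p\langle V\rangle$
   and
   $\Delta H = \langle K+U\rangle_\mathrm{gas} - \langle K+U\rangle_\mathrm{sol}
   + \tfrac52 RT - p\langle V\rangle_\mathrm{sol}$.
   Classical sampling contains no zero-point energy, and its
   configurational averages are independent of nuclear mass.
3. **PIMD** - path-integral sampling of the quantum Boltzmann
   distribution with $P$ replicas (32 by default).  Integration is in
   ring-polymer normal modes with exact propagation of the free-polymer
   springs and PILE thermostatting (centroid at the chosen friction,
   internal modes at their optimal coupling $\gamma_k = 2\omega_k$).
   The kinetic energy uses the centroid-virial estimator
   $K_\mathrm{cv} = \tfrac{3N}{2}k_BT + \tfrac{1}{2P}\sum_{j,i}
   (\mathbf r_i^{(j)}-\bar{\mathbf r}_i)\cdot(-\mathbf F_i^{(j)})$,
   which already contains the centre-of-mass $\tfrac32 RT$, so the gas
   assembly adds only $RT$:
   $\Delta H = \langle K_\mathrm{cv}+U\rangle_\mathrm{gas}
   - \langle K_\mathrm{cv}+U\rangle_\mathrm{sol} + RT
   - p\langle V\rangle_\mathrm{sol}$.

A zero-temperature reference correction (`reference_correction`) moves
the electronic part of a model-level result to a higher-level reference
lattice energy, with the reference uncertainty added in quadrature to
the sampling error.

Statistical errors of all sampled means come from Flyvbjerg-Petersen
reblocking: successive pairwise block averaging with the plateau chosen
as the smallest level whose SEM changes over the next two doublings
stay below $\max(5\%, \sqrt{8/n_\mathrm{blocks}})$.  The second term is
new relative to a bare 5% rule: with few blocks the blocked SEM itself
fluctuates by $\sim\sqrt{1/2n_\mathrm{blocks}}$, and a noise-blind rule
tends to latch onto a late, downward-fluctuating level and
underestimate the error.

## Ensembles and numerical choices

* **NVT**: BAOAB with exact Ornstein-Uhlenbeck noise; fixed (inputs,
  seed) give bit-identical trajectories.  A one-bead path-integral run
  *is* the classical integrator - `run_md` simply calls `run_pimd` with
  `P = 1` - so the classical limit is exact by construction, not by
  analogy.
* **NPT**: an isotropic stochastic cell via Metropolis volume moves in
  $\ln V$ every 20 steps (atomic scaling, acceptance
  $\exp[-\beta_P\,\Delta\Phi - \beta p\,\Delta V + (NP+1)\Delta\ln V]$,
  which is exact for the discretised partition function at any bead
  count).  A Langevin piston was considered and rejected: the Monte
  Carlo cell needs no piston mass or friction parameters and makes the
  average internal pressure match the target by construction, which is
  what the estimator tests check.
* **Timesteps**: 1 fs default; runs on the double-well hydrogen bond
  use 0.5 fs because the proton-transfer curvature approaches
  300 rad/ps.  Equilibration discards the first 20% of samples
  (overridable).
* **Relaxation** alternates BFGS on internal coordinates with a 1D
  enthalpy minimisation over the isotropic cell scale
  (tolerances $10^{-4}$ kJ/mol/Å on forces, 1 bar on pressure);
  anisotropic cells are out of scope for the packaged toys.
* **EOS**: third-order Birch-Murnaghan (the community default for
  crystalline $E(V)$), fitted by Levenberg-Marquardt from a quadratic
  initialisation; quasi-harmonic properties are evaluated at the
  $p = 0$ volume.  Model-vs-reference deviation profiles are computed
  on minimum-aligned relative energies, because constant offsets are
  the lattice-energy check's business, not the EOS shape's.
* **Imaginary phonons** are a hard error in energies and only reported
  in diagnostics ($\omega_\mathrm{tol} = 10^{-4}$ rad/ps at $\Gamma$);
  the thermodynamic formulas presume a dynamically stable crystal.
  Gas-phase null-mode detection uses a looser 5 rad/ps because finite
  displacements contaminate rotational curvatures at $O(u^2)$.

## The training-set sampling loop

The data-efficiency loop mirrors how machine-learned potentials are
fine-tuned for crystals: relax the reference EOS at 0, ±1, ±2, ±4 kbar
(~7 volumes); run short (~5 ps) low-temperature (~100 K) MD with the
*model* at each volume (the reference is never used for dynamics -
that is the cost saving); randomly select ~10 frames per volume; label
them with the reference; fit; test against three gates (lattice energy
within 4 kJ/mol, EOS deviation within 1 kJ/mol, QHA vibrational energy
within 2 kJ/mol); and augment ~5 frames per worst-deviation volume
until the gates pass or a ~200-structure budget is exhausted.

The packaged trainable potential is a linear pair expansion in
cutoff-shifted $r^{-12}$ and $r^{-6}$ terms fitted by ridge-regularised
least squares on energies, forces and virials with weights 1 : 0.1 :
0.1 (the regulariser is scaled by the design matrix so it never
competes with data).  Because a truncated, shifted Lennard-Jones lies
exactly in its span, the loop has a realizable case with a known
answer, which the tests exploit; fitting it to the diatomic molecular
crystal provides the honest, unrealizable learning-curve case.

## The toy systems and what they do (and do not) show

* **Harmonic spring crystal** (`toy_harmonic_crystal`): one water-like
  3-atom molecule per cubic cell, pair springs with a transverse
  component.  Purely central (bond-projection) springs have
  rotation-like modes of near-zero frequency that never equilibrate;
  the transverse term removes them.  Constants are chosen so
  $\beta\hbar\omega_\mathrm{max} \approx 3.9$ at 300 K, the regime
  where 32-64 beads converge path-integral averages and where quantum
  effects (ZPE of ~25 kJ/mol per molecule) are large enough to be
  resolved against sampling noise.  Being exactly quadratic, it has
  closed-form finite-bead expectations
  (`harmonic_finite_p_energy`), which is what makes the cross-method
  closure tests sharp.
* **LJ fcc crystal** (`toy_lj_crystal`): $\varepsilon = 8$ kJ/mol,
  $\sigma = 3$ Å, 3$\sigma$ energy-shifted truncation without tail
  correction (continuity matters for MD stability; tails do not matter
  for the toys).  $\varepsilon$ is set so the ±4 kbar scan stays inside
  the tensile stability range and the cohesion (~60 kJ/mol per site) is
  molecular-crystal-like.
* **Diatomic molecular crystal** (`toy_molecular_crystal`): harmonic
  bonds plus intermolecular LJ; the minimal system with distinct intra-
  and intermolecular physics, used for topology-aware tests and the
  unrealizable learning curve.
* **Double-well hydrogen bond** (`toy_hbond`): collinear O-H-O with a
  quartic double well in the proton-transfer coordinate $s$, an O-O
  restraint, and a coupling $\lambda s^2 (R - R_0)$ that shortens the
  O-O distance when the proton localises.  With the defaults (barrier
  6 kJ/mol, wells 0.6 Å apart, $k_\mathrm{OO} = 100$ kJ/mol/Å$^2$,
  $\lambda = 270$ kJ/mol/Å$^3$) the proton zero-point energy sits just
  above the barrier for H and just below for D, so H delocalises
  (smaller $\langle s^2\rangle$) and its O-O distance is longer - the
  conventional Ubbelohde effect, with
  $\Delta(\mathrm{O\!-\!O}) \approx 0.035$ Å at 300 K.  The stiffness
  and coupling were set, using the exact two-dof oracle below, so the
  shift is several times larger than the thermal O-O noise divided by
  the number of independent samples a ~50 ps, 32-bead run provides; a
  much softer restraint would bury the same physics under
  $\sqrt{k_BT/k_\mathrm{OO}}$ fluctuations at any desk-scale run
  length.  This model is exactly solvable by grid diagonalisation of
  the two internal Jacobi coordinates (`hbond_oracle_thermal`, 5-point
  finite differences, Boltzmann average over eigenstates), which
  provides reference values that involve no dynamics at all.

What passing these tests shows is that the estimators, integrators and
assemblies are correct on systems with known answers.  What they do not
show: accuracy of any real interatomic potential, anharmonic physics
beyond the double well (the harmonic crystal has none by construction),
long-range electrostatics, or molecular flexibility - real molecular
crystals add all of these on top of the statistical mechanics tested
here.

## Problem sizes used by the packaged checks

The shipped tests and the acceptance analysis use: the 24-atom
harmonic crystal (50 ps at $P = 64$ for the cross-method closure; 25 ps
pairs of isotope runs at $P = 32$), 32 LJ atoms for 15 ps of NPT,
100 ps double-well runs at $P = 32$, $2^{16}$-point AR(1) series for
reblocking, and a sampling loop capped at 200 structures.  These sizes
were chosen so each comparison's statistical error is a few times
smaller than the effect it measures.

## Known limitations

* The harmonic-crystal virial references absolute positions, so its
  NPT behaviour is physically meaningful only near the reference
  structure; the enthalpy assemblies therefore accept fixed-cell solid
  records and flag the result (`constant_volume_solid`).
* No Ewald summation: all packaged potentials are short-ranged.
* The NPT cell is isotropic; shear and anisotropic strain are frozen.
* Gas-phase rotation of the harmonic toy molecule is suppressed by its
  transverse springs; that is deliberate (it keeps the gas reference
  exactly harmonic) but means rotational anharmonicity is untested.
* Reported SEMs are reblocked estimates; for series much shorter than
  ~50 correlation times they can still underestimate, which is why the
  packaged checks use 3-SEM tolerances on top of generous run lengths.

## A worked example

```{r example, eval = FALSE}
sys <- toy_harmonic_crystal()

# QHA vibrational energy of the solid at 300 K
phi <- compute_force_constants(sys$potential, sys$crystal)
mp <- monkhorst_pack(c(2, 2, 2))
spec <- phonon_spectrum(phi, sys$crystal, mp$qpoints, mp$weights,
                        n_molecules = 1)
qha_vib_energy_solid(spec, 300)

# quantum sampling of the same quantity
est <- run_pimd(sys$potential, sys$crystal, P = 32, "NVT", T = 300,
                n_steps = 20000, seed = 1)
record_stats(est, "K_cv")$mean + record_stats(est, "U")$mean
```
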