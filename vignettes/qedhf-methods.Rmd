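---
title: "Cavity QED Hartree-Fock: model, gradients, and field-aware optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cavity QED Hartree-Fock: model, gradients, and field-aware optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`qedhf` solves the closed-shell Hartree-Fock problem for a molecule coupled
to one or more quantized cavity modes, in the coherent-state (displaced
photon vacuum) frame.  In that frame the bilinear light-matter coupling has
zero expectation value against the photon vacuum, and the only survivor
beyond ordinary Hartree-Fock is the **dipole self-energy**, a non-negative
variance of the molecular dipole along each polarization:

$$E_\text{QED-HF} = E_\text{HF} +
  \tfrac12 \sum_\alpha \left\langle\left[\lambda_\alpha\cdot
  (d - \langle d\rangle)\right]^2\right\rangle ,$$

where $\lambda_\alpha$ is the coupling vector of mode $\alpha$ (magnitude
$\sqrt{4\pi/V}$ for a cavity of volume $V$ in atomic units) and $d$ is the
*composite* dipole operator: the electronic part plus the nuclear dipole
shared evenly over the $N_e$ electrons,
$d_{\mu\nu} = -\langle\mu|r|\nu\rangle + (d_\text{nuc}/N_e) S_{\mu\nu}$.
With this convention $2\,\mathrm{Tr}(Dd)$ is the physical molecular dipole,
and the fluctuation form makes the energy origin-invariant for neutral
*and* charged systems (the cross terms vanish through $DSD = D$).

Expanding the square folds the cavity into modified one- and two-electron
integrals.  Writing $A_\alpha = \lambda_\alpha\cdot d$ in the AO basis:

* one-electron: $h = h_e + \sum_\alpha\left(\tfrac12 A_\alpha S^{-1}
  A_\alpha - \langle A_\alpha\rangle A_\alpha +
  \tfrac{\langle A_\alpha\rangle^2}{2N_e} S\right)$,
* two-electron contraction: $G(D) = G_e(D) + \sum_\alpha\left(
  2\,\mathrm{Tr}(DA_\alpha)\,A_\alpha - A_\alpha D A_\alpha\right)$,

and the energy is the familiar $E = \mathrm{Tr}(2Dh + DG(D)) + h_\text{nuc}$.
The photon frequency $\omega_\alpha$ never enters this energy; it is stored
for reporting and for the equivalent-field identity
$E = \sqrt{\omega/2}\,|\lambda|$.

The coherent-state reference $\langle A_\alpha\rangle = 2\,\mathrm{Tr}(DA_\alpha)$
is **refreshed from the current density at every SCF iteration**, with no
damping.  This is the convergence-critical choice: the energy is exactly
independent of the reference on the $\mathrm{Tr}(DS)=N_e/2$ manifold (the
terms cancel algebraically), so the refresh cannot destabilise the fixed
point, and DIIS on the orbital-gradient residual $FDS-SDF$ converges at
essentially the plain-HF rate.  At $\lambda=0$ every added term is exactly
zero and the solver *is* restricted Hartree-Fock, bit for bit.

## Static fields

A uniform electric field adds $-E_\text{ext}\cdot d$ to $h$; because $d$ is
the composite operator, the nuclear term $-E\cdot d_\text{nuc}$ rides along
automatically and $-\partial E/\partial E_z$ equals the full SCF dipole (we
verify this to seven digits in the tests).  The static field does not
couple to the cavity mode at this level — their interaction term vanishes
by the linearity of Maxwell's equations — so dual-field calculations are
simply both modifications at once.

A static magnetic field at a fixed gauge origin $O$ adds the orbital-Zeeman
term $-\tfrac12 B\cdot L_O$ (imaginary-Hermitian) and the symmetric-gauge
diamagnetic term $\tfrac18\left(B^2 r_O^2 - (B\cdot r_O)^2\right)$.  Any
magnetic run switches the whole SCF to complex arithmetic: a real-
constrained determinant cannot respond to the Zeeman operator at first
order, and the tests check that the complex solution lies strictly below
the real-constrained one.  **Without London (field-dependent) orbitals
these energies are gauge-origin dependent**; the package exposes the origin
(default: centre of nuclear charge), refuses silently mismatched origins,
and provides only finite-difference gradients for magnetic fields, because
an analytical fixed-gauge gradient would inherit exactly the gauge
artifacts the field-dependent-orbital literature warns about.

## The analytical nuclear gradient

The gradient combines the standard restricted-HF pieces — core-Hamiltonian
derivative, two-electron derivative contraction
$\mathrm{Tr}(D\,G_e^{(1)}(D))$, the energy-weighted overlap term
$-2\,\mathrm{Tr}(DFDS^{(1)})$ with $F$ the *full* cavity Fock matrix, and
the nuclear repulsion — with two cavity-specific groups:

$$2\sum_\alpha \mathrm{Tr}\!\left[D A_\alpha (S^{-1}-D)\, A_\alpha^{(1)}\right]
 \;-\; \sum_\alpha \mathrm{Tr}\!\left[\left(S^{-1}A_\alpha D A_\alpha S^{-1}
 - \tfrac{\langle A_\alpha\rangle^2}{N_e} D\right) S^{(1)}\right],$$

plus $-E_\text{ext}\cdot d^{(1)}$ contracted with the density for static
fields.  The derivatives of $\langle A_\alpha\rangle$ cancel against the
$N_e = 2\,\mathrm{Tr}(DS)$ identity and never need to be formed.  The
composite dipole derivative $d^{(1)}$ carries three contributions that are
easy to miss: the electronic moment-integral derivatives, the nuclear-share
overlap derivative $(d_\text{nuc}/N_e)S^{(1)}$, and the nuclear-dipole
derivative $(Z_A/N_e)S$ along the displaced coordinate.  Correctness is
enforced by a central-finite-difference oracle rather than assumed: the
suite requires agreement to $10^{-6}$ hartree/bohr (step $10^{-3}$ bohr)
for no field, one mode, two non-parallel modes, a static field, and the
dual-field combination, and the remaining deviation is pure
finite-difference truncation ($\sim10^{-7}$).

## Integrals

No existing R package evaluates Gaussian-orbital molecular integrals, so
the engine is implemented in C++ (McMurchie-Davidson Hermite expansion):
overlap, kinetic, nuclear attraction, multipoles, angular momentum,
two-electron integrals, and first derivatives of all of them.  Design
points:

* **Uncontracted spherical shells.**  Every basis is uncontracted before
  use — each distinct primitive becomes its own shell (duplicate
  `(centre, l, exponent)` primitives are merged) — because contraction
  coefficients optimized without fields are a bias under fields.  Shells
  are real solid harmonics through *d*; higher angular momenta are an
  explicit not-implemented error rather than a silent fallback.
* **Screening.**  Two-electron quartets are screened with the
  Cauchy-Schwarz bound $\sqrt{(\mu\nu|\mu\nu)(\rho\sigma|\rho\sigma)}$
  (threshold $10^{-12}$ by default; 0 disables it and is bit-identical to
  unscreened).  The gradient pass adds density-weighted screening and uses
  the permutational symmetry of the derivative integrals.
* **Derivative verification.**  All derivative integrals are tested
  against central differences at step $10^{-4}$ bohr to $10^{-7}$ — the
  step that balances truncation against round-off in double precision —
  plus translational sum rules and the inversion antisymmetry of
  homonuclear diatomics.
* Linear dependence is caught by the smallest overlap eigenvalue (default
  floor $10^{-10}$) and reported with the eigenvalue.

Unit policy: everything internal is in Hartree atomic units; Angstrom
appears only at XYZ I/O boundaries with the conversion factor stored once
in `qed_constants` (CODATA 2018 fundamental constants; the derived field
conversions $E_h/ea_0$ and $\hbar/ea_0^2$ are computed, not transcribed).

## Geometry optimization in fields

External fields break rotational invariance, so the optimizer must treat
overall orientation as physical.  The scheme is BFGS-updated quasi-Newton
steps with a trust radius in Cartesian coordinates: translations are always
projected out; **rotations are projected out only when every field is
zero**.  Steps that raise the energy are rejected and the trust radius
shrinks, so the energy is monotonically non-increasing along accepted
steps.  Defaults (common quantum-chemistry practice): max gradient
$4.5\times10^{-4}$, RMS $3\times10^{-4}$ hartree/bohr, energy change
$10^{-7}$ hartree, trust radius 0.3 bohr.  A full
translational-rotational-internal coordinate system with a partitioned
rational-function step would converge in fewer iterations on floppy
clusters; retaining rotations in Cartesians is the minimal scheme the
physics requires, and the cross-check below guards its correctness.

Constraints come in two forms: frozen Cartesian coordinates (removed from
the variable space — used for the planarity-constrained inversion saddle)
and dihedral constraints (gradient/step projection plus Newton restoration
to within 0.01 degrees).  Scans warm-start each point from the previous
optimized geometry, which also resolves ties between symmetry-equivalent
minima deterministically.

Two workflows mirror the study design.  `rigid_rotation_scan()` rotates
the molecule rigidly about an axis through its centre of mass with fields
fixed in the laboratory frame (five-degree default increments, endpoint
periodicity checked to $10^{-9}$); orientation minima found this way are
cross-validated against full optimizations to within one grid cell.
`coupling_sweep()` and `constrained_scan()` track optimized internal
coordinates along a field-strength or dihedral grid.

### Orientation protocol for the water shifts

The field-induced changes in water's internals depend on which rotational
stationary point the molecule sits at.  With the cavity polarization along
$z$ and $\lambda = 0.1$, the rotational surface has its global minimum
with the **molecular plane perpendicular to the field**, about 1.7 mH
below the dipole-aligned orientation; the dipole-aligned and
H-H-axis-aligned orientations are symmetry-stationary saddles (their
rotational gradients vanish identically, so an optimizer started there
stays there).  The packaged protocol therefore pre-orients at the
rigid-scan global minimum before relaxing everything.  At that orientation
the bond contracts by $1.5\times10^{-3}$ Å between $\lambda=0$ and $0.1$;
the angle response is nearly flat (thousandths of a degree, sign unstable
between couplings) in the uncontracted aug-cc-pVDZ basis used throughout.
In a $0.01$ a.u. static field along the dipole the bond stretches by
$1.4\times10^{-3}$ Å and the angle closes by $1.25$ degrees.  These are
the numbers `scripts/acceptance.R` recomputes; nothing beyond that run is
claimed here.

### Water dimer

The tracked intermolecular coordinate is the four-atom dihedral
(donor free H, donor O, acceptor O, first acceptor H) — the "donor-acceptor
frame" choice, made configurable because the literature phrase "dihedral
angle between the two water molecules" admits several four-atom
realisations.  At the plain-HF optimum of the uncontracted aug-cc-pVDZ
dimer this dihedral is $-120^\circ$ (the mirror image at $+120^\circ$ is
equivalent; the fixture's atom ordering selects the negative sign
deterministically).  With a cavity mode of $\lambda_z = 0.085$ the relaxed
$0^\circ$ structure drops about 1.4 mH below the relaxed $-120^\circ$
structure: the global minimum switches basins, reproduced in the
acceptance suite as a two-basin energy comparison.

### Inversion-barrier surrogate

The bowl-inversion workflow is exercised on ammonia: the pyramidal minimum
is optimized freely and the planar transition configuration is optimized
with all out-of-plane coordinates frozen at zero, the barrier being the
difference.  The tests assert the qualitative law — the barrier decreases
monotonically with coupling — at minimal-basis scale.  This is a surrogate
for the same workflow on larger bowl-shaped systems, which runs through
identical code but not in the test suite.

## What the fixtures do and do not emulate

The built-in geometries (`water`, `water_dimer`, `ammonia`, `h2`) are
deterministic, literature-typical *starting* structures — a C2v water at
0.9572 Å/104.52°, a Cs hydrogen-bonded dimer at O···O = 2.98 Å, a C3v
ammonia pyramid — not optimized results and not coordinates taken from any
publication.  Tests that pass on them demonstrate the machinery (SCF
convergence, gradient exactness, optimizer behaviour, basin energetics) at
double-zeta scale; they do not demonstrate basis-set-converged chemistry,
correlation effects (the theory is mean-field), finite-temperature
behaviour, or multi-mode Fabry-Pérot realism (modes are independent
single-mode couplings; no cross-mode terms exist at this level).

## Problem sizes and runtimes

The test and acceptance runs use uncontracted STO-3G (21 functions for
water) for property checks and uncontracted aug-cc-pVDZ (57 functions for
water, 114 for the dimer) for the headline numbers.  A dimer
energy-plus-gradient evaluation takes a few seconds on one core; the full
dimer optimization from the fixture takes a few minutes.  These sizes were
chosen so the entire evidence chain re-runs from scratch in minutes while
still using the double-zeta basis the headline protocol specifies.

## Known limitations

* Restricted (closed-shell) determinants only; odd-electron systems are
  rejected at construction.
* Basis sets through *d* functions; the bundled sets are STO-3G and
  aug-cc-pVDZ for H, N, O.  The uncontracted-triple-zeta variant of the
  water sweeps is therefore out of reach here; where the angle response is
  near-zero at double zeta this matters (see the orientation protocol
  section).
* Magnetic energies are fixed-gauge (no London orbitals): gauge-dependent
  by construction, with finite-difference gradients only.  Trends, not
  absolute magnetic numbers, are meaningful.
* The optimizer is a general-purpose quasi-Newton scheme; very floppy
  clusters may need more steps than an internal-coordinate optimizer
  would.
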