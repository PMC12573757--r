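# qedhf

Electronic-structure calculations for molecules in optical cavities and
static electromagnetic fields: closed-shell **cavity QED Hartree-Fock
(QED-HF)** energies, **analytical nuclear gradients**, and the
**field-aware geometry machinery** built on them — optimization with
rotational degrees of freedom retained, rigid-rotation potential-energy
scans, constrained-dihedral scans, and coupling-strength sweeps.

It is written for computational chemists who want to ask how strong
light-matter coupling or strong static fields reshape molecular
equilibrium structure — bond lengths, angles, orientation relative to the
field, hydrogen-bond arrangements — with a self-contained, fully testable
R implementation (the Gaussian-integral engine, McMurchie-Davidson with
analytic derivatives, is compiled C++ under the hood).

## The model

For cavity modes with coupling vectors
$\lambda_\alpha$ (magnitude $\sqrt{4\pi/V}$ for cavity volume $V$ in a.u.)
the reference is the Hartree-Fock determinant tensored with the photon
vacuum in the coherent-state frame, where the only new energy term is the
dipole self-energy — a non-negative variance of the molecular dipole along
each polarization:

$$E_\mathrm{QED\text{-}HF} \;=\; E_\mathrm{HF} \;+\;
\tfrac12\sum_\alpha \big\langle\,[\lambda_\alpha\cdot(d-\langle d\rangle)]^2\,\big\rangle .$$

The square folds into modified one- and two-electron integrals, so the SCF
and its analytical gradient reuse the Hartree-Fock structure with extra
dipole-matrix terms; static electric fields add $-E_\mathrm{ext}\cdot d$,
and static magnetic fields add orbital-Zeeman plus diamagnetic terms at a
fixed gauge origin (complex SCF, finite-difference gradients).  The
frequency $\omega_\alpha$ does not enter the energy; couplings and fields
are in atomic units throughout (1 a.u. of electric field
$= E_h/ea_0 \approx 5.142\times10^{11}$ V/m, 1 a.u. of magnetic field
$\approx 2.35\times10^{5}$ T).

See `vignettes/qedhf-methods.Rmd` for the full account: modified
integrals, the gradient expression and its finite-difference oracle,
orientation protocol, optimizer design, and limitations.

## Worked example

Water in a single cavity mode polarized along z with coupling
$\lambda_z = 0.1$ a.u., in uncontracted STO-3G:

```r
library(qedhf)
bas <- uncontract_basis(read_basis("sto-3g"))
wat <- make_fixture("water")
st  <- scf_solve(wat, bas,
                 field_config(modes = list(cavity_mode(c(0, 0, 0.1),
                                                       omega = 0.5))))
print(st)
#> <qed_scf> converged in 12 iterations
#>   E_total                -75.1527160425 hartree
#>   electronic             -84.3568003982
#>   nuclear repulsion        9.1949648545
#>   dipole self-energy       0.0091195013 (mode 1)
#>   dipole moment      (0.000000, 0.000000, 0.883212) a.u.

qed_hf_gradient(st)
#> <qed_gradient> (hartree/bohr)
#>   O     -0.00000000     0.00000000    -0.00141920
#>   H     -0.00000000    -0.01273362     0.00070960
#>   H      0.00000000     0.01273362     0.00070960
#>   max |g| = 1.273e-02  rms = 6.031e-03
```

The energy decomposition separates the dipole self-energy (here +9.1 mH:
the cavity penalises dipole fluctuations along its polarization, raising
the energy above plain HF), and the analytical gradient is ready for
`optimize_geometry()`, which keeps rotations free because orientation in a
field is physical.  Higher-level drivers (`rigid_rotation_scan`,
`constrained_scan`, `coupling_sweep`, `inversion_barrier_sweep`) and a
YAML-configured command line (`exec/qedhf --config run.yaml`) wrap the
same calls.

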