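# Example run configuration for the qedhf command line:
#   qedhf --config example-run.yaml
# Fields are in atomic units unless a unit tag is given
# (e.g.  E_ext: {value: [0, 0, 5.142], unit: "V/nm"}).
task: energy
geometry: water          # fixture name or path to an .xyz file (Angstrom)
basis: aug-cc-pvdz       # bundled set or path; always used uncontracted
fields:
  modes:
    - lambda: [0.0, 0.0, 0.1]
      omega: 0.5
  E_ext: [0.0, 0.0, 0.0]
  B_ext: [0.0, 0.0, 0.0]
output_dir: qedhf-run
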