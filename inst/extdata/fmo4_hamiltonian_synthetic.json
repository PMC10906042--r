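{
  "description": "SYNTHETIC 4-site exciton Hamiltonian for the 1->2->3->4 transfer pathway of an FMO-type pigment-protein complex. These are literature-scale stand-in values (site energies relative to site 3; nearest-neighbour couplings dominant), NOT the tabulated Hamiltonian of any specific structure determination. Replace with a user-verified matrix for production work.",
  "synthetic": true,
  "units": "cm-1",
  "matrix": [
    [310.0, -98.0,   6.0,  -6.0],
    [-98.0, 230.0,  30.0,   7.0],
    [  6.0,  30.0,   0.0, -58.0],
    [ -6.0,   7.0, -58.0, 180.0]
  ]
}
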