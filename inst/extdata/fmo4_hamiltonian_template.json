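{
  "description": "Template for a user-supplied 4-site exciton Hamiltonian (cm^-1, Hermitian). Fill in the tabulated values from your preferred structure-based parameterization.",
  "synthetic": false,
  "units": "cm-1",
  "matrix": [
    [0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0]
  ]
}
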