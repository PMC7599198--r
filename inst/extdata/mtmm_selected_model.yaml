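# selected model of the multitrait-multimethod worked example:
# S = 3 orthogonal common factors, specific factors correlated within
# traits (banded), scale-invariant via free D with unit-diagonal Psi
J: 4
K: 3
variable_labels: [E, A, I, M]
occasion_labels: [P, T, S]
n_factors: 3
phi_structure: orthogonal
psi_structure: banded_within_variable
invariance: psi_unit_diag
identification: first_row_unit
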