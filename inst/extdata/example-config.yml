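# Example analysis configuration (see ?analysis_config for all keys).
# Primary analysis: hospital outcomes, dynamic lag-lead window, phase basis.
n_patients: 300
n_icus: 20
seed: 1
outcome_set: hospital
window_mode: dynamic
basis_mode: phase
subgroup: all
smoothing: reml
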