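n_case_carriers	n_cases	n_control_carriers	n_controls
14	925	426	46673
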