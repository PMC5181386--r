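# Example generator configuration (synthetic cohorts; all other parameters
# take their calibrated defaults)
n_young: 886
n_old: 483
missing_rate: 0.03
seed: 2016
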