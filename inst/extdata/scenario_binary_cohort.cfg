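# Binary cohort scenario: 7 continuous predictors, ~34% event rate.
n_rows = 200
n_continuous = 7
support = 2,6,7
beta = 1.2,0.8,0.6
event_target = 0.34
mode = binary
seed = 2002
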