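# Sparse linear scenario: 6 correlated continuous predictors, 2 true effects.
n_rows = 300
n_continuous = 6
correlation = 0.1
support = 2,5
beta = 3,3
noise_sd = 1
mode = linear
seed = 2001
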