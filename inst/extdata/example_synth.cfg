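# Example configuration: generate a small synthetic BC1 population under the
# zyp1 Poisson/uniform model, then call crossovers from it with the 'call'
# stage and analyse them with 'stats'.
subcommand = synth
seed = 1
genotype = zyp1_hei10oe_hybrid
sex = female
n_samples = 12
marker_density = 0.1
mean_depth = 2
error_rate = 0
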