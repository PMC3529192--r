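# Example synthetic-world configuration for `closecall simulate`.
# Flat key = value pairs; control distributions as <control>.<field>;
# per-context values as comma-separated context:value lists.

n_groups = 2
individuals_per_group = 4
calls_per_context = 5
seed = 7
p_harmonic_absent_digging = 0.5

# make the context gradation a little steeper than the default world
harmonic_duration.mean = digging:0.03,searching:0.06,moving:0.09
harmonic_f0.individual_sd = 25
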