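# mirSpan synthetic study manifest
rng_seed=7
n_blocks=6
block_size=20
p_within=0.3
p_between=0.015
n_seeds=5
n_absent_seeds=1
seed_block_bias=1
n_families=12
targets_per_family=24
broad_family_spread=6
narrow_spread=1
decoy_target_rate=1
chip_n_per_group=5
chip_noise_sd=0.2
chip_input_fraction=0.1
chip_percent_a=10
chip_percent_b=2
chip_percent_igg=0.2
qpcr_n_per_group=20
qpcr_fold=2
qpcr_noise_sd=0.2
qpcr_dct_base=5
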