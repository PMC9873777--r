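name: Meko
t_base_veg: 6.0
t_opt_veg: 27.0
t_max_veg: 42.0
t_base_gf: 5.7
t_opt_gf: 23.5
tt_flag_to_anthesis: 207.0
tt_anthesis_to_maturity: 819.0
tt_sow_to_emerg: 40.0
tt_anthesis_to_startgf: 100.0
lar: 63.0
lir: 31.5
tln: 15.0
tln_phen: 15.0
x0_slope: 0.83
x0_intercept: 0.0
y0_slope: 36.9
y0_intercept: -95.2
partition_k: 0.0073
grain_number_factor: 0.00083
rue: 1.25
extinction_k: 0.4
max_kernel_wt: 0.030
stem_transloc_frac: 0.2
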