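quantity,outer_pct,inner_pct
sum_fa_of_dm,52,25
safa,30,35
mufa,54,38
pufa,16,28
omega3,10,16
omega6,3.3,5
omega9,4.1,13
epa_plus_dha,7.8,13
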