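tract_id,n_residents,frac_over_65,frac_female,frac_disabled,sei_rank,above_avg_salary
11,5926,0.12,0.505,0.09,10,TRUE
12+13,7023,0.08,0.50,0.08,"7,8",FALSE
14,1205,0.15,0.48,0.11,7,FALSE
15,1198,0.15,0.46,0.27,7,FALSE
21,5122,0.11,0.50,0.135,9,FALSE
22+23,4638,0.125,0.54,0.11,"8,9",FALSE
24,2152,0.015,0.52,0.035,9,TRUE
25,3038,0.08,0.50,0.17,9,FALSE
31+32,5467,0.10,0.50,0.175,6,FALSE
33,1752,0.14,0.50,0.23,6,FALSE
34,1974,0.05,0.48,0.14,6,FALSE
36,2584,0.165,0.49,0.275,6,FALSE
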