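diameter_mm,volume_cm3,formula_threshold_percent,abs_threshold_to_suvmax_percent,target_volume_cm3,relative_deviation_percent
37,26.51,31.94,39,26.82,1.18
22,5.57,30.92,36,6.04,8.39
17,2.57,29.92,36,2.65,3.07
10,0.52,40.46,53,0.57,8.92
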