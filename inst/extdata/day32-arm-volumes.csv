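arm,volume_cm3,reported_tgi_percent
control,8.496,NA
gqd_low,8.704,-2.450
gqd_medium,7.976,6.125
gqd_high,6.216,26.836
pd1,4.847,48.216
gqd_low_pd1,2.436,70.526
gqd_medium_pd1,3.362,60.424
gqd_high_pd1,3.305,60.097
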