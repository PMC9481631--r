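region,RPE_LOSS,PDR,HT,RORA,printed_sum
foveal,13.4,6.4,8.5,14.8,43.1
inner_superior,2.3,1.6,2.5,3.1,9.5
inner_nasal,1.7,1.7,2.0,2.6,8.9
inner_inferior,1.7,1.6,1.9,2.1,7.3
inner_temporal,1.5,1.8,1.7,2.0,7.0
outer_superior,0.8,1.8,2.1,1.4,6.1
outer_nasal,0.9,2.1,2.3,1.7,7.0
outer_inferior,0.7,2.3,2.4,1.6,7.0
outer_temporal,0.6,1.4,1.8,1.2,5.0
column_sum,23.7,20.7,25.1,30.5,NA
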