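region,RPE_LOSS,PDR,HT,RORA,printed_sum
foveal,3.0,12.2,5.6,4.8,25.5
inner_superior,2.8,4.0,2.9,3.0,12.7
inner_nasal,1.7,3.1,2.2,2.2,9.2
inner_inferior,1.9,4.1,2.7,2.9,11.6
inner_temporal,1.6,3.3,2.3,2.4,9.5
outer_superior,0.9,3.7,2.7,1.7,8.9
outer_nasal,0.9,3.0,2.5,1.7,8.1
outer_inferior,0.5,3.0,2.5,1.3,7.3
outer_temporal,0.7,2.5,2.5,1.5,7.1
column_sum,13.8,38.9,26.0,21.4,NA
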