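group,winter_pct,spring_pct,spring_sd,summer_pct,summer_sd,fall_pct,average_pct,average_sd
EUB,73.7,76.8,2.2,52.1,2.2,73.3,74.1,10.2
CFB,15.9,12.9,1.0,8.4,1.1,11.9,11.6,3.0
ROSEO,4.5,3.1,1.4,3.0,0.1,2.4,3.6,1.9
SAR11,43.5,38.9,1.6,35.0,6.7,45.1,27.7,14.1
GAMMA,2.0,3.2,0.6,3.3,1.3,5.8,7.7,11.0
ALT,1.9,0.1,0.0,2.6,0.4,4.3,2.0,1.6
NOR5,1.2,0.7,0.4,2.0,0.5,1.7,2.4,1.5
AAP,8.9,4.9,1.8,16.7,5.0,10.4,6.0,1.4
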