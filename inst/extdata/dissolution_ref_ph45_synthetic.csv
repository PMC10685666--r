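time_min,pct_mean,pct_sd,medium_ph
5,55.2,2.1,4.5
10,82.4,1.8,4.5
15,93.1,1.5,4.5
20,97.2,1.1,4.5
35,99.5,0.7,4.5
45,99.8,0.5,4.5
60,100,0.4,4.5
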