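time_min,pct_mean,pct_sd,medium_ph
5,46.8,2.4,4.5
10,74.9,2.0,4.5
15,88.6,1.6,4.5
20,94.8,1.2,4.5
35,99.0,0.8,4.5
45,99.6,0.6,4.5
60,99.9,0.4,4.5
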