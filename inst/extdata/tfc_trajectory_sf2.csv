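time_years,mean_delta,ci_lower,ci_upper
0,0,,
1,-0.44,-0.78,-0.13
3,-1.974,,
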