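# Estimated per-monocyte TNF synthesis rates (pg/h/monocyte) per LPS dose.
lps_ng_ml,rate
5,0.007043
0.25,0.005270
0.1,0.002359
0.05,0.001136
0.001,0.0000
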