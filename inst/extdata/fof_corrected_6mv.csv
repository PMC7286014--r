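side_cm,CC01,PFD,EFD,avg,sd,percent_sd,EDGE,CC13
6,0.920,0.928,0.916,0.921,0.01,0.7,0.918,0.922
4,0.865,0.873,0.857,0.865,0.01,0.9,0.865,0.865
3,0.831,0.840,0.824,0.832,0.01,1.0,0.829,0.834
2,0.790,0.800,0.782,0.791,0.01,1.1,0.789,0.797
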