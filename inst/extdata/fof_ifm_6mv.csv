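side_cm,CC01,PFD,EFD,avg,sd,percent_sd,EDGE,CC13
6,0.920,0.919,0.925,0.922,0.00,0.3,0.921,0.922
4,0.865,0.865,0.865,0.865,0.00,0.0,0.865,0.865
3,0.831,0.833,0.832,0.832,0.00,0.1,0.832,0.834
2,0.790,0.792,0.790,0.791,0.00,0.2,0.792,0.797
1,0.686,0.701,0.678,0.689,0.01,1.7,0.698,NA
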