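side_cm,CC01,PFD,EFD,avg,sd,percent_sd,EDGE,CC13
6,0.916,0.928,0.908,0.917,0.01,1.1,0.918,0.922
4,0.859,0.875,0.845,0.860,0.02,1.7,0.863,0.865
3,0.824,0.844,0.811,0.826,0.02,2.0,0.830,0.833
2,0.783,0.811,0.771,0.788,0.02,2.6,0.794,0.790
1,0.674,0.736,0.668,0.693,0.04,5.4,0.720,0.615
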