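side_cm,cc13_mlc,cc13_jaw,cc13_ratio,edge_mlc,edge_jaw,edge_ratio
10,1,1,1.000,1,1,1.000
6,0.925,0.922,1.003,0.921,0.918,1.003
4,0.870,0.865,1.006,0.865,0.863,1.003
3,0.837,0.833,1.005,0.833,0.830,1.004
2,0.795,0.790,1.006,0.799,0.794,1.006
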