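side_100cm,side_110cm,fwhm_cross_cm,fwhm_in_cm,sclin_cm
6,6.6,6.45,6.63,6.54
4,4.4,4.23,4.43,4.33
3,3.3,3.12,3.32,3.22
2,2.2,2.01,2.20,2.10
1,1.1,0.90,1.11,1.00
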