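case,technique,commissioning,mean_mu,sd_mu,percent_sd
field_1cm,symmetric,uncorrected,183,11.0,6.0
field_1cm,symmetric,corrected,187,4.1,2.2
case_10,imrt,uncorrected,3838,231,6.0
case_10,imrt,corrected,3981,100,2.5
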