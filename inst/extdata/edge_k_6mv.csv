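detector_model,sclin_cm,k
EDGE,2.10,0.999
EDGE,3.22,0.994
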