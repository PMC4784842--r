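damage_state,light,moderate,severe,fatal
slight,0.05,0.005,0,0
moderate,0.25,0.03,0,0
severe,1,0.1,0.001,0.001
complete_no_collapse,5,1,0.01,0.01
complete_collapse,40,20,5,10
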