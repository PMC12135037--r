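sample,C,O,Si,N,K,P,Ca
control,88.5,9.2,0.4,0.8,0.6,0.2,0.3
plasma_treated,52.8,37.6,4.8,2.1,1.7,0.2,0.8
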