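0.25,-1.5,3.125,0
1,2,-0.5,4.75
-2.25,0.125,1,1.5
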