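sample_id,cluster
1,0
2,2
3,1
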